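#' Parameters of the time-orienting predicate
#'
#' A tester fly is "orienting" toward the target in a frame when all three
#' conditions hold: the target lies within `max_angle` of the tester's
#' heading, the centroid-to-centroid distance is at most `max_dist`, and
#' the tester is moving faster than `min_speed` (this strict gate removes
#' frames where a standing, often grooming, tester is merely passed by the
#' target). Runs shorter than `min_bout` are discarded to suppress
#' head/tail-flip tracking artifacts.
#'
#' @param max_angle Half-width of the angular acceptance cone, degrees
#'   (inclusive). Default 60.
#' @param max_dist Maximum centroid distance, mm (inclusive; roughly two
#'   body lengths). Default 5.
#' @param min_speed Minimum tester speed, mm/s (strict). Default 0.1.
#' @param min_bout Minimum bout duration, ms; shorter runs are discarded,
#'   runs of exactly `min_bout` are kept. Default 200.
#'
#' @return An object of class `orienting_params`.
#' @export
orienting_params <- function(max_angle = 60, max_dist = 5, min_speed = 0.1,
                             min_bout = 200) {
  stopifnot(max_angle > 0, max_angle <= 180, max_dist > 0, min_speed > 0,
            min_bout > 0)
  structure(list(max_angle = max_angle, max_dist = max_dist,
                 min_speed = min_speed, min_bout = min_bout),
            class = "orienting_params")
}

#' Per-frame orienting predicate
#'
#' Evaluates the three-condition orienting predicate for every frame of a
#' dyad. The bearing is taken from the tester centroid to the target
#' centroid; its absolute wrapped difference from the tester heading must
#' not exceed `max_angle`. Coincident centroids leave the bearing
#' undefined; since the distance condition is then trivially met, the
#' angular condition is treated as satisfied (and a message is emitted).
#'
#' @param dyad A [dyad_trajectory()].
#' @param params An [orienting_params()].
#' @param speed Optional per-frame tester speed (mm/s); when absent it is
#'   taken from the track or derived with [derive_speed()].
#' @param smooth_window Boxcar width for speed derivation (frames, odd);
#'   the speed entering the threshold is unsmoothed by default.
#'
#' @return Logical vector of length `n_frames`.
#' @export
orienting_mask <- function(dyad, params = orienting_params(), speed = NULL,
                           smooth_window = 1L) {
  stopifnot(inherits(dyad, "dyad_trajectory"),
            inherits(params, "orienting_params"))
  if (is.null(speed)) speed <- dyad$tester$speed
  if (is.null(speed))
    speed <- derive_speed(dyad$tester, dyad$arena$fps, smooth_window)
  dx <- dyad$target$x - dyad$tester$x
  dy <- dyad$target$y - dyad$tester$y
  dist <- sqrt(dx^2 + dy^2)
  dang <- abs(wrap_angle(atan2(dy, dx) - dyad$tester$heading))
  coincident <- dist == 0
  if (any(coincident))
    message("orienting_mask: ", sum(coincident),
            " frame(s) with coincident centroids; ",
            "angle condition treated as satisfied")
  cond_angle <- dang <= params$max_angle * pi / 180 | coincident
  cond_angle & dist <= params$max_dist & speed > params$min_speed
}

#' Segment an orienting mask into duration-filtered bouts
#'
#' Maximal runs of TRUE frames become bouts; runs shorter than
#' `params$min_bout` milliseconds are discarded (a run of exactly
#' `min_bout` is kept).
#'
#' @param mask Logical per-frame series.
#' @param fps Frames per second.
#' @param params An [orienting_params()].
#'
#' @return A [bout_table()] of `orienting` bouts by the tester, with
#'   provenance `"filtered"`.
#' @export
segment_orienting_bouts <- function(mask, fps, params = orienting_params()) {
  stopifnot(is.logical(mask), length(mask) >= 1)
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & (r$lengths >= params$min_bout * fps / 1000 - 1e-9)
  bout_table(behavior = rep("orienting", sum(keep)),
             fly = rep("tester", sum(keep)),
             start_frame = starts[keep], end_frame = ends[keep],
             provenance = "filtered")
}

# seconds of [start, end) (0-based frames) falling in each minute bin
split_duration_by_minute <- function(start_frame, end_frame, fps,
                                     n_minutes) {
  fpm <- 60 * fps
  out <- numeric(n_minutes)
  for (i in seq_along(start_frame)) {
    m0 <- floor(start_frame[i] / fpm)
    m1 <- min(ceiling(end_frame[i] / fpm) - 1, n_minutes - 1)
    for (m in m0:m1) {
      ov <- min(end_frame[i], (m + 1) * fpm) - max(start_frame[i], m * fpm)
      if (ov > 0) out[m + 1] <- out[m + 1] + ov / fps
    }
  }
  out
}

#' Total and per-minute time orienting
#'
#' Sums the durations of duration-filtered orienting bouts and attributes
#' them to minute bins, splitting bouts that span a minute boundary so the
#' per-minute series conserves the total.
#'
#' @param bouts A [bout_table()] from [segment_orienting_bouts()].
#' @param fps Frames per second.
#' @param n_frames Recording length in frames.
#'
#' @return List with `total_s` (seconds) and `per_minute` (seconds per
#'   minute bin, length `ceiling(n_frames / (60 * fps))`).
#' @export
time_orienting <- function(bouts, fps, n_frames) {
  b <- bouts[bouts$behavior == "orienting", , drop = FALSE]
  n_minutes <- ceiling(n_frames / (60 * fps))
  per_min <- split_duration_by_minute(b$start_frame, b$end_frame, fps,
                                      n_minutes)
  list(total_s = sum(bout_durations(b, fps)), per_minute = per_min)
}
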