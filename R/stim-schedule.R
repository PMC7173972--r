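#' Optogenetic stimulation paradigm
#'
#' The standard 10-min paradigm: 1 min pre-stimulation, then three blocks
#' of 1 min LED stimulation each followed by a 2 min inter-stimulus
#' interval (ISI). The timing invariant
#' `pre_s + n_blocks * (on_s + isi_s) == total_s` is enforced.
#'
#' @param pre_s Pre-stimulation duration, s.
#' @param n_blocks Number of stimulation blocks.
#' @param on_s LED-on duration per block, s.
#' @param isi_s Inter-stimulus interval per block, s.
#' @param led_frequency_hz Stimulation frequency metadata (Hz), optional.
#'
#' @return An object of class `paradigm` (includes derived `total_s`).
#' @export
paradigm <- function(pre_s = 60, n_blocks = 3, on_s = 60, isi_s = 120,
                     led_frequency_hz = NULL) {
  stopifnot(pre_s >= 0, n_blocks >= 1, on_s > 0, isi_s >= 0)
  structure(list(pre_s = pre_s, n_blocks = as.integer(n_blocks),
                 on_s = on_s, isi_s = isi_s,
                 led_frequency_hz = led_frequency_hz,
                 total_s = pre_s + n_blocks * (on_s + isi_s)),
            class = "paradigm")
}

#' Detect the LED onset frame from an indicator series
#'
#' Recordings are aligned on the frame in which the infrared indicator LED
#' first turns on: the first frame whose intensity exceeds `threshold`.
#'
#' @param intensity Per-frame indicator intensity.
#' @param threshold Intensity threshold (strict `>`).
#' @return 0-based frame index of the onset.
#' @export
detect_led_onset <- function(intensity, threshold = 1) {
  stopifnot(length(intensity) >= 1)
  i <- which(intensity > threshold)
  if (length(i) == 0L)
    stop("no frame exceeds the indicator threshold (", threshold,
         "); cannot align recording", call. = FALSE)
  i[1] - 1L
}

#' Map the paradigm onto analysis windows 1-4
#'
#' Builds the frame intervals of the pooled analysis windows, aligned on
#' the detected LED onset: window 1 is the pre-stimulation minute, window
#' 2 the union of the LED-on minutes. ISI minutes are assigned by
#' `window_mode`: `"isi_split"` (default) puts the first minute of each
#' ISI in window 3 and the second in window 4; `"isi_pooled"` puts all ISI
#' minutes in window 3 and leaves window 4 empty. The mode is carried in
#' the schedule and must be reported with any derived result.
#'
#' @param onset_frame 0-based frame of the first LED onset; must be at
#'   least `pre_s * fps` so the full pre-stimulation window exists.
#' @param fps Frames per second.
#' @param pdgm A [paradigm()].
#' @param window_mode `"isi_split"` or `"isi_pooled"`.
#' @param n_frames Optional recording length; an error is raised if the
#'   schedule would extend past it.
#'
#' @return An object of class `stim_schedule`: list with `windows` (named
#'   list of two-column start/end frame matrices, half-open), `window_minutes`,
#'   `onset_frame`, `fps`, `window_mode`, `paradigm`.
#' @export
build_schedule <- function(onset_frame, fps, pdgm = paradigm(),
                           window_mode = c("isi_split", "isi_pooled"),
                           n_frames = NULL) {
  window_mode <- match.arg(window_mode)
  stopifnot(inherits(pdgm, "paradigm"), fps > 0)
  pre_f <- round(pdgm$pre_s * fps)
  if (onset_frame < pre_f)
    stop("onset_frame (", onset_frame, ") precedes the end of the ",
         "pre-stimulation window (needs >= ", pre_f, " frames)",
         call. = FALSE)
  on_f <- round(pdgm$on_s * fps)
  isi_f <- round(pdgm$isi_s * fps)
  block_starts <- onset_frame + (seq_len(pdgm$n_blocks) - 1L) *
    (on_f + isi_f)
  w1 <- cbind(onset_frame - pre_f, onset_frame)
  w2 <- cbind(block_starts, block_starts + on_f)
  isi_start <- block_starts + on_f
  if (window_mode == "isi_split") {
    half_f <- isi_f %/% 2L
    w3 <- cbind(isi_start, isi_start + half_f)
    w4 <- cbind(isi_start + half_f, isi_start + isi_f)
  } else {
    w3 <- cbind(isi_start, isi_start + isi_f)
    w4 <- cbind(integer(0), integer(0))
  }
  windows <- list(`1` = w1, `2` = w2, `3` = w3, `4` = w4)
  windows <- lapply(windows, function(w) { dimnames(w) <- NULL; w })
  last <- max(vapply(windows, function(w)
    if (nrow(w)) max(w[, 2]) else 0L, numeric(1)))
  if (!is.null(n_frames) && last > n_frames)
    stop("schedule extends to frame ", last, " but the recording has only ",
         n_frames, " frames", call. = FALSE)
  window_minutes <- vapply(windows, function(w)
    sum(w[, 2] - w[, 1]) / (60 * fps), numeric(1))
  structure(list(windows = windows, window_minutes = window_minutes,
                 onset_frame = as.integer(onset_frame), fps = fps,
                 window_mode = window_mode, paradigm = pdgm),
            class = "stim_schedule")
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat("stim_schedule (", x$window_mode, "), onset frame ", x$onset_frame,
      " @ ", x$fps, " fps\n", sep = "")
  for (w in names(x$windows)) {
    iv <- x$windows[[w]]
    cat("  window ", w, " (", x$window_minutes[[w]], " min): ",
        if (nrow(iv)) paste(sprintf("[%d,%d)", iv[, 1], iv[, 2]),
                            collapse = " ") else "(empty)", "\n", sep = "")
  }
  invisible(x)
}

# seconds of overlap of [s,e) bouts with a set of [a,b) intervals
overlap_seconds <- function(start_frame, end_frame, intervals, fps) {
  tot <- 0
  for (k in seq_len(nrow(intervals))) {
    ov <- pmin(end_frame, intervals[k, 2]) - pmax(start_frame,
                                                  intervals[k, 1])
    tot <- tot + sum(pmax(ov, 0)) / fps
  }
  tot
}

in_intervals <- function(frames, intervals) {
  hit <- rep(FALSE, length(frames))
  for (k in seq_len(nrow(intervals)))
    hit <- hit | (frames >= intervals[k, 1] & frames < intervals[k, 2])
  hit
}

#' Pool behavior amounts into analysis windows
#'
#' Computes, for one behavior, the per-minute amount in each analysis
#' window: pooled amount divided by pooled minutes. Counts attribute each
#' bout to the window containing its start frame; durations are split
#' across window boundaries by frame membership. A window with zero
#' pooled minutes (window 4 under `"isi_pooled"`) gets `NA`.
#'
#' @param bouts A filtered [bout_table()].
#' @param schedule A [build_schedule()] result.
#' @param behavior Behavior label to pool.
#' @param mode `"count"` (bouts/min) or `"duration"` (s/min).
#' @param fly Optional fly role subset.
#'
#' @return Data frame with columns `window`, `minutes`, `amount`, `rate`.
#' @export
pool_windows <- function(bouts, schedule, behavior,
                         mode = c("count", "duration"), fly = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(bouts, "bout_table"))
  b <- bouts[bouts$behavior == behavior, , drop = FALSE]
  if (!is.null(fly)) b <- b[b$fly == fly, , drop = FALSE]
  res <- lapply(names(schedule$windows), function(w) {
    iv <- schedule$windows[[w]]
    minutes <- schedule$window_minutes[[w]]
    if (minutes == 0)
      return(data.frame(window = as.integer(w), minutes = 0,
                        amount = NA_real_, rate = NA_real_))
    amount <- if (mode == "count") {
      sum(in_intervals(b$start_frame, iv))
    } else {
      overlap_seconds(b$start_frame, b$end_frame, iv, schedule$fps)
    }
    data.frame(window = as.integer(w), minutes = minutes, amount = amount,
               rate = amount / minutes)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
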