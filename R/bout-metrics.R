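#' Behavior-specific minimum bout durations
#'
#' Extremely short classifier bouts are nearly always false positives and
#' are removed before quantification: lunges and headbutts shorter than
#' 50 ms, wing extensions shorter than 100 ms. Comparisons are strict
#' "less than" discards, so a bout of exactly the threshold duration is
#' kept.
#'
#' @param lunge,headbutt,wing_extension Thresholds in ms.
#' @param ... Further named thresholds (e.g. `orienting = 200`) for other
#'   behavior labels.
#'
#' @return A named list of class `bout_filter_params`.
#' @export
bout_filter_params <- function(lunge = 50, headbutt = 50,
                               wing_extension = 100, ...) {
  p <- c(list(lunge = lunge, headbutt = headbutt,
              wing_extension = wing_extension), list(...))
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v > 0, logical(1))))
  bad <- !(names(p) %in% known_behaviors)
  if (any(bad))
    stop("thresholds keyed by unknown behavior label(s): ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "bout_filter_params")
}

#' Duration-filter a bout table
#'
#' Removes bouts shorter than their behavior's minimum duration. Every
#' behavior present in the table must have a threshold; an unknown label
#' is a configuration error, never silently passed through. Filtering is
#' idempotent and order-preserving.
#'
#' @param bouts A [bout_table()].
#' @param params A [bout_filter_params()].
#' @param fps Frames per second.
#'
#' @return The filtered [bout_table()] with provenance `"filtered"`.
#' @export
filter_bouts <- function(bouts, params = bout_filter_params(), fps) {
  stopifnot(inherits(bouts, "bout_table"), fps > 0)
  if (nrow(bouts) == 0L) {
    attr(bouts, "provenance") <- "filtered"
    return(bouts)
  }
  miss <- setdiff(unique(bouts$behavior), names(params))
  if (length(miss))
    stop("no duration threshold configured for behavior(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  thr_s <- unlist(params)[bouts$behavior] / 1000
  keep <- bout_durations(bouts, fps) >= thr_s - 1e-9
  out <- bouts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- "filtered"
  class(out) <- c("bout_table", "data.frame")
  out
}

#' Per-minute amounts of one behavior
#'
#' Bins the amount of a behavior per minute of recording: bout counts for
#' momentary actions (lunges, headbutts; each bout is attributed to the
#' minute of its start frame) or total seconds for duration-scored actions
#' (wing extension, orienting; bouts spanning a minute boundary are split
#' by frame membership so durations are conserved).
#'
#' @param bouts A filtered [bout_table()].
#' @param behavior Behavior label to bin.
#' @param mode `"count"` (bouts/min) or `"duration"` (s/min).
#' @param fps Frames per second.
#' @param n_frames Recording length in frames.
#' @param fly Optional fly role to subset; default pools all flies in the
#'   table.
#'
#' @return An object of class `minute_bins`: list with `behavior`, `fly`,
#'   `mode`, `values` (length `ceiling(n_frames/(60*fps))`) and
#'   `n_minutes`.
#' @export
bin_per_minute <- function(bouts, behavior,
                           mode = c("count", "duration"), fps, n_frames,
                           fly = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(bouts, "bout_table"))
  if (bout_provenance(bouts) != "filtered")
    stop("bin_per_minute expects a duration-filtered bout table; ",
         "run filter_bouts() first", call. = FALSE)
  if (behavior == "wing_extension" && mode == "count")
    message("bin_per_minute: counting wing_extension bouts; this behavior ",
            "is conventionally scored by duration")
  b <- bouts[bouts$behavior == behavior, , drop = FALSE]
  if (!is.null(fly)) b <- b[b$fly == fly, , drop = FALSE]
  n_minutes <- ceiling(n_frames / (60 * fps))
  values <- if (mode == "count") {
    tabulate(floor(b$start_frame / (60 * fps)) + 1L, nbins = n_minutes)
  } else {
    split_duration_by_minute(b$start_frame, b$end_frame, fps, n_minutes)
  }
  structure(list(behavior = behavior, fly = fly %||% "all", mode = mode,
                 values = values, n_minutes = n_minutes, fps = fps),
            class = "minute_bins")
}

#' @export
print.minute_bins <- function(x, ...) {
  cat("minute_bins:", x$behavior, "(", x$mode, ") for", x$fly, "over",
      x$n_minutes, "min\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Minute bins as a data frame
#'
#' @param x A `minute_bins` object.
#' @param ... Unused.
#' @return Data frame with columns `behavior,fly,mode,minute,value`.
#' @method as.data.frame minute_bins
#' @export
as.data.frame.minute_bins <- function(x, ...) {
  data.frame(behavior = x$behavior, fly = x$fly, mode = x$mode,
             minute = seq_len(x$n_minutes) - 1L, value = x$values,
             stringsAsFactors = FALSE)
}
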