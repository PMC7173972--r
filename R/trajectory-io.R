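#' Arena and recording configuration
#'
#' Describes the recording geometry and frame rate shared by both flies of a
#' dyad. The arena is a circular chamber centered on the coordinate origin;
#' all positions are in millimetres and all internal computation is done in
#' mm and seconds.
#'
#' @param fps Frames per second of the recording (Hz). Default 60.
#' @param arena_diameter Diameter of the circular arena in mm.
#' @param n_frames Total number of frames in the recording.
#' @param mm_per_px Optional mm-per-pixel scale for pixel-unit input files.
#'
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(fps = 60, arena_diameter = 20, n_frames,
                         mm_per_px = NULL) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0)
  stopifnot(is.numeric(arena_diameter), length(arena_diameter) == 1L,
            arena_diameter > 0)
  stopifnot(is.numeric(n_frames), length(n_frames) == 1L, n_frames >= 1)
  if (!is.null(mm_per_px)) stopifnot(is.numeric(mm_per_px), mm_per_px > 0)
  structure(list(fps = fps, arena_diameter = arena_diameter,
                 n_frames = as.integer(n_frames), mm_per_px = mm_per_px),
            class = "arena_config")
}

#' Per-frame track of a single fly
#'
#' Holds the per-frame centroid (mm) and head direction (radians,
#' mathematical convention: 0 along +x, counterclockwise positive, wrapped
#' to (-pi, pi]) of one fly. Speed (mm/s) is optional and derivable with
#' [derive_speed()].
#'
#' @param role Either `"tester"` or `"target"`.
#' @param x,y Per-frame centroid coordinates in mm.
#' @param heading Per-frame head direction in radians; values are wrapped
#'   to (-pi, pi] on construction.
#' @param speed Optional per-frame centroid speed in mm/s.
#'
#' @return An object of class `fly_track`.
#' @export
fly_track <- function(role = c("tester", "target"), x, y, heading,
                      speed = NULL) {
  role <- match.arg(role)
  n <- length(x)
  if (length(y) != n || length(heading) != n)
    stop("x, y and heading must have identical length", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("track coordinates contain NA at frames: ",
         paste(utils::head(which(is.na(x) | is.na(y)) - 1L, 10L),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(heading)))
    stop("heading contains non-finite values", call. = FALSE)
  heading <- wrap_angle(heading)
  if (!is.null(speed)) {
    if (length(speed) != n) stop("speed length mismatch", call. = FALSE)
    if (any(speed < 0)) stop("speed must be non-negative", call. = FALSE)
  }
  structure(list(role = role, x = as.numeric(x), y = as.numeric(y),
                 heading = heading, speed = speed),
            class = "fly_track")
}

#' Tester/target dyad trajectory
#'
#' @param arena An [arena_config()].
#' @param tester,target [fly_track()] objects with roles `"tester"` and
#'   `"target"`; both must have `arena$n_frames` frames and lie within the
#'   arena bounds.
#' @param validate_bounds Check that centroids fall inside the arena circle.
#'
#' @return An object of class `dyad_trajectory`.
#' @export
dyad_trajectory <- function(arena, tester, target, validate_bounds = TRUE) {
  stopifnot(inherits(arena, "arena_config"),
            inherits(tester, "fly_track"), inherits(target, "fly_track"))
  if (tester$role != "tester" || target$role != "target")
    stop("exactly one tester and one target track are required",
         call. = FALSE)
  n <- arena$n_frames
  if (length(tester$x) != n || length(target$x) != n)
    stop("track lengths must equal arena$n_frames (", n, ")", call. = FALSE)
  if (validate_bounds) {
    r <- arena$arena_diameter / 2 + 1e-9
    for (tr in list(tester, target)) {
      if (any(tr$x^2 + tr$y^2 > r^2))
        stop(tr$role, " track leaves the arena bounds", call. = FALSE)
    }
  }
  structure(list(arena = arena, tester = tester, target = target),
            class = "dyad_trajectory")
}

#' @export
print.dyad_trajectory <- function(x, ...) {
  cat("dyad_trajectory:", x$arena$n_frames, "frames @", x$arena$fps,
      "fps (", round(x$arena$n_frames / x$arena$fps, 2), "s ),",
      "arena diameter", x$arena$arena_diameter, "mm\n")
  invisible(x)
}

# wrap angles to (-pi, pi]
wrap_angle <- function(theta) {
  w <- ((theta + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

known_behaviors <- c("lunge", "wing_extension", "headbutt", "orienting",
                     "other")

#' Table of labeled behavior bouts
#'
#' A bout is a half-open frame interval `[start_frame, end_frame)` of one
#' behavior by one fly; frames are 0-based, so `duration_s =
#' (end_frame - start_frame) / fps`. Rows are sorted by
#' (behavior, fly, start_frame); overlapping bouts of the same behavior and
#' fly are merged on construction.
#'
#' @param behavior Behavior labels (`lunge`, `wing_extension`, `headbutt`,
#'   `orienting`, `other`).
#' @param fly Fly roles (`tester`/`target`).
#' @param start_frame,end_frame 0-based half-open frame intervals.
#' @param provenance `"raw"` (classifier output) or `"filtered"` (after
#'   [filter_bouts()]).
#'
#' @return A `data.frame` of class `bout_table` with attribute
#'   `provenance`.
#' @export
bout_table <- function(behavior = character(), fly = character(),
                       start_frame = integer(), end_frame = integer(),
                       provenance = c("raw", "filtered")) {
  provenance <- match.arg(provenance)
  n <- max(length(start_frame), length(end_frame))
  if (length(behavior) == 1L) behavior <- rep(behavior, length.out = n)
  if (length(fly) == 1L) fly <- rep(fly, length.out = n)
  stopifnot(length(behavior) == n, length(fly) == n,
            length(start_frame) == n, length(end_frame) == n)
  bad <- !(behavior %in% known_behaviors)
  if (any(bad))
    stop("unknown behavior label(s): ",
         paste(unique(behavior[bad]), collapse = ", "), call. = FALSE)
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  if (any(start_frame < 0L))
    stop("start_frame must be >= 0", call. = FALSE)
  if (any(end_frame <= start_frame))
    stop("end_frame must be strictly greater than start_frame ",
         "(half-open intervals)", call. = FALSE)
  df <- data.frame(behavior = as.character(behavior),
                   fly = as.character(fly),
                   start_frame = start_frame, end_frame = end_frame,
                   stringsAsFactors = FALSE)
  df <- merge_overlapping_bouts(df)
  df <- df[order(df$behavior, df$fly, df$start_frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("bout_table", "data.frame"))
}

# merge overlapping same-behavior same-fly intervals; strictly adjacent
# intervals ([a,b) then [b,c)) are kept separate
merge_overlapping_bouts <- function(df) {
  if (nrow(df) == 0L) return(df)
  parts <- split(df, list(df$behavior, df$fly), drop = TRUE)
  out <- lapply(parts, function(p) {
    p <- p[order(p$start_frame, p$end_frame), , drop = FALSE]
    s <- p$start_frame; e <- p$end_frame
    keep_s <- s[1]; keep_e <- e[1]
    for (i in seq_len(nrow(p))[-1]) {
      k <- length(keep_s)
      if (s[i] < keep_e[k]) {           # strict overlap
        keep_e[k] <- max(keep_e[k], e[i])
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
      }
    }
    data.frame(behavior = p$behavior[1], fly = p$fly[1],
               start_frame = keep_s, end_frame = keep_e,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

bout_provenance <- function(bouts) attr(bouts, "provenance") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bout durations in seconds
#'
#' @param bouts A [bout_table()].
#' @param fps Frames per second.
#' @return Numeric vector of durations, `(end - start) / fps`.
#' @export
bout_durations <- function(bouts, fps) {
  (bouts$end_frame - bouts$start_frame) / fps
}

#' Read a dyad trajectory CSV
#'
#' Expects the canonical dialect: header `frame,role,x_mm,y_mm,heading_rad`
#' with one row per fly per frame, frames contiguous from 0 for each role.
#' Pixel-unit files may instead carry `x_px,y_px` together with a
#' `mm_per_px` scale (argument or arena metadata), which the reader
#' converts; all downstream computation is in mm.
#'
#' @param path CSV file path.
#' @param fps Frames per second of the recording.
#' @param arena_diameter Arena diameter in mm.
#' @param mm_per_px Optional pixel scale for `x_px`/`y_px` files.
#' @param validate_bounds Passed to [dyad_trajectory()].
#'
#' @return A [dyad_trajectory()].
#' @export
read_trajectory <- function(path, fps = 60, arena_diameter = 20,
                            mm_per_px = NULL, validate_bounds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path))
  need <- c("frame", "role", "heading_rad")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trajectory file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (all(c("x_mm", "y_mm") %in% names(df))) {
    df$x <- df$x_mm; df$y <- df$y_mm
  } else if (all(c("x_px", "y_px") %in% names(df))) {
    if (is.null(mm_per_px))
      stop("pixel-unit trajectory requires mm_per_px", call. = FALSE)
    df$x <- df$x_px * mm_per_px; df$y <- df$y_px * mm_per_px
  } else {
    stop("trajectory file is missing column(s): x_mm, y_mm",
         call. = FALSE)
  }
  tracks <- lapply(c("tester", "target"), function(role) {
    sub <- df[df$role == role, , drop = FALSE]
    if (nrow(sub) == 0L)
      stop("no rows for role '", role, "'", call. = FALSE)
    sub <- sub[order(sub$frame), , drop = FALSE]
    expected <- seq.int(0L, nrow(sub) - 1L)
    if (!identical(as.integer(sub$frame), expected)) {
      gaps <- setdiff(seq.int(0L, max(sub$frame)), sub$frame)
      stop("non-contiguous frames for role '", role, "': missing frame(s) ",
           paste(utils::head(gaps, 10L), collapse = ", "), call. = FALSE)
    }
    bad <- which(!is.finite(sub$x) | !is.finite(sub$y))
    if (length(bad))
      stop("NaN/NA coordinates for role '", role, "' at frame(s) ",
           paste(utils::head(sub$frame[bad], 10L), collapse = ", "),
           call. = FALSE)
    fly_track(role, sub$x, sub$y, sub$heading_rad)
  })
  n <- length(tracks[[1]]$x)
  if (length(tracks[[2]]$x) != n)
    stop("tester and target frame counts differ", call. = FALSE)
  arena <- arena_config(fps = fps, arena_diameter = arena_diameter,
                        n_frames = n, mm_per_px = mm_per_px)
  dyad_trajectory(arena, tracks[[1]], tracks[[2]],
                  validate_bounds = validate_bounds)
}

#' Write a dyad trajectory CSV
#'
#' @param dyad A [dyad_trajectory()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(dyad, path) {
  n <- dyad$arena$n_frames
  df <- rbind(
    data.frame(frame = seq.int(0L, n - 1L), role = "tester",
               x_mm = dyad$tester$x, y_mm = dyad$tester$y,
               heading_rad = dyad$tester$heading),
    data.frame(frame = seq.int(0L, n - 1L), role = "target",
               x_mm = dyad$target$x, y_mm = dyad$target$y,
               heading_rad = dyad$target$heading))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a bout table CSV
#'
#' Expects header `behavior,fly,start_frame,end_frame` (0-based, half-open
#' intervals). Overlapping same-behavior same-fly intervals are merged into
#' a single bout. An empty file with only the header yields an empty table.
#'
#' @param path CSV file path.
#' @return A [bout_table()] with provenance `"raw"`.
#' @export
read_bouts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path))
  need <- c("behavior", "fly", "start_frame", "end_frame")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("bout file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bout_table(df$behavior, df$fly, df$start_frame, df$end_frame,
             provenance = "raw")
}

#' Write a bout table CSV
#'
#' @param bouts A [bout_table()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  data.table::fwrite(as.data.frame(bouts)[, c("behavior", "fly",
                                              "start_frame", "end_frame")],
                     path)
  invisible(path)
}

#' Per-frame centroid speed
#'
#' Speed is the backward finite difference of the centroid position scaled
#' by the frame rate, optionally boxcar-smoothed. The first frame copies
#' the second frame's value (0 for a single-frame track), so no frame is
#' left undefined. At the series edges the boxcar window shrinks to the
#' available frames.
#'
#' @param track A [fly_track()] (or any list with `x`/`y`).
#' @param fps Frames per second.
#' @param smooth_window Odd boxcar width in frames; 1 (default) disables
#'   smoothing.
#'
#' @return Numeric vector of speeds in mm/s, all `>= 0`.
#' @export
derive_speed <- function(track, fps, smooth_window = 1L) {
  stopifnot(fps > 0, smooth_window >= 1, smooth_window %% 2 == 1)
  x <- track$x; y <- track$y
  n <- length(x)
  if (n == 1L) return(0)
  v <- c(0, sqrt(diff(x)^2 + diff(y)^2) * fps)
  v[1] <- v[2]
  if (smooth_window > 1L) {
    half <- (smooth_window - 1L) %/% 2L
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    v <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  v
}

#' Write analysis results to CSV or JSON
#'
#' Writes a `window_summary`, `stat_report`, minute-bin table or any plain
#' data frame losslessly; [read_results()] restores it. CSV uses
#' shortest-round-trip numeric formatting so `read(write(x))` reproduces
#' `x` exactly.
#'
#' @param x A data frame (possibly classed).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(x)
  if (format == "csv") {
    data.table::fwrite(df, path)
  } else {
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows",
                         na = "null")
  }
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"`.
#' @return A data frame.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    as.data.frame(data.table::fread(path))
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
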