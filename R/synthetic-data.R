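# run code under a local RNG seed, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Simulation specification
#'
#' Bundles everything the generators need: arena and recording geometry,
#' dyad kinematics, interaction (approach-epoch) dynamics, per-window
#' behavior bout rates with log-normal duration models, and the LED
#' paradigm. Defaults emulate the standard assay: a 10-min recording at
#' 60 fps in a circular arena of 10 mm radius, with bout durations well
#' above the false-positive filters (lunge median 120 ms, wing extension
#' median 800 ms) and stimulation-elevated rates in window 2.
#'
#' @param seed Integer seed; a fixed seed reproduces every generated
#'   object exactly.
#' @param arena An [arena_config()]; default 60 fps, 36,000 frames
#'   (600 s), 20 mm diameter.
#' @param kinematics List: `step_sd` (mm per frame scale of step lengths),
#'   `turn_sd` (rad, per-frame heading diffusion), `wall_margin` (mm kept
#'   off the wall by reflection).
#' @param interaction List: `p_enter`,`p_exit` (per-frame probabilities of
#'   entering/leaving an approach epoch in which the tester steers toward
#'   the target), `approach_turn_sd` (rad, heading noise while
#'   approaching). Set `p_enter = 0` for independent wanderers.
#' @param bout_model Named list per behavior: `rates` (events/min in
#'   windows 1-4), `median_ms` and `sdlog` of the log-normal duration.
#' @param led A [paradigm()].
#' @param onset_s LED onset time, s from recording start.
#'
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     arena = arena_config(fps = 60, arena_diameter = 20,
                                          n_frames = 36000),
                     kinematics = list(step_sd = 0.15, turn_sd = 0.3,
                                       wall_margin = 0.5),
                     interaction = list(p_enter = 0.01, p_exit = 0.02,
                                        approach_turn_sd = 0.1),
                     bout_model = list(
                       lunge = list(rates = c(0.2, 3, 0.8, 0.4),
                                    median_ms = 120, sdlog = 0.3),
                       wing_extension = list(rates = c(0.5, 4, 1.5, 0.8),
                                             median_ms = 800,
                                             sdlog = 0.4),
                       headbutt = list(rates = c(0.2, 0.2, 0.2, 0.2),
                                       median_ms = 120, sdlog = 0.3)),
                     led = paradigm(), onset_s = 60) {
  stopifnot(inherits(arena, "arena_config"), inherits(led, "paradigm"))
  if (arena$arena_diameter / 2 <= kinematics$wall_margin)
    stop("infeasible arena: wall margin leaves no interior", call. = FALSE)
  for (bm in bout_model)
    stopifnot(all(bm$rates >= 0), bm$median_ms > 0, bm$sdlog >= 0)
  structure(list(seed = as.integer(seed), arena = arena,
                 kinematics = kinematics, interaction = interaction,
                 bout_model = bout_model, led = led, onset_s = onset_s),
            class = "sim_spec")
}

# orienting predicate re-stated inline (kept independent of
# orienting_mask so generator truth can cross-check the pipeline)
truth_orienting <- function(tx, ty, th, gx, gy, fps,
                            max_angle = 60, max_dist = 5,
                            min_speed = 0.1) {
  n <- length(tx)
  sp <- c(0, sqrt(diff(tx)^2 + diff(ty)^2) * fps)
  if (n > 1) sp[1] <- sp[2]
  dx <- gx - tx; dy <- gy - ty
  dist <- sqrt(dx^2 + dy^2)
  dang <- abs(wrap_angle(atan2(dy, dx) - th))
  (dang <= max_angle * pi / 180 | dist == 0) & dist <= max_dist &
    sp > min_speed
}

#' Simulate a dyad trajectory with known orienting truth
#'
#' Correlated random walk for both flies in the circular arena, with
#' reflective walls. The tester intermittently enters "approach" epochs
#' (two-state Markov chain) during which its heading is steered toward
#' the target, generating genuine orienting episodes. The per-frame truth
#' of the orienting predicate, evaluated from the generated kinematics,
#' is attached as attribute `"orienting_truth"`.
#'
#' @param spec A [sim_spec()].
#' @return A [dyad_trajectory()] with attributes `orienting_truth`
#'   (logical vector) and `seed`.
#' @export
simulate_dyad <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_local_seed(spec$seed, {
    n <- spec$arena$n_frames
    fps <- spec$arena$fps
    R <- spec$arena$arena_diameter / 2 - spec$kinematics$wall_margin
    step_sd <- spec$kinematics$step_sd
    turn_sd <- spec$kinematics$turn_sd
    p_in <- spec$interaction$p_enter
    p_out <- spec$interaction$p_exit
    app_sd <- spec$interaction$approach_turn_sd
    # pre-draw randomness (2 flies x n frames)
    turns <- matrix(stats::rnorm(2L * n, 0, turn_sd), nrow = 2L)
    steps <- matrix(abs(stats::rnorm(2L * n, 0, step_sd)), nrow = 2L)
    u_state <- stats::runif(n)
    app_noise <- stats::rnorm(n, 0, app_sd)
    x <- matrix(0, nrow = 2L, ncol = n)
    y <- matrix(0, nrow = 2L, ncol = n)
    h <- matrix(0, nrow = 2L, ncol = n)
    # initial poses: uniform in the disc, uniform heading
    r0 <- R * sqrt(stats::runif(2L)); a0 <- stats::runif(2L, 0, 2 * pi)
    x[, 1] <- r0 * cos(a0); y[, 1] <- r0 * sin(a0)
    h[, 1] <- stats::runif(2L, -pi, pi)
    approaching <- FALSE
    for (t in seq_len(n)[-1]) {
      for (f in 1:2) {
        if (f == 1L) {
          approaching <- if (approaching) u_state[t] >= p_out
                         else u_state[t] < p_in
        }
        th <- if (f == 1L && approaching) {
          wrap_angle(atan2(y[2, t - 1] - y[1, t - 1],
                           x[2, t - 1] - x[1, t - 1]) + app_noise[t])
        } else {
          wrap_angle(h[f, t - 1] + turns[f, t])
        }
        nx <- x[f, t - 1] + steps[f, t] * cos(th)
        ny <- y[f, t - 1] + steps[f, t] * sin(th)
        rr <- sqrt(nx^2 + ny^2)
        if (rr > R) {
          # reflect position radially and heading across the wall tangent
          sc <- (2 * R - rr) / rr
          nx <- nx * sc; ny <- ny * sc
          nhat <- c(nx, ny) / sqrt(nx^2 + ny^2)
          v <- c(cos(th), sin(th))
          v <- v - 2 * sum(v * nhat) * nhat
          th <- atan2(v[2], v[1])
        }
        x[f, t] <- nx; y[f, t] <- ny; h[f, t] <- th
      }
    }
    tester <- fly_track("tester", x[1, ], y[1, ], h[1, ])
    target <- fly_track("target", x[2, ], y[2, ], h[2, ])
    dyad <- dyad_trajectory(spec$arena, tester, target)
    attr(dyad, "orienting_truth") <-
      truth_orienting(x[1, ], y[1, ], h[1, ], x[2, ], y[2, ], fps)
    attr(dyad, "seed") <- spec$seed
    dyad
  })
}

#' Deterministic scripted dyad with analytically known orienting truth
#'
#' Builds a piecewise-constant trajectory from a segment table: within a
#' segment the tester keeps a fixed pose relative to the target and moves
#' at a fixed speed (both flies drift together along +x, so the relative
#' geometry — bearing angle and distance — is exact and constant, and the
#' tester's backward-difference speed equals the scripted speed on every
#' frame). The truth of the orienting predicate per segment follows
#' directly from the scripted pose and speed and is attached as attribute
#' `"orienting_truth"`.
#'
#' @param segments Data frame with columns `duration_s`, `tester_x`,
#'   `tester_y`, `tester_heading`, `tester_speed`, `target_x`,
#'   `target_y`. Durations must be whole numbers of frames.
#' @param fps Frames per second.
#' @param params [orienting_params()] used to evaluate the per-segment
#'   truth.
#'
#' @return A [dyad_trajectory()] (arena sized to contain the drift;
#'   bounds not re-validated) with attribute `orienting_truth`.
#' @export
scripted_dyad <- function(segments, fps = 60,
                          params = orienting_params()) {
  need <- c("duration_s", "tester_x", "tester_y", "tester_heading",
            "tester_speed", "target_x", "target_y")
  miss <- setdiff(need, names(segments))
  if (length(miss))
    stop("segments missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  nf <- segments$duration_s * fps
  if (any(abs(nf - round(nf)) > 1e-6))
    stop("segment durations must be whole numbers of frames",
         call. = FALSE)
  nf <- as.integer(round(nf))
  n <- sum(nf)
  seg_of <- rep(seq_len(nrow(segments)), nf)
  # common drift: per-frame displacement equals the segment's tester speed
  drift <- cumsum(rep(segments$tester_speed / fps, nf))
  tx <- segments$tester_x[seg_of] + drift
  ty <- segments$tester_y[seg_of]
  th <- segments$tester_heading[seg_of]
  gx <- segments$target_x[seg_of] + drift
  gy <- segments$target_y[seg_of]
  # per-segment analytic truth of the three conditions
  dxs <- segments$target_x - segments$tester_x
  dys <- segments$target_y - segments$tester_y
  dist <- sqrt(dxs^2 + dys^2)
  dang <- abs(wrap_angle(atan2(dys, dxs) - segments$tester_heading))
  seg_true <- (dang <= params$max_angle * pi / 180 | dist == 0) &
    dist <= params$max_dist & segments$tester_speed > params$min_speed
  truth <- seg_true[seg_of]
  extent <- 2 * max(abs(c(tx, ty, gx, gy))) + 2
  arena <- arena_config(fps = fps, arena_diameter = extent, n_frames = n)
  dyad <- dyad_trajectory(arena,
                          fly_track("tester", tx, ty, th),
                          fly_track("target", gx, gy, rep(0, n)),
                          validate_bounds = FALSE)
  attr(dyad, "orienting_truth") <- truth
  dyad
}

#' Simulate behavior bouts from per-window Poisson rates
#'
#' Draws bout onsets as a homogeneous Poisson process within each
#' analysis window at that window's rate, with i.i.d. log-normal
#' durations (truncated at the end of the recording). Overlapping
#' same-behavior bouts are merged by the [bout_table()] constructor. The
#' per-window rates used are attached as attribute `"true_rates"`.
#'
#' @param spec A [sim_spec()] (bout model and seed).
#' @param schedule A [build_schedule()] result; windows must match the
#'   rate vectors' length (4).
#' @param seed Optional override of `spec$seed`.
#'
#' @return A [bout_table()] (provenance `"raw"`, fly `"tester"`) with
#'   attribute `true_rates`.
#' @export
simulate_bouts <- function(spec, schedule, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"), inherits(schedule, "stim_schedule"))
  n_frames <- spec$arena$n_frames
  fps <- spec$arena$fps
  with_local_seed(seed %||% spec$seed, {
    beh <- character(); s0 <- integer(); s1 <- integer()
    for (b in names(spec$bout_model)) {
      bm <- spec$bout_model[[b]]
      stopifnot(length(bm$rates) == length(schedule$windows))
      for (w in seq_along(schedule$windows)) {
        iv <- schedule$windows[[w]]
        for (k in seq_len(nrow(iv))) {
          minutes <- (iv[k, 2] - iv[k, 1]) / (60 * fps)
          nev <- stats::rpois(1L, bm$rates[w] * minutes)
          if (nev == 0L) next
          starts <- sort(floor(stats::runif(nev, iv[k, 1], iv[k, 2])))
          dur_ms <- stats::rlnorm(nev, log(bm$median_ms), bm$sdlog)
          dur_f <- pmax(1L, as.integer(round(dur_ms / 1000 * fps)))
          ends <- pmin(starts + dur_f, n_frames)
          ok <- ends > starts
          beh <- c(beh, rep(b, sum(ok)))
          s0 <- c(s0, as.integer(starts[ok]))
          s1 <- c(s1, as.integer(ends[ok]))
        }
      }
    }
    bt <- bout_table(beh, rep("tester", length(beh)), s0, s1,
                     provenance = "raw")
    attr(bt, "true_rates") <- lapply(spec$bout_model, `[[`, "rates")
    bt
  })
}

#' Synthetic LED indicator trace
#'
#' Per-frame indicator intensity: baseline everywhere, `amplitude` during
#' the LED-on (window 2) intervals, optional Gaussian noise clipped at 0.
#'
#' @param schedule A [build_schedule()] result.
#' @param n_frames Recording length.
#' @param baseline,amplitude Intensities off/on.
#' @param noise_sd Gaussian noise SD.
#' @param seed Seed for the noise (only used when `noise_sd > 0`).
#' @return Numeric vector of length `n_frames`.
#' @export
simulate_led_indicator <- function(schedule, n_frames, baseline = 0,
                                   amplitude = 10, noise_sd = 0,
                                   seed = 1L) {
  iv <- schedule$windows[["2"]]
  out <- rep(baseline, n_frames)
  for (k in seq_len(nrow(iv)))
    out[(iv[k, 1] + 1L):min(iv[k, 2], n_frames)] <- amplitude
  if (noise_sd > 0)
    out <- with_local_seed(seed,
                           pmax(out + stats::rnorm(n_frames, 0, noise_sd),
                                0))
  out
}

#' Simulate a voxel stack of spherical blobs with known volumes
#'
#' Rasterizes spheres of stated intensity onto a voxel grid (overlaps
#' take the maximum intensity), adds Gaussian noise clipped at zero, and
#' records the true rasterized voxel counts (per blob and for the union)
#' as attribute `"true_voxels"`.
#'
#' @param blobs List of `list(center = c(x, y, z), radius, intensity)`
#'   in voxel units; a radius of 0 marks a single voxel.
#' @param shape Grid dimensions.
#' @param voxel_size Micrometres per voxel along each axis.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param seed Seed for the noise.
#'
#' @return A [voxel_stack()] with attribute `true_voxels`
#'   (`list(per_blob =, union =)`).
#' @export
simulate_voxel_stack <- function(blobs, shape = c(32, 32, 16),
                                 voxel_size = c(1, 1, 1), noise_sd = 0,
                                 seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  grid <- array(0, dim = shape)
  cx <- slice.index(grid, 1L)
  cy <- slice.index(grid, 2L)
  cz <- slice.index(grid, 3L)
  union_mask <- array(FALSE, dim = shape)
  per_blob <- integer(length(blobs))
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    stopifnot(length(b$center) == 3L, b$radius >= 0, b$intensity >= 0)
    if (any(b$center < 1 - 1e-9) || any(b$center > shape + 1e-9))
      stop("blob ", i, " lies outside the grid", call. = FALSE)
    inside <- (cx - b$center[1])^2 + (cy - b$center[2])^2 +
      (cz - b$center[3])^2 <= b$radius^2 + 1e-12
    per_blob[i] <- sum(inside)
    union_mask <- union_mask | inside
    grid[inside] <- pmax(grid[inside], b$intensity)
  }
  if (noise_sd > 0)
    grid <- with_local_seed(seed,
                            pmax(grid + array(stats::rnorm(length(grid),
                                                           0, noise_sd),
                                              dim = shape), 0))
  st <- voxel_stack(grid, voxel_size)
  attr(st, "true_voxels") <- list(per_blob = per_blob,
                                  union = sum(union_mask))
  st
}

#' Simulate one assay pair (trajectory, bouts, indicator)
#'
#' Convenience wrapper producing everything [run_pair()] consumes, with
#' the generator truths attached.
#'
#' @param spec A [sim_spec()].
#' @param window_mode Passed to [build_schedule()].
#' @return List with `trajectory`, `bouts`, `indicator`, `schedule`.
#' @export
simulate_pair <- function(spec = sim_spec(),
                          window_mode = c("isi_split", "isi_pooled")) {
  window_mode <- match.arg(window_mode)
  schedule <- build_schedule(round(spec$onset_s * spec$arena$fps),
                             spec$arena$fps, spec$led, window_mode,
                             n_frames = spec$arena$n_frames)
  dyad <- simulate_dyad(spec)
  bouts <- simulate_bouts(spec, schedule, seed = spec$seed + 500013L)
  ind <- simulate_led_indicator(schedule, spec$arena$n_frames)
  list(trajectory = dyad, bouts = bouts, indicator = ind,
       schedule = schedule)
}

#' Simulate a cohort of pairs
#'
#' @param n_pairs Number of tester/target pairs.
#' @param spec Base [sim_spec()]; pair i uses seed `spec$seed + i`.
#' @param genotype Genotype label applied to all pairs.
#' @param window_mode Passed to [simulate_pair()].
#' @return List of pair lists suitable for [run_cohort()].
#' @export
simulate_cohort <- function(n_pairs, spec = sim_spec(),
                            genotype = "tester",
                            window_mode = c("isi_split", "isi_pooled")) {
  window_mode <- match.arg(window_mode)
  stopifnot(n_pairs >= 1)
  lapply(seq_len(n_pairs), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i
    p <- simulate_pair(sp, window_mode)
    list(trajectory = p$trajectory, bouts = p$bouts,
         indicator = p$indicator,
         pair_id = sprintf("%s_pair%02d", genotype, i),
         genotype = genotype)
  })
}
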