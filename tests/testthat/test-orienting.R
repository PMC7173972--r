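make_static_dyad <- function(tx, ty, th, gx, gy, speed_step = 0.5 / 60,
                             n = 4, fps = 60) {
  # tester drifts along +x so its backward-difference speed is exact;
  # target drifts identically, keeping relative geometry fixed
  drift <- (seq_len(n) - 1) * speed_step
  arena <- arena_config(fps = fps, arena_diameter = 1000, n_frames = n)
  dyad_trajectory(arena,
                  fly_track("tester", tx + drift, rep(ty, n), rep(th, n)),
                  fly_track("target", gx + drift, rep(gy, n), rep(0, n)),
                  validate_bounds = FALSE)
}

test_that("orienting predicate applies the three conditions literally", {
  # ahead, near, moving -> orienting
  d <- make_static_dyad(0, 0, 0, 3, 0)
  expect_true(all(orienting_mask(d)))
  # too far (6 mm > 5 mm)
  d <- make_static_dyad(0, 0, pi / 2, 0, 6)
  expect_false(any(orienting_mask(d)))
  # boundary cases are inclusive for angle and distance
  d <- make_static_dyad(0, 0, 0, 5, 0)                  # exactly 5 mm
  expect_true(all(orienting_mask(d)))
  d <- make_static_dyad(0, 0, pi / 3, 2, 0)             # exactly 60 deg
  expect_true(all(orienting_mask(d)))
  d <- make_static_dyad(0, 0, 70 * pi / 180, 2, 0)      # 70 deg > 60
  expect_false(any(orienting_mask(d)))
  # speed condition is strict: exactly 0.1 mm/s fails, just above passes
  d <- make_static_dyad(0, 0, 0, 3, 0, speed_step = 0.1 / 60)
  expect_false(any(orienting_mask(d)))
  d <- make_static_dyad(0, 0, 0, 3, 0, speed_step = 0.11 / 60)
  expect_true(all(orienting_mask(d)))
})

test_that("coincident centroids satisfy the angle condition with a message", {
  n <- 3
  arena <- arena_config(fps = 60, arena_diameter = 1000, n_frames = n)
  drift <- (seq_len(n) - 1) * 0.5 / 60
  d <- dyad_trajectory(arena,
                       fly_track("tester", drift, rep(0, n), rep(0, n)),
                       fly_track("target", drift, rep(0, n), rep(0, n)),
                       validate_bounds = FALSE)
  expect_message(m <- orienting_mask(d), "coincident")
  expect_true(all(m))
})

test_that("orienting mask equals the brute-force oracle on random dyads", {
  for (seed in 1:5) {
    spec <- sim_spec(seed = seed,
                     arena = arena_config(fps = 60, arena_diameter = 20,
                                          n_frames = 3000))
    dyad <- simulate_dyad(spec)
    expect_identical(orienting_mask(dyad), oracle_orienting(dyad))
  }
})

test_that("mask is invariant under rotation of the whole arena", {
  spec <- sim_spec(seed = 11,
                   arena = arena_config(fps = 60, arena_diameter = 20,
                                        n_frames = 2000))
  dyad <- simulate_dyad(spec)
  m0 <- orienting_mask(dyad)
  for (ang in c(0.7, 2.1, -1.3)) {
    rot <- function(x, y) list(x = x * cos(ang) - y * sin(ang),
                               y = x * sin(ang) + y * cos(ang))
    rt <- rot(dyad$tester$x, dyad$tester$y)
    rg <- rot(dyad$target$x, dyad$target$y)
    d2 <- dyad_trajectory(dyad$arena,
                          fly_track("tester", rt$x, rt$y,
                                    dyad$tester$heading + ang),
                          fly_track("target", rg$x, rg$y,
                                    dyad$target$heading + ang),
                          validate_bounds = FALSE)
    expect_identical(orienting_mask(d2), m0)
  }
})

test_that("bout segmentation keeps 200 ms runs and drops shorter ones", {
  fps <- 60
  # 12 true frames = exactly 200 ms -> kept
  mask <- c(rep(FALSE, 5), rep(TRUE, 12), rep(FALSE, 5))
  b <- segment_orienting_bouts(mask, fps)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start_frame, 5L)
  expect_equal(b$end_frame, 17L)
  # 11 frames (~183 ms) -> discarded
  mask <- c(rep(FALSE, 5), rep(TRUE, 11), rep(FALSE, 5))
  expect_equal(nrow(segment_orienting_bouts(mask, fps)), 0L)
  # runs {5, 20, 12} -> keep {20, 12}
  mask <- c(rep(TRUE, 5), FALSE, rep(TRUE, 20), FALSE, rep(TRUE, 12))
  b <- segment_orienting_bouts(mask, fps)
  expect_equal(b$end_frame - b$start_frame, c(20L, 12L))
})

test_that("raising min_bout never increases bout count; relaxing the
           predicate never decreases orienting time", {
  spec <- sim_spec(seed = 3,
                   arena = arena_config(fps = 60, arena_diameter = 20,
                                        n_frames = 6000))
  dyad <- simulate_dyad(spec)
  counts <- vapply(c(50, 100, 200, 400, 800), function(mb) {
    nrow(segment_orienting_bouts(orienting_mask(dyad), 60,
                                 orienting_params(min_bout = mb)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  total_time <- function(params) {
    b <- segment_orienting_bouts(orienting_mask(dyad, params), 60, params)
    time_orienting(b, 60, dyad$arena$n_frames)$total_s
  }
  t_base <- total_time(orienting_params())
  expect_gte(total_time(orienting_params(max_angle = 90)), t_base)
  expect_gte(total_time(orienting_params(max_dist = 8)), t_base)
  expect_gte(total_time(orienting_params(min_speed = 0.05)), t_base)
})

test_that("per-minute orienting conserves the total and splits boundaries", {
  fps <- 60
  b <- bout_table("orienting", "tester", 0L, 600L,
                  provenance = "filtered")
  t1 <- time_orienting(b, fps, 36000)
  expect_equal(t1$total_s, 10)
  expect_equal(t1$per_minute[1], 10)
  # a bout straddling the first minute boundary splits 0.5 s / 0.5 s
  b <- bout_table("orienting", "tester", 3570L, 3630L,
                  provenance = "filtered")
  t2 <- time_orienting(b, fps, 36000)
  expect_equal(t2$per_minute[1:2], c(0.5, 0.5))
  # random bout sets conserve the total
  set.seed(5)
  for (i in 1:20) {
    df <- random_bout_df(15, 36000, fps, behavior = "orienting")
    bt <- bout_table(df$behavior, df$fly, df$start_frame, df$end_frame,
                     provenance = "filtered")
    tt <- time_orienting(bt, fps, 36000)
    expect_equal(sum(tt$per_minute), tt$total_s, tolerance = 1e-12)
    expect_lte(tt$total_s, 600)
  }
})
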