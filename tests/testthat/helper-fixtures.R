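# shared fixture builders; everything is generated in code at test time

# random bout table of one behavior/fly within n_frames
random_bout_df <- function(n, n_frames, fps, behavior = "lunge",
                           fly = "tester", max_dur_f = 60) {
  s <- sort(sample.int(n_frames - max_dur_f, n))
  d <- sample.int(max_dur_f, n, replace = TRUE)
  data.frame(behavior = behavior, fly = fly, start_frame = s,
             end_frame = pmin(s + d, n_frames), stringsAsFactors = FALSE)
}

# a tiny valid trajectory CSV on disk; returns the path
write_traj_csv <- function(n_frames = 5, fps = 60, dir = tempdir()) {
  path <- tempfile("traj", tmpdir = dir, fileext = ".csv")
  fr <- seq_len(n_frames) - 1L
  df <- rbind(
    data.frame(frame = fr, role = "tester", x_mm = fr * 0.1, y_mm = 0,
               heading_rad = 0),
    data.frame(frame = fr, role = "target", x_mm = 3, y_mm = 0.5,
               heading_rad = pi / 2))
  write.csv(df, path, row.names = FALSE)
  path
}

# brute-force per-frame orienting predicate, coded independently of the
# package (dot-product angle test, explicit loop)
oracle_orienting <- function(dyad, max_angle = 60, max_dist = 5,
                             min_speed = 0.1) {
  n <- dyad$arena$n_frames
  fps <- dyad$arena$fps
  out <- logical(n)
  for (t in seq_len(n)) {
    tprev <- if (t == 1) min(2, n) else t
    if (n == 1) sp <- 0
    else {
      i <- if (t == 1) 2 else t
      sp <- fps * sqrt((dyad$tester$x[i] - dyad$tester$x[i - 1])^2 +
                       (dyad$tester$y[i] - dyad$tester$y[i - 1])^2)
    }
    dx <- dyad$target$x[t] - dyad$tester$x[t]
    dy <- dyad$target$y[t] - dyad$tester$y[t]
    d <- sqrt(dx^2 + dy^2)
    if (d == 0) {
      ang_ok <- TRUE
    } else {
      hx <- cos(dyad$tester$heading[t]); hy <- sin(dyad$tester$heading[t])
      cosang <- (hx * dx + hy * dy) / d
      cosang <- max(-1, min(1, cosang))
      ang_ok <- acos(cosang) <= max_angle * pi / 180 + 1e-12
    }
    out[t] <- ang_ok && d <= max_dist && sp > min_speed
  }
  out
}

# exact signed-rank two-sided p by explicit enumeration of all 2^n sign
# assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# exact Mann-Whitney two-sided p by enumeration of all assignments of the
# pooled values into the two groups
enum_mann_whitney_p <- function(a, b) {
  n <- length(a); N <- n + length(b)
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(n)])
  combs <- combn(N, n)
  Ws <- colSums(matrix(rk[combs], nrow = n))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Fisher two-sided p by direct enumeration over all tables with the
# observed margins, summing hypergeometric probabilities <= observed
enum_fisher_p <- function(tb) {
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ]); c1 <- sum(tb[, 1])
  if (min(r1, r2, c1, sum(tb[, 2])) == 0) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(ks, function(k)
    choose(r1, k) * choose(r2, c1 - k) / choose(r1 + r2, c1), numeric(1))
  p_obs <- pr[ks == tb[1, 1]]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# hand-assembled window summary for responder tests
responder_summary <- function(cases) {
  do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    data.frame(pair_id = sprintf("f%02d", i), genotype = "g",
               fly = "tester", behavior = cases$behavior[i],
               window = 1:3,
               rate = c(cases$w1[i], cases$w2[i], cases$w3[i]),
               stringsAsFactors = FALSE)
  }))
}
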