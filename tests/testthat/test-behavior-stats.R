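test_that("Kruskal-Wallis reproduces the hand-ranked H and handles
           degeneracy", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # ranks 1..6, group means 1.5/3.5/5.5: H = 12/(6*7)*sum(n_i R_i^2) - 3*7
  expect_equal(r$statistic, 12 / 42 * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2)
               - 21, tolerance = 1e-12)
  expect_equal(r$statistic, 4.5714, tolerance = 1e-4)

  sym <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_raw, 1)

  deg <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_raw, 1)
})

test_that("Kruskal-Wallis null rejection rate is near nominal", {
  set.seed(101)
  rej <- mean(replicate(400, {
    g <- split(rnorm(36), rep(1:3, each = 12))
    kruskal_wallis(unname(g))$p_raw < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("signed-rank exact path equals full sign enumeration", {
  r <- wilcoxon_signed_rank((1:6) / 10 + 1)
  expect_equal(r$p_raw, 2 / 64)

  expect_equal(wilcoxon_signed_rank(c(3, 1, 4), c(3, 1, 4))$p_raw, 1)
  expect_true(wilcoxon_signed_rank(c(1, 1), c(1, 1))$degenerate)

  set.seed(13)
  for (n in 2:10) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 1)         # rounding induces ties and zeros
      if (all(d == 0)) d[1] <- 0.3
      r <- wilcoxon_signed_rank(d)
      expect_equal(r$p_raw, enum_signed_rank_p(d), tolerance = 1e-12,
                   info = sprintf("n=%d rep=%d", n, rep))
    }
  }
})

test_that("signed-rank exact path agrees with wilcox.test on untied data", {
  set.seed(14)
  for (n in c(5, 8, 12, 20)) {
    d <- rnorm(n)
    r <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(r$p_raw, ref, tolerance = 1e-12)
  }
})

test_that("signed-rank approximation path is tie-corrected and sane", {
  set.seed(15)
  d <- c(rnorm(30, 0.1), 0.1, 0.1)    # n = 32 > exact bound, with ties
  r <- wilcoxon_signed_rank(d)
  expect_gt(r$p_raw, 0)
  expect_lt(r$p_raw, 1)
  # against the exact path at the same data (approximation quality)
  r_ex <- wilcoxon_signed_rank(d, exact_below_n = 100)
  expect_lt(abs(r$p_raw - r_ex$p_raw), 0.02)
})

test_that("Mann-Whitney exact path equals full permutation enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 0.1)

  set.seed(16)
  for (rep in 1:10) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- rnorm(n); y <- rnorm(m)     # continuous: untied a.s.
    r <- mann_whitney_u(x, y)
    expect_equal(r$p_raw, enum_mann_whitney_p(x, y), tolerance = 1e-12)
    ref <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(r$p_raw, ref, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney tied/large samples use the corrected normal
           approximation", {
  a <- c(1, 2, 2, 3, 5); b <- c(2, 3, 3, 4, 6)
  r <- mann_whitney_u(a, b)
  expect_false(r$degenerate)
  expect_gt(r$p_raw, 0); expect_lt(r$p_raw, 1)
  # identical multisets give U = nm/2 and p = 1
  same <- mann_whitney_u(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p_raw, 1)
  # all values identical -> zero variance -> degenerate
  expect_true(mann_whitney_u(c(2, 2), c(2, 2, 2))$degenerate)
})

test_that("Fisher's exact test matches enumeration and fisher.test on
           small tables", {
  r <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$p_raw, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_raw, 1)
  expect_true(fisher_exact(matrix(c(0, 0, 3, 4), 2))$degenerate)

  set.seed(17)
  for (rep in 1:30) {
    tb <- matrix(rpois(4, 4), 2)
    r <- fisher_exact(tb)
    expect_equal(r$p_raw, enum_fisher_p(tb), tolerance = 1e-12)
    if (min(rowSums(tb), colSums(tb)) > 0)
      expect_equal(r$p_raw, fisher.test(tb)$p.value, tolerance = 1e-9)
    # invariance under transposition
    expect_equal(fisher_exact(t(tb))$p_raw, r$p_raw, tolerance = 1e-12)
  }
})

test_that("Bonferroni correction is capped, monotone, and identity at
           m = 1", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroni(p, 4)) >= 0))
  expect_true(all(bonferroni(p, 7) <= 1))
})

test_that("stat_result flags marginal results per the parenthesis rule", {
  r <- stat_result("demo", 1, p_raw = 0.03, m = 3)
  expect_equal(r$p_corrected, 0.09)
  expect_false(r$significant)
  expect_true(r$marginal)
  r2 <- stat_result("demo", 1, p_raw = 0.01, m = 3)
  expect_true(r2$significant)
  expect_false(r2$marginal)
})

test_that("the comparison suite gates post-hoc tests on the omnibus", {
  # flat data: omnibus far from significant -> omnibus row only
  set.seed(18)
  flat <- do.call(rbind, lapply(1:8, function(i)
    data.frame(pair_id = paste0("f", i), genotype = "g", fly = "tester",
               behavior = "lunge", window = 1:3,
               rate = rnorm(3, 5, 0.1))))
  rep1 <- window_comparison_suite(flat, "within_windows", "lunge")
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$test, "kruskal_wallis")

  # strong window-2 effect -> 3 post-hoc rows, m = 3 recorded
  eff <- flat
  eff$rate[eff$window == 2] <- eff$rate[eff$window == 2] * 5
  rep2 <- window_comparison_suite(eff, "within_windows", "lunge")
  expect_equal(sum(rep2$test == "wilcoxon_signed_rank"), 3L)
  expect_true(all(rep2$m[rep2$test == "wilcoxon_signed_rank"] == 3L))
  expect_true(rep2$significant[rep2$comparison %in% "window 2 vs 1"])
})

test_that("genotype comparisons run tester vs each control with m = k-1", {
  set.seed(19)
  mk <- function(g, shift) do.call(rbind, lapply(1:10, function(i)
    data.frame(pair_id = paste0(g, i), genotype = g, fly = "tester",
               behavior = "lunge", window = 2,
               rate = rnorm(1, 5 + shift, 0.5))))
  summ <- rbind(mk("tester", 4), mk("ctrl1", 0), mk("ctrl2", 0))
  rep <- window_comparison_suite(summ, "between_genotypes", "lunge",
                                 window = 2, tester_genotype = "tester")
  ph <- rep[rep$test == "mann_whitney_u", ]
  expect_equal(nrow(ph), 2L)
  expect_true(all(ph$m == 2L))
  expect_true(all(grepl("^tester vs ctrl", ph$comparison)))
})

test_that("unpaired data sent to the paired path is a design error", {
  summ <- data.frame(pair_id = c("a", "a", "a", "b", "b"),
                     genotype = "g", fly = "tester", behavior = "lunge",
                     window = c(1, 2, 3, 1, 2), rate = 1:5)
  expect_error(window_comparison_suite(summ, "within_windows", "lunge"),
               "paired")
  one <- data.frame(pair_id = "a", genotype = "g", fly = "tester",
                    behavior = "lunge", window = 2, rate = 1)
  expect_error(window_comparison_suite(one, "between_genotypes", "lunge"),
               "two genotypes")
})

test_that("responder rules classify the three branches correctly", {
  cases <- data.frame(
    behavior = c(rep("lunge", 6), rep("wing_extension", 6)),
    w1 = c(0,   2, 2, 0, 1,   0,    0,   2, 2, 0, 0.2, 0),
    w2 = c(1.5, 2.9, 3.5, 0.9, 1.6, 0.5, 0.6, 2.9, 3.5, 0.4, 0.35, 0.2),
    w3 = c(0,   2, 2, 0, 1,   0,    0,   2, 2, 0, 0.2, 0),
    expected = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE,
                 TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  for (bh in c("lunge", "wing_extension")) {
    sub <- cases[cases$behavior == bh, ]
    got <- classify_responders(responder_summary(sub), bh)
    expect_equal(got$responder, sub$expected, info = bh)
  }
})

test_that("responder status is monotone in the window-2 rate", {
  for (w1 in c(0, 0.5, 2)) {
    resp <- vapply(seq(0, 8, by = 0.25), function(w2) {
      s <- responder_summary(data.frame(behavior = "lunge", w1 = w1,
                                        w2 = w2, w3 = w1))
      classify_responders(s, "lunge")$responder
    }, logical(1))
    expect_true(all(diff(resp) >= 0))   # never flips back to FALSE
  }
})

test_that("responder classification requires all reference windows", {
  s <- responder_summary(data.frame(behavior = "lunge", w1 = 0, w2 = 2,
                                    w3 = 0))
  s <- s[s$window != 3, ]
  expect_error(classify_responders(s, "lunge"), "missing window")
})

test_that("t-test wrapper returns a coherent stat_result", {
  set.seed(20)
  r <- cell_count_ttest(rnorm(10, 20, 2), rnorm(10, 12, 2))
  expect_s3_class(r, "stat_result")
  expect_lt(r$p_raw, 0.01)
})
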