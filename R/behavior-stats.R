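#' Container for a single test result
#'
#' Every test in the package returns a `stat_result` carrying the raw and
#' Bonferroni-corrected p-value, the number of comparisons `m` used for the
#' correction (recorded for auditability), a significance flag at the
#' corrected level, and a `marginal` flag for the "parenthesis rule":
#' raw p below alpha but corrected p at or above it.
#'
#' @param test Test name.
#' @param statistic Test statistic.
#' @param p_raw Uncorrected two-sided p-value.
#' @param m Number of comparisons in the Bonferroni family.
#' @param comparison Optional label of what was compared.
#' @param degenerate TRUE when the data admitted no real test (e.g. all
#'   values tied); such results carry p = 1.
#' @param alpha Significance level. Default 0.05.
#'
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, p_raw, m = 1L, comparison = NA,
                        degenerate = FALSE, alpha = 0.05) {
  stopifnot(p_raw >= 0, p_raw <= 1, m >= 1)
  p_corrected <- bonferroni(p_raw, m)
  significant <- p_corrected < alpha
  structure(list(test = test, comparison = comparison,
                 statistic = statistic, p_raw = p_raw, m = as.integer(m),
                 p_corrected = p_corrected, significant = significant,
                 marginal = !significant && p_raw < alpha,
                 degenerate = degenerate, alpha = alpha),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  ptxt <- if (x$marginal) sprintf("(p = %.4g)", x$p_raw)
          else sprintf("p = %.4g", x$p_corrected)
  cat(sprintf("%s%s: statistic = %.4g, %s [raw %.4g, m = %d]%s%s\n",
              x$test,
              if (!is.na(x$comparison)) paste0(" [", x$comparison, "]")
              else "",
              x$statistic, ptxt, x$p_raw, x$m,
              if (x$significant) " *" else "",
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

as_report_row <- function(x) {
  data.frame(test = x$test, comparison = as.character(x$comparison),
             statistic = x$statistic, p_raw = x$p_raw, m = x$m,
             p_corrected = x$p_corrected, significant = x$significant,
             marginal = x$marginal, degenerate = x$degenerate,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' @param p_raw Raw p-value(s).
#' @param m Number of comparisons in the family.
#' @return `min(1, m * p_raw)`, elementwise.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1, all(p_raw >= 0), all(p_raw <= 1))
  pmin(1, m * p_raw)
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic against a chi-squared distribution with
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]). Used
#' as the gate before any post-hoc comparison. If every value in every
#' group is identical the statistic is undefined under the tie
#' correction; the result is degenerate with p = 1.
#'
#' @param groups List of two or more numeric vectors.
#' @param ... Passed to [stat_result()].
#' @return A [stat_result()].
#' @export
kruskal_wallis <- function(groups, ...) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(stat_result("kruskal_wallis", statistic = 0, p_raw = 1,
                       degenerate = TRUE, ...))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(values, g)
  stat_result("kruskal_wallis", statistic = unname(kt$statistic),
              p_raw = kt$p.value, ...)
}

# exact null distribution of the positive-rank sum W for given |d| ranks
# (possibly tied, i.e. half-integer): probability vector over 2*W = 0..sum
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  maxw <- sum(r2)
  f <- numeric(maxw + 1L)
  f[1L] <- 1
  for (r in r2) {
    g <- 0.5 * f
    g[(r + 1L):(maxw + 1L)] <- g[(r + 1L):(maxw + 1L)] +
      0.5 * f[seq_len(maxw + 1L - r)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided paired signed-rank test as used post hoc between stimulation
#' windows. Zero differences are dropped before ranking; ties in |d| get
#' average ranks. When the effective n is below `exact_below_n` the p-value
#' is exact, from the full null distribution over all 2^n sign
#' assignments (computed by convolution, valid with tied ranks); otherwise
#' a tie-corrected normal approximation without continuity correction is
#' used. The two-sided p is twice the smaller tail (capped at 1).
#'
#' @param paired_a,paired_b Equal-length numeric vectors; the test is on
#'   `paired_a - paired_b`. `paired_b` may be omitted to test differences
#'   directly.
#' @param exact_below_n Use the exact path when the number of nonzero
#'   differences is below this. Default 26.
#' @param ... Passed to [stat_result()].
#'
#' @return A [stat_result()] with statistic W = sum of positive ranks.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b = NULL,
                                 exact_below_n = 26L, ...) {
  d <- if (is.null(paired_b)) paired_a else {
    stopifnot(length(paired_a) == length(paired_b))
    paired_a - paired_b
  }
  stopifnot(length(d) >= 1)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(stat_result("wilcoxon_signed_rank", statistic = 0, p_raw = 1,
                       degenerate = TRUE, ...))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n < exact_below_n) {
    f <- signed_rank_null(rk)
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(f[seq_len(w2 + 1L)])
    p_hi <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    if (sig2 <= 0)
      return(stat_result("wilcoxon_signed_rank", statistic = W, p_raw = 1,
                         degenerate = TRUE, ...))
    p <- 2 * stats::pnorm(-abs(W - mu) / sqrt(sig2))
    p <- min(1, p)
  }
  stat_result("wilcoxon_signed_rank", statistic = W, p_raw = p, ...)
}

# exact null distribution of the rank sum of the first sample: number of
# n-subsets of ranks 1..N with each possible sum
rank_sum_null <- function(n, N) {
  maxs <- sum((N - n + 1):N)
  # dp[j+1, s+1] = number of ways to pick j of the ranks considered so far
  # with sum s
  dp <- matrix(0, nrow = n + 1L, ncol = maxs + 1L)
  dp[1L, 1L] <- 1
  for (r in seq_len(N)) {
    for (j in rev(seq_len(min(r, n)))) {
      cols <- (r + 1L):(maxs + 1L)
      dp[j + 1L, cols] <- dp[j + 1L, cols] + dp[j, cols - r]
    }
  }
  dp[n + 1L, ]
}

#' Mann-Whitney U test (rank-sum)
#'
#' Two-sided unpaired rank-sum test as used between genotypes. With small
#' untied samples (both below `exact_below_n`, no tied values) the p-value
#' is exact from the full permutation distribution of the rank sum;
#' otherwise a tie-corrected normal approximation without continuity
#' correction is used. The two-sided p is twice the smaller tail (capped
#' at 1).
#'
#' @param a,b Numeric samples.
#' @param exact_below_n Exact-path size bound per group. Default 20.
#' @param ... Passed to [stat_result()].
#'
#' @return A [stat_result()] with statistic U (of sample `a`).
#' @export
mann_whitney_u <- function(a, b, exact_below_n = 20L, ...) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n <- length(a); m <- length(b); N <- n + m
  rk <- rank(c(a, b))
  W <- sum(rk[seq_len(n)])
  U <- W - n * (n + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && n < exact_below_n && m < exact_below_n) {
    cnt <- rank_sum_null(n, N)
    tot <- sum(cnt)
    w <- as.integer(round(W))
    p_lo <- sum(cnt[seq_len(w + 1L)]) / tot
    p_hi <- sum(cnt[(w + 1L):length(cnt)]) / tot
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    tt <- table(rk)
    sig2 <- n * m / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sig2 <= 0)
      return(stat_result("mann_whitney_u", statistic = U, p_raw = 1,
                         degenerate = TRUE, ...))
    p <- 2 * stats::pnorm(-abs(U - n * m / 2) / sqrt(sig2))
    p <- min(1, p)
  }
  stat_result("mann_whitney_u", statistic = U, p_raw = p, ...)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value obtained by summing, over the hypergeometric null
#' with the observed margins, the probabilities of all tables at most as
#' probable as the observed one. A zero margin makes the table
#' deterministic; the result is degenerate with p = 1.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param ... Passed to [stat_result()].
#' @return A [stat_result()]; the statistic is the sample odds ratio.
#' @export
fisher_exact <- function(table, ...) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == c(2L, 2L)), all(tb >= 0),
            all(tb == round(tb)))
  r1 <- sum(tb[1, ]); r2 <- sum(tb[2, ])
  c1 <- sum(tb[, 1]); c2 <- sum(tb[, 2])
  orat <- (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1])
  if (min(r1, r2, c1, c2) == 0L)
    return(stat_result("fisher_exact", statistic = orat, p_raw = 1,
                       degenerate = TRUE, ...))
  supp <- max(0L, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(tb[1, 1], r1, r2, c1)
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  stat_result("fisher_exact", statistic = orat, p_raw = p, ...)
}

#' Gated window/genotype comparison suite
#'
#' Runs the full testing scheme on a window summary: a Kruskal-Wallis
#' omnibus test over windows (within a genotype) or over genotypes (within
#' a window), followed — only when the omnibus raw p is below `alpha` —
#' by post-hoc tests with Bonferroni correction over the comparisons
#' actually performed. Within-fly window comparisons are paired
#' (signed-rank, paired by `pair_id`); genotype comparisons are unpaired
#' (Mann-Whitney U, tester genotype vs each control). The `m` used is
#' recorded in every row.
#'
#' @param summary A `window_summary` data frame (columns `pair_id`,
#'   `genotype`, `behavior`, `window`, `rate`).
#' @param design `"within_windows"` or `"between_genotypes"`.
#' @param behavior Behavior to analyze.
#' @param windows Windows entering the omnibus for `within_windows`
#'   (default 1:3, matching the standard analysis); all pairs among them
#'   are tested post hoc.
#' @param genotype For `within_windows`: restrict to one genotype
#'   (required when several are present).
#' @param window For `between_genotypes`: the window whose rates are
#'   compared (default 2, the stimulation window).
#' @param tester_genotype For `between_genotypes`: the genotype compared
#'   against each of the others (default: first level present).
#' @param alpha Significance level for the gate and flags.
#'
#' @return A `stat_report` data frame: one omnibus row plus any post-hoc
#'   rows, columns `test,comparison,statistic,p_raw,m,p_corrected,
#'   significant,marginal,degenerate`.
#' @export
window_comparison_suite <- function(summary,
                                    design = c("within_windows",
                                               "between_genotypes"),
                                    behavior, windows = 1:3,
                                    genotype = NULL, window = 2L,
                                    tester_genotype = NULL,
                                    alpha = 0.05) {
  design <- match.arg(design)
  df <- as.data.frame(summary)
  df <- df[df$behavior == behavior, , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no rows for behavior '", behavior, "'", call. = FALSE)
  rows <- list()
  if (design == "within_windows") {
    if (!is.null(genotype)) df <- df[df$genotype == genotype, , drop = FALSE]
    if (length(unique(df$genotype)) > 1L)
      stop("within-window comparisons are paired per fly; restrict to one ",
           "genotype via the genotype argument", call. = FALSE)
    wide <- lapply(windows, function(w) {
      sub <- df[df$window == w, , drop = FALSE]
      stats::setNames(sub$rate, sub$pair_id)
    })
    ids <- Reduce(intersect, lapply(wide, names))
    if (length(ids) < length(unique(df$pair_id)) ||
        any(lengths(wide) != length(ids)))
      stop("unpaired data sent to the paired path: every fly must have a ",
           "rate in each of windows ", paste(windows, collapse = ", "),
           call. = FALSE)
    groups <- lapply(wide, function(v) unname(v[ids]))
    omni <- kruskal_wallis(groups,
                           comparison = paste0("windows ",
                                               paste(windows,
                                                     collapse = ",")),
                           alpha = alpha)
    rows[[1]] <- omni
    if (!omni$degenerate && omni$p_raw < alpha) {
      pairs <- utils::combn(seq_along(windows), 2L)
      m <- ncol(pairs)
      for (j in seq_len(m)) {
        i1 <- pairs[1, j]; i2 <- pairs[2, j]
        rows[[length(rows) + 1L]] <- wilcoxon_signed_rank(
          groups[[i2]], groups[[i1]], m = m,
          comparison = sprintf("window %d vs %d", windows[i2],
                               windows[i1]),
          alpha = alpha)
      }
    }
  } else {
    df <- df[df$window == window, , drop = FALSE]
    genos <- unique(df$genotype)
    if (length(genos) < 2L)
      stop("between-genotype comparisons need at least two genotypes",
           call. = FALSE)
    if (is.null(tester_genotype)) tester_genotype <- genos[1]
    if (!tester_genotype %in% genos)
      stop("tester genotype '", tester_genotype, "' not present",
           call. = FALSE)
    groups <- split(df$rate, df$genotype)
    omni <- kruskal_wallis(unname(groups),
                           comparison = sprintf("genotypes @ window %d",
                                                window),
                           alpha = alpha)
    rows[[1]] <- omni
    controls <- setdiff(genos, tester_genotype)
    if (!omni$degenerate && omni$p_raw < alpha) {
      m <- length(controls)
      for (ctrl in controls) {
        rows[[length(rows) + 1L]] <- mann_whitney_u(
          groups[[tester_genotype]], groups[[ctrl]], m = m,
          comparison = sprintf("%s vs %s @ window %d", tester_genotype,
                               ctrl, window),
          alpha = alpha)
      }
    }
  }
  report <- do.call(rbind, lapply(rows, as_report_row))
  rownames(report) <- NULL
  structure(report, behavior = behavior, design = design,
            class = c("stat_report", "data.frame"))
}

#' @export
print.stat_report <- function(x, ...) {
  cat("stat_report:", attr(x, "design") %||% "", "for",
      attr(x, "behavior") %||% "", "\n")
  print.data.frame(cbind(x[, c("test", "comparison")],
                         round(x[, c("statistic", "p_raw",
                                     "p_corrected")], 4),
                         x[, c("m", "significant", "marginal",
                               "degenerate")]))
  invisible(x)
}

#' Responder classification rules
#'
#' A tester is classified as having increased a behavior in the
#' stimulation window (window 2) relative to the reference windows 1 and
#' 3 when either (1) its rate increased more than `relative_increase`
#' (50%) over a nonzero reference rate, or (2) no behavior at all occurred
#' in either reference window and the window-2 rate exceeds the behavior's
#' floor: more than 1 lunge/min, or more than 500 ms/min of wing
#' extension.
#'
#' @param relative_increase Required fractional increase over a nonzero
#'   reference. Default 0.5.
#' @param lunge_floor Window-2 floor for lunges when both references are
#'   zero, bouts/min. Default 1.
#' @param wing_floor Window-2 floor for wing extension when both
#'   references are zero, s/min. Default 0.5.
#' @param reference_windows Reference window ids. Default `c(1, 3)`.
#'
#' @return An object of class `responder_rules`.
#' @export
responder_rules <- function(relative_increase = 0.5, lunge_floor = 1,
                            wing_floor = 0.5, reference_windows = c(1, 3)) {
  stopifnot(relative_increase > 0, lunge_floor > 0, wing_floor > 0)
  structure(list(relative_increase = relative_increase,
                 lunge_floor = lunge_floor, wing_floor = wing_floor,
                 reference_windows = reference_windows),
            class = "responder_rules")
}

#' Classify per-fly responders
#'
#' Applies [responder_rules()] per fly to a window summary. The relative
#' rule is a disjunction over the reference windows: the fly responds if
#' window 2 exceeds 1.5x either reference, provided that reference is
#' strictly positive (a zero reference is handled only by the floor rule,
#' which requires both references to be zero).
#'
#' @param summary A `window_summary` data frame.
#' @param behavior `"lunge"` or `"wing_extension"` (the floor differs).
#' @param rules A [responder_rules()].
#'
#' @return Data frame with `pair_id`, `genotype`, `responder` (logical)
#'   and `rule` (`"relative"`, `"floor"` or `NA`).
#' @export
classify_responders <- function(summary, behavior,
                                rules = responder_rules()) {
  stopifnot(behavior %in% c("lunge", "wing_extension"))
  df <- as.data.frame(summary)
  df <- df[df$behavior == behavior, , drop = FALSE]
  floor_val <- if (behavior == "lunge") rules$lunge_floor else
    rules$wing_floor
  refs <- rules$reference_windows
  ids <- unique(df$pair_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$pair_id == id, , drop = FALSE]
    need <- c(2, refs)
    if (!all(need %in% sub$window))
      stop("fly '", id, "' is missing window(s) ",
           paste(setdiff(need, sub$window), collapse = ", "),
           call. = FALSE)
    w2 <- sub$rate[sub$window == 2][1]
    ref_rates <- vapply(refs, function(w) sub$rate[sub$window == w][1],
                        numeric(1))
    relative <- any(ref_rates > 0 &
                      w2 > (1 + rules$relative_increase) * ref_rates)
    floored <- all(ref_rates == 0) && w2 > floor_val
    data.frame(pair_id = id, genotype = sub$genotype[1],
               responder = relative || floored,
               rule = if (relative) "relative" else if (floored) "floor"
                      else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-sample t-test wrapper for cell-count comparisons
#'
#' Parametric comparison used for anatomical cell counts (where normality
#' is a reasonable assumption, unlike the zero-inflated behavior rates).
#' Thin wrapper over [stats::t.test()] returning a [stat_result()].
#'
#' @param a,b Numeric count samples.
#' @param ... Passed to [stat_result()].
#' @return A [stat_result()].
#' @export
cell_count_ttest <- function(a, b, ...) {
  tt <- stats::t.test(a, b)
  stat_result("t_test", statistic = unname(tt$statistic),
              p_raw = tt$p.value, ...)
}
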