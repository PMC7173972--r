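#' Default analysis configuration
#'
#' One nested list drives every stage: arena geometry, LED paradigm and
#' window mode, orienting predicate parameters, bout duration filters,
#' indicator threshold, statistics level and responder rules. YAML config
#' files ([read_config()]) are merged over these defaults.
#'
#' @return Named list of class `flydyad_config`.
#' @export
default_config <- function() {
  structure(list(
    arena = list(fps = 60, arena_diameter = 20),
    paradigm = list(pre_s = 60, n_blocks = 3, on_s = 60, isi_s = 120,
                    led_frequency_hz = NULL,
                    window_mode = "isi_split"),
    orienting = list(max_angle = 60, max_dist = 5, min_speed = 0.1,
                     min_bout = 200, smooth_window = 1),
    filters = list(lunge = 50, headbutt = 50, wing_extension = 100),
    led = list(threshold = 1),
    matching = list(min_overlap = 0),
    stats = list(alpha = 0.05),
    responders = list(relative_increase = 0.5, lunge_floor = 1,
                      wing_floor = 0.5)),
    class = "flydyad_config")
}

#' Read a YAML analysis configuration
#'
#' Values present in the file override the matching [default_config()]
#' entries; everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A `flydyad_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), user)
  structure(cfg, class = "flydyad_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

# behavior -> pooling mode used throughout the analysis
behavior_mode <- function(behavior) {
  if (behavior %in% c("wing_extension", "orienting")) "duration"
  else "count"
}

#' Analyze one tester/target pair
#'
#' Runs the full single-pair chain: derives tester speed, computes the
#' orienting mask and duration-filtered orienting bouts, duration-filters
#' the classifier bout table, aligns everything on the LED onset
#' (detected from an indicator trace, or given directly) and pools each
#' behavior into the analysis windows as per-minute rates. Pairs listed
#' in `exclusions` (manually flagged assays — a killed fly, a stuck wing,
#' lost identity) are skipped with a message.
#'
#' @param trajectory A [dyad_trajectory()].
#' @param bouts A [bout_table()] of classifier output (provenance
#'   `"raw"`; an already-filtered table is used as is).
#' @param config A `flydyad_config` list.
#' @param pair_id,genotype Identifiers carried into the summary.
#' @param indicator Optional per-frame LED indicator trace for onset
#'   detection.
#' @param onset_frame LED onset (0-based) when no indicator is supplied;
#'   defaults to `pre_s * fps` (recording and LED program started
#'   together).
#' @param exclusions Character vector of excluded pair ids.
#'
#' @return A `window_summary` data frame (`pair_id, genotype, fly,
#'   behavior, window, minutes, rate, window_mode`), or `NULL` for an
#'   excluded pair.
#' @export
run_pair <- function(trajectory, bouts, config = default_config(),
                     pair_id = "pair1", genotype = "genotype1",
                     indicator = NULL, onset_frame = NULL,
                     exclusions = character()) {
  if (pair_id %in% exclusions) {
    message("run_pair: pair '", pair_id,
            "' is on the exclusion list; skipped")
    return(NULL)
  }
  stopifnot(inherits(trajectory, "dyad_trajectory"),
            inherits(bouts, "bout_table"))
  fps <- trajectory$arena$fps
  n_frames <- trajectory$arena$n_frames
  if (fps != config$arena$fps)
    stop("trajectory fps (", fps, ") differs from config fps (",
         config$arena$fps, ")", call. = FALSE)
  if (nrow(bouts) && max(bouts$end_frame) > n_frames)
    stop("bout table extends past the trajectory (", n_frames,
         " frames)", call. = FALSE)
  pdgm <- paradigm(config$paradigm$pre_s, config$paradigm$n_blocks,
                   config$paradigm$on_s, config$paradigm$isi_s,
                   config$paradigm$led_frequency_hz)
  onset <- if (!is.null(indicator)) {
    detect_led_onset(indicator, config$led$threshold)
  } else onset_frame %||% round(pdgm$pre_s * fps)
  schedule <- build_schedule(onset, fps, pdgm,
                             config$paradigm$window_mode,
                             n_frames = n_frames)
  oparams <- orienting_params(config$orienting$max_angle,
                              config$orienting$max_dist,
                              config$orienting$min_speed,
                              config$orienting$min_bout)
  mask <- orienting_mask(trajectory, oparams,
                         smooth_window = config$orienting$smooth_window)
  obouts <- segment_orienting_bouts(mask, fps, oparams)
  fparams <- do.call(bout_filter_params, config$filters)
  fbouts <- if (bout_provenance(bouts) == "raw")
    filter_bouts(bouts, fparams, fps) else bouts
  message("run_pair [", pair_id, "]: ", nrow(bouts), " raw bouts, ",
          nrow(fbouts), " after duration filtering; ",
          nrow(obouts), " orienting bouts")
  rows <- list()
  pooled <- pool_windows(obouts, schedule, "orienting", "duration",
                         fly = "tester")
  rows[[1]] <- cbind(behavior = "orienting", fly = "tester", pooled)
  for (bh in unique(fbouts$behavior)) {
    for (fl in unique(fbouts$fly[fbouts$behavior == bh])) {
      pooled <- pool_windows(fbouts, schedule, bh, behavior_mode(bh),
                             fly = fl)
      rows[[length(rows) + 1L]] <- cbind(behavior = bh, fly = fl, pooled)
    }
  }
  out <- do.call(rbind, rows)
  out <- data.frame(pair_id = pair_id, genotype = genotype,
                    fly = out$fly, behavior = out$behavior,
                    window = out$window, minutes = out$minutes,
                    rate = out$rate,
                    window_mode = schedule$window_mode,
                    stringsAsFactors = FALSE)
  structure(out, class = c("window_summary", "data.frame"))
}

#' Analyze a cohort of pairs
#'
#' Assembles per-pair window summaries, then for every behavior runs the
#' gated within-genotype window comparison (Kruskal-Wallis over windows
#' 1-3, paired signed-rank post hoc) and, when at least two genotypes are
#' present, the between-genotype comparison at the stimulation window
#' (Kruskal-Wallis, Mann-Whitney post hoc vs each control). Lunge and
#' wing-extension responders are classified per fly. Outputs carry the
#' window mode and a hash of the configuration for provenance.
#'
#' @param pairs List of pair lists: each with `trajectory`, `bouts`,
#'   `pair_id`, `genotype` and optionally `indicator`/`onset_frame`.
#' @param config A `flydyad_config` list.
#' @param exclusions Character vector of excluded pair ids.
#' @param tester_genotype Genotype treated as the tested line in genotype
#'   comparisons (default: the first pair's genotype).
#' @param genotype_window Window compared across genotypes. Default 2.
#'
#' @return An object of class `cohort_analysis`: list with `summary`,
#'   `report` (stat_report rows across behaviors), `responders`,
#'   `window_mode`, `config_hash`, `n_pairs`.
#' @export
run_cohort <- function(pairs, config = default_config(),
                       exclusions = character(), tester_genotype = NULL,
                       genotype_window = 2L) {
  if (length(pairs) == 0L) stop("empty cohort", call. = FALSE)
  summaries <- list()
  for (p in pairs) {
    s <- run_pair(p$trajectory, p$bouts, config, p$pair_id, p$genotype,
                  indicator = p$indicator,
                  onset_frame = p$onset_frame, exclusions = exclusions)
    if (!is.null(s)) summaries[[length(summaries) + 1L]] <- s
  }
  if (length(summaries) == 0L)
    stop("all pairs excluded; nothing to analyze", call. = FALSE)
  summary <- do.call(rbind, summaries)
  class(summary) <- c("window_summary", "data.frame")
  alpha <- config$stats$alpha
  genos <- unique(summary$genotype)
  if (is.null(tester_genotype)) tester_genotype <- genos[1]
  reports <- list()
  for (bh in unique(summary$behavior)) {
    for (g in genos) {
      rep_w <- window_comparison_suite(summary, "within_windows", bh,
                                       genotype = g, alpha = alpha)
      rep_w$comparison <- paste0(g, ": ", rep_w$comparison)
      rep_w$behavior <- bh
      reports[[length(reports) + 1L]] <- rep_w
    }
    if (length(genos) >= 2L) {
      rep_g <- window_comparison_suite(summary, "between_genotypes", bh,
                                       window = genotype_window,
                                       tester_genotype = tester_genotype,
                                       alpha = alpha)
      rep_g$behavior <- bh
      reports[[length(reports) + 1L]] <- rep_g
    }
  }
  report <- do.call(rbind, lapply(reports, as.data.frame))
  rownames(report) <- NULL
  class(report) <- c("stat_report", "data.frame")
  rrules <- responder_rules(config$responders$relative_increase,
                            config$responders$lunge_floor,
                            config$responders$wing_floor)
  responders <- list()
  for (bh in intersect(c("lunge", "wing_extension"),
                       unique(summary$behavior))) {
    r <- classify_responders(summary, bh, rrules)
    r$behavior <- bh
    responders[[length(responders) + 1L]] <- r
  }
  responders <- if (length(responders)) do.call(rbind, responders)
                else NULL
  structure(list(summary = summary, report = report,
                 responders = responders,
                 window_mode = config$paradigm$window_mode,
                 config_hash = config_hash(config),
                 n_pairs = length(summaries)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("cohort_analysis:", x$n_pairs, "pairs,",
      length(unique(x$summary$genotype)), "genotype(s), window mode '",
      x$window_mode, "'\n", sep = " ")
  sig <- x$report[x$report$significant & x$report$test !=
                    "kruskal_wallis", , drop = FALSE]
  cat("  significant post-hoc comparisons:", nrow(sig), "\n")
  if (nrow(sig))
    for (i in seq_len(nrow(sig)))
      cat(sprintf("    %s | %s: %s (p = %.4g, m = %d)\n",
                  sig$behavior[i], sig$test[i], sig$comparison[i],
                  sig$p_corrected[i], sig$m[i]))
  if (!is.null(x$responders)) {
    agg <- stats::aggregate(responder ~ behavior, data = x$responders,
                            FUN = function(v) sprintf("%d/%d", sum(v),
                                                      length(v)))
    cat("  responders:",
        paste(agg$behavior, agg$responder, collapse = ", "), "\n")
  }
  cat("  config:", x$config_hash, "\n")
  invisible(x)
}

#' Write a cohort analysis to a directory
#'
#' Emits `summary.csv`, `report.csv`, `responders.csv` (when present) and
#' `metadata.json` (window mode, config hash, pair count). Rerunning the
#' same analysis reproduces the files byte for byte.
#'
#' @param x A `cohort_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_results(x$summary, file.path(dir, "summary.csv"))
  write_results(x$report, file.path(dir, "report.csv"))
  if (!is.null(x$responders))
    write_results(x$responders, file.path(dir, "responders.csv"))
  jsonlite::write_json(list(window_mode = x$window_mode,
                            config_hash = x$config_hash,
                            n_pairs = x$n_pairs),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
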