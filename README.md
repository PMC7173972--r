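# flydyad

Trajectory-to-statistics analysis of dyadic social behavior in
*Drosophila* optogenetic assays.

In these experiments a genetically manipulated **tester** fly is paired
with a wild-type **target** fly in a small circular arena while
candidate neurons are photostimulated: after 1 min of pre-stimulation,
three 1-min LED blocks are delivered, each followed by a 2-min
inter-stimulus interval (ISI), for 10 min in total at 60 frames/s.
`flydyad` turns per-frame tracking output and behavior-classifier bout
tables into the statistics such experiments are scored by, and ships a
ground-truth synthetic-data generator so the whole chain is testable
without any video.

## What it computes

**Time orienting.** The behavior-neutral interaction metric: the tester
is *orienting* in frame *t* when

- the target centroid lies within ±60° of the tester's heading,
- the centroid–centroid distance is ≤ 5 mm (about two body lengths), and
- the tester moves faster than 0.1 mm/s (removing standing/grooming
  frames),

with runs shorter than 200 ms discarded as tracking artifacts
(`orienting_mask()`, `segment_orienting_bouts()`, `time_orienting()`).

**Bout post-processing.** Classifier bouts are duration-filtered
(lunges/headbutts < 50 ms and wing extensions < 100 ms are nearly always
false positives) and binned per minute — counts for momentary actions,
seconds for duration-scored ones (`filter_bouts()`, `bin_per_minute()`).

**Window statistics.** Recordings are aligned on the detected indicator-
LED onset and pooled into analysis windows (1 = pre-stimulation,
2 = LED-on, 3/4 = early/late ISI minutes) as per-minute rates
(`detect_led_onset()`, `build_schedule()`, `pool_windows()`). Rates are
compared with a Kruskal–Wallis omnibus gate followed — only when the
omnibus p < 0.05 — by paired Wilcoxon signed-rank tests across windows
or Mann–Whitney U tests across genotypes, Bonferroni-corrected over the
`m` post-hoc comparisons actually performed; raw p-values that lose
significance after correction are flagged `marginal`
(`window_comparison_suite()`). The signed-rank and rank-sum tests use
exact enumeration-equivalent null distributions for small samples (ties
included for the paired test) and tie-corrected normal approximations
otherwise; `fisher_exact()` sums hypergeometric tail probabilities.

**Responders.** A tester has "increased" a behavior under stimulation
when its window-2 rate exceeds 1.5× a nonzero reference rate (window 1
*or* 3), or — when no behavior occurred in either reference window — it
exceeds a floor of 1 lunge/min or 500 ms/min of wing extension
(`classify_responders()`); responder frequencies feed `fisher_exact()`.

**Classifier evaluation.** Bout-level recall `tp / n_true` and precision
`tp / (n_detected + fp)` (the as-printed form, with the conventional
`tp / n_detected` reported alongside) under a configurable
overlap-matching rule (`match_bouts()`, `evaluate_classifier()`).

**Morphometry.** Registered NRRD stacks are mirror-averaged into
bilaterally symmetric mean images and structure volumes are measured by
voxel counting at an intensity threshold (default 800)
(`mirror_average()`, `threshold_volume()`, `read_nrrd()`).

## Worked example

Simulate a 12-pair cohort whose generator elevates window-2 bout rates
(the optogenetic effect), then run the full analysis:

```r
library(flydyad)
spec  <- sim_spec(seed = 7)
pairs <- simulate_cohort(12, spec, genotype = "tester")
res   <- run_cohort(pairs)
print(res)
#> cohort_analysis: 12 pairs, 1 genotype(s), window mode ' isi_split '
#>   significant post-hoc comparisons: 5
#>     lunge | wilcoxon_signed_rank: tester: window 2 vs 1 (p = 0.001465, m = 3)
#>     lunge | wilcoxon_signed_rank: tester: window 3 vs 2 (p = 0.00293, m = 3)
#>     wing_extension | wilcoxon_signed_rank: tester: window 2 vs 1 (p = 0.001465, m = 3)
#>     wing_extension | wilcoxon_signed_rank: tester: window 3 vs 1 (p = 0.00293, m = 3)
#>     wing_extension | wilcoxon_signed_rank: tester: window 3 vs 2 (p = 0.00293, m = 3)
#>   responders: lunge 10/12, wing_extension 10/12
#>   config: 0856463edbee21ab9845c17f2b52dda8
```

The lunge rows of the report show the gate, correction, and marginal
flag at work — window 3 vs 1 is raw-significant but does not survive
Bonferroni over the three post-hoc comparisons:

```r
subset(as.data.frame(res$report), behavior == "lunge")
#>                   test            comparison        p_raw m  p_corrected significant marginal
#> 6       kruskal_wallis tester: windows 1,2,3 4.414085e-06 1 4.414085e-06        TRUE    FALSE
#> 7 wilcoxon_signed_rank tester: window 2 vs 1 4.882812e-04 3 1.464844e-03        TRUE    FALSE
#> 8 wilcoxon_signed_rank tester: window 3 vs 1 3.125000e-02 3 9.375000e-02       FALSE     TRUE
#> 9 wilcoxon_signed_rank tester: window 3 vs 2 9.765625e-04 3 2.929688e-03        TRUE    FALSE
```

The per-window rates are in `res$summary` (one row per pair × behavior
× window, in bouts/min or s/min), responder calls in `res$responders`,
and `write_cohort(res, dir)` writes everything as CSV/JSON with the
window mode and a configuration hash for provenance. Real data enter
through `read_trajectory()` (CSV: `frame,role,x_mm,y_mm,heading_rad`),
`read_bouts()` (`behavior,fly,start_frame,end_frame`) and
`read_config()` (YAML).

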