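#' Match predicted bouts against annotated bouts
#'
#' Bout-level matching between a human-annotated ("true") bout table and a
#' classifier's output for a single behavior and fly. A true bout counts
#' as detected when some predicted bout overlaps it by at least
#' `min_overlap` of the true bout's frames (never less than one frame; the
#' default `min_overlap = 0` means any one-frame overlap suffices, the
#' weakest defensible criterion). A predicted bout is a false positive
#' when it overlaps no true bout by at least one frame. Interval overlap
#' is computed with IRanges.
#'
#' @param true_bouts,pred_bouts [bout_table()]s restricted to one behavior
#'   and one fly each (mixed behaviors are a usage error).
#' @param min_overlap Required overlap as a fraction of the true bout's
#'   frames, in `[0, 1]`.
#'
#' @return An object of class `match_counts`: list with `n_true`,
#'   `n_detected`, `tp`, `fp`.
#' @export
match_bouts <- function(true_bouts, pred_bouts, min_overlap = 0) {
  stopifnot(min_overlap >= 0, min_overlap <= 1)
  for (tb in list(true_bouts, pred_bouts)) {
    if (length(unique(tb$behavior)) > 1L ||
        length(unique(tb$fly)) > 1L)
      stop("match_bouts compares one behavior of one fly at a time; ",
           "split the tables first", call. = FALSE)
  }
  if (nrow(true_bouts) && nrow(pred_bouts) &&
      (true_bouts$behavior[1] != pred_bouts$behavior[1] ||
       true_bouts$fly[1] != pred_bouts$fly[1]))
    stop("true and predicted tables refer to different behavior or fly",
         call. = FALSE)
  n_true <- nrow(true_bouts)
  n_det <- nrow(pred_bouts)
  if (n_true == 0L || n_det == 0L) {
    return(structure(list(n_true = n_true, n_detected = n_det, tp = 0L,
                          fp = n_det),
                     class = "match_counts"))
  }
  # half-open frame intervals -> 1-based closed integer ranges
  tr <- IRanges::IRanges(true_bouts$start_frame + 1L, true_bouts$end_frame)
  pr <- IRanges::IRanges(pred_bouts$start_frame + 1L, pred_bouts$end_frame)
  hits <- IRanges::findOverlaps(tr, pr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ovw <- IRanges::width(IRanges::pintersect(tr[q], pr[s]))
  need <- pmax(1, min_overlap * IRanges::width(tr)[q])
  detected <- unique(q[ovw >= need])
  fp <- n_det - length(unique(s))
  structure(list(n_true = n_true, n_detected = n_det,
                 tp = length(detected), fp = fp),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("match_counts: %d true, %d detected, tp = %d, fp = %d\n",
              x$n_true, x$n_detected, x$tp, x$fp))
  invisible(x)
}

#' Classifier recall
#'
#' Fraction of annotated bouts detected by the classifier:
#' `tp / n_true`.
#'
#' @param counts A [match_bouts()] result.
#' @return Recall in `[0, 1]`, or `NA` (with a warning) when there are no
#'   true bouts.
#' @export
recall <- function(counts) {
  if (counts$n_true == 0L) {
    warning("recall undefined: no true bouts", call. = FALSE)
    return(NA_real_)
  }
  counts$tp / counts$n_true
}

#' Classifier precision
#'
#' By default uses the formula as printed in the evaluation protocol,
#' `tp / (n_detected + fp)`, whose denominator counts false positives on
#' top of all detected bouts and is therefore never larger than the
#' conventional `tp / n_detected` (set `conventional = TRUE` for the
#' latter). Both are reported by [evaluate_classifier()].
#'
#' @param counts A [match_bouts()] result.
#' @param conventional Use `tp / n_detected` instead.
#' @return Precision in `[0, 1]`, or `NA` (with a warning) for an empty
#'   denominator.
#' @export
precision <- function(counts, conventional = FALSE) {
  denom <- if (conventional) counts$n_detected else
    counts$n_detected + counts$fp
  if (denom == 0L) {
    warning("precision undefined: no detected bouts", call. = FALSE)
    return(NA_real_)
  }
  counts$tp / denom
}

#' Evaluate a classifier against annotation, per behavior
#'
#' Splits both tables by behavior (and fly), matches bouts and assembles
#' the standard evaluation report.
#'
#' @param true_bouts,pred_bouts [bout_table()]s.
#' @param min_overlap Passed to [match_bouts()].
#' @return Data frame with columns `behavior,fly,n_true,n_detected,tp,fp,
#'   recall,precision,precision_conventional`.
#' @export
evaluate_classifier <- function(true_bouts, pred_bouts, min_overlap = 0) {
  keys <- unique(rbind(unique(true_bouts[, c("behavior", "fly")]),
                       unique(pred_bouts[, c("behavior", "fly")])))
  out <- lapply(seq_len(nrow(keys)), function(i) {
    bh <- keys$behavior[i]; fl <- keys$fly[i]
    tsub <- true_bouts[true_bouts$behavior == bh & true_bouts$fly == fl, ,
                       drop = FALSE]
    psub <- pred_bouts[pred_bouts$behavior == bh & pred_bouts$fly == fl, ,
                       drop = FALSE]
    cnt <- match_bouts(tsub, psub, min_overlap)
    data.frame(behavior = bh, fly = fl, n_true = cnt$n_true,
               n_detected = cnt$n_detected, tp = cnt$tp, fp = cnt$fp,
               recall = if (cnt$n_true) recall(cnt) else NA_real_,
               precision = if (cnt$n_detected + cnt$fp)
                 precision(cnt) else NA_real_,
               precision_conventional = if (cnt$n_detected)
                 precision(cnt, conventional = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
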