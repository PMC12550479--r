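# Nucleotide-level benchmarking of a predicted MITE annotation against a
# reference annotation: per-base confusion counts and the six derived
# metrics (sensitivity, specificity, accuracy, precision, false positive
# rate, F1).

#' Base-level confusion counts
#'
#' Both interval sets are merged per contig, then every base is classified:
#' TP covered by both, FP by prediction only, FN by reference only, TN by
#' neither. Intervals are 0-based half-open.
#'
#' @param contig_lengths named integer vector of contig lengths.
#' @param predicted,reference `data.frame`s with `contig_id`, `start`,
#'   `end`.
#' @return list with `tp`, `fp`, `tn`, `fn` (base counts).
#' @export
confusion_counts <- function(contig_lengths, predicted, reference) {
  check <- function(x, label) {
    if (nrow(x) == 0L) return()
    bad <- !(x$contig_id %in% names(contig_lengths)) |
      x$end > contig_lengths[x$contig_id] | x$start < 0L
    if (any(bad))
      .stopf("%s interval outside contig bounds (first: %s:%d-%d)",
             label, x$contig_id[bad][1L], x$start[bad][1L], x$end[bad][1L])
  }
  check(predicted, "predicted")
  check(reference, "reference")
  tp <- fp <- fn <- 0L
  total <- sum(as.numeric(contig_lengths))
  for (cid in names(contig_lengths)) {
    p <- predicted[predicted$contig_id == cid, , drop = FALSE]
    r <- reference[reference$contig_id == cid, , drop = FALSE]
    pr <- IRanges::reduce(IRanges::IRanges(start = p$start + 1L, end = p$end))
    rr <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L, end = r$end))
    inter <- IRanges::intersect(pr, rr)
    tp <- tp + sum(IRanges::width(inter))
    fp <- fp + sum(IRanges::width(pr)) - sum(IRanges::width(inter))
    fn <- fn + sum(IRanges::width(rr)) - sum(IRanges::width(inter))
  }
  list(tp = tp, fp = fp, fn = fn, tn = total - tp - fp - fn)
}

#' Benchmark metrics from confusion counts
#'
#' Undefined ratios (0/0) are reported as `NaN`, never as 0.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn`.
#' @return one-row `data.frame`: `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, `false_positive_rate`, `f1`.
#' @export
benchmark_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) .stopf("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) NaN
        else 2 * prec * sens / (prec + sens)
  data.frame(sensitivity = sens, specificity = spec,
             accuracy = (tp + tn) / total, precision = prec,
             false_positive_rate = ratio(fp, fp + tn), f1 = f1)
}

#' Element-level benchmark (secondary report)
#'
#' An element matches when a predicted and a reference interval overlap
#' reciprocally by at least `min_reciprocal`.
#'
#' @param predicted,reference interval `data.frame`s.
#' @param min_reciprocal reciprocal-overlap threshold (default 0.8).
#' @return one-row `data.frame`: `matched`, `predicted_only`,
#'   `reference_only`, `element_sensitivity`, `element_precision`.
#' @export
element_level_metrics <- function(predicted, reference,
                                  min_reciprocal = 0.8) {
  matched_p <- logical(nrow(predicted))
  matched_r <- logical(nrow(reference))
  for (i in seq_len(nrow(predicted))) {
    for (j in which(!matched_r)) {
      if (predicted$contig_id[i] != reference$contig_id[j]) next
      ov <- min(predicted$end[i], reference$end[j]) -
        max(predicted$start[i], reference$start[j])
      if (ov <= 0) next
      if (ov >= min_reciprocal * (predicted$end[i] - predicted$start[i]) &&
          ov >= min_reciprocal * (reference$end[j] - reference$start[j])) {
        matched_p[i] <- TRUE; matched_r[j] <- TRUE; break
      }
    }
  }
  data.frame(matched = sum(matched_r),
             predicted_only = sum(!matched_p),
             reference_only = sum(!matched_r),
             element_sensitivity = if (nrow(reference))
               sum(matched_r) / nrow(reference) else NaN,
             element_precision = if (nrow(predicted))
               sum(matched_p) / nrow(predicted) else NaN)
}
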