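#' @title Evaluation metrics
#' @description Confusion-matrix based scoring: overall accuracy, macro-F1
#'   (unweighted mean of per-stage F1 over stages present in the truth),
#'   Cohen's kappa, per-stage precision/recall/F1, all optionally
#'   restricted to transition or nontransition epochs. Fold results are
#'   pooled at the epoch level (one confusion matrix over all folds), not
#'   averaged per fold.
#' @name metrics
NULL

#' Mark transition epochs
#'
#' Epoch `t` is a transition epoch iff its stage differs from the stage at
#' `t-1` or at `t+1`; boundary epochs compare only to their existing
#' neighbor. Everything else is a nontransition epoch; the two masks
#' partition the recording.
#'
#' @param hyp a [hypnogram()].
#' @return Logical vector, `TRUE` for transition epochs.
#' @export
mark_transitions <- function(hyp) {
  s <- as.integer(hypnogram(hyp))
  n <- length(s)
  if (n == 0L) return(logical(0))
  if (n == 1L) return(FALSE)
  prev_diff <- c(FALSE, s[-1L] != s[-n])
  next_diff <- c(s[-n] != s[-1L], FALSE)
  prev_diff | next_diff
}

stage_prf <- function(conf) {
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), NA_real_)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & (prec + rec) > 0,
               2 * prec * rec / (prec + rec),
               ifelse(rowSums(conf) > 0, 0, NA_real_))
  data.frame(stage = stage_labels(), precision = 100 * prec,
             recall = 100 * rec, f1 = 100 * f1)
}

#' Compute a metrics report
#'
#' @param truth,pred [hypnogram()]s of equal length (rows of the confusion
#'   matrix are truth, columns prediction).
#' @param mask optional logical vector restricting evaluation to a subset
#'   of epochs (e.g. transition epochs).
#' @return A `"metrics_report"` list: `confusion` (5x5 counts), `n`,
#'   `accuracy` (%), `macro_f1` (% over stages present in truth), `kappa`,
#'   `per_stage` (precision/recall/F1 in %).
#' @export
compute_metrics <- function(truth, pred, mask = NULL) {
  truth <- as.integer(hypnogram(truth))
  pred <- as.integer(hypnogram(pred))
  if (length(truth) != length(pred)) {
    stop("truth and pred must have equal length")
  }
  if (!is.null(mask)) {
    if (length(mask) != length(truth)) stop("mask length mismatch")
    truth <- truth[mask]
    pred <- pred[mask]
  }
  n <- length(truth)
  if (n == 0L) stop("no epochs selected for evaluation")
  conf <- matrix(0L, N_STAGES, N_STAGES,
                 dimnames = list(truth = stage_labels(),
                                 pred = stage_labels()))
  for (i in seq_len(n)) {
    conf[truth[i] + 1L, pred[i] + 1L] <- conf[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  acc <- sum(diag(conf)) / n
  p_e <- sum(rowSums(conf) * colSums(conf)) / n^2
  kappa <- if (p_e < 1) (acc - p_e) / (1 - p_e) else 0
  per_stage <- stage_prf(conf)
  present <- rowSums(conf) > 0
  macro_f1 <- mean(per_stage$f1[present])
  structure(list(confusion = conf, n = n, accuracy = 100 * acc,
                 macro_f1 = macro_f1, kappa = kappa,
                 per_stage = per_stage),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.1f%%  MF1 %.1f%%  kappa %.2f  (n = %d)\n",
              x$accuracy, x$macro_f1, x$kappa, x$n))
  print(round(as.data.frame(x$per_stage[-1]), 1))
  invisible(x)
}

#' Overall + transition/nontransition stratified report
#'
#' @param truth,pred [hypnogram()]s of equal length; the transition mask is
#'   derived from `truth`.
#' @return List with `overall`, `transition`, `nontransition`
#'   `"metrics_report"`s and the `transition_fraction`.
#' @export
stratified_metrics <- function(truth, pred) {
  mask <- mark_transitions(truth)
  list(overall = compute_metrics(truth, pred),
       transition = compute_metrics(truth, pred, mask),
       nontransition = compute_metrics(truth, pred, !mask),
       transition_fraction = mean(mask))
}

#' Pool per-fold predictions and score once
#'
#' Epoch-level pooling: all folds' (truth, prediction) pairs are
#' concatenated and one report is computed, so folds contribute in
#' proportion to their size (not an average of per-fold metrics).
#'
#' @param folds list of `list(truth =, pred =)` pairs of hypnograms.
#' @return A `"metrics_report"`.
#' @export
pool_folds <- function(folds) {
  if (length(folds) < 1L) stop("need at least one fold")
  truth <- do.call(c, lapply(folds, function(f) hypnogram(f$truth)))
  pred <- do.call(c, lapply(folds, function(f) hypnogram(f$pred)))
  compute_metrics(truth, pred)
}
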