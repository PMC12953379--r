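# Agreement metrics, sleep-architecture metrics, cohort statistics,
# and longitudinal trend summaries.

#' Confusion matrix over scored epochs
#'
#' Counts expert stage (rows) against predicted stage (columns) over the
#' four classes, excluding epochs whose expert label is `ARTIFACT` or
#' `PAD` (unscorable epochs never enter performance metrics).
#'
#' @param truth,pred [hypnogram]s of equal length.
#' @return 4 x 4 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) {
    stop("truth and prediction differ in length")
  }
  keep <- is_scoreable(truth)
  cm <- table(factor(as.character(truth)[keep], levels = SLEEP_STAGES),
              factor(as.character(pred)[keep], levels = SLEEP_STAGES))
  cm <- unclass(cm)
  dimnames(cm) <- list(expert = SLEEP_STAGES, predicted = SLEEP_STAGES)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Row-normalized percentage view of a confusion matrix
#' @param cm `confusion_matrix`.
#' @return Matrix of row percentages (rows sum to 100 where nonzero).
#' @export
confusion_percent <- function(cm) {
  rs <- rowSums(cm)
  sweep(unclass(cm), 1, ifelse(rs == 0, 1, rs), `/`) * 100
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d scored epochs\n", sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Overall agreement (percent)
#' @param cm `confusion_matrix`.
#' @return Accuracy in percent: 100 * trace / total.
#' @export
accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix: accuracy undefined")
  100 * sum(diag(cm)) / tot
}

#' Cohen's Kappa
#'
#' Chance-corrected agreement: `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the row/column marginals.
#'
#' @param cm `confusion_matrix`.
#' @return Kappa (unitless). If `p_e = 1`, returns 1 when agreement is
#'   also perfect, otherwise errors.
#' @export
cohens_kappa <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix: kappa undefined")
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(po - 1) < 1e-12) return(1)
    stop("degenerate marginals: p_e = 1 with imperfect agreement")
  }
  (po - pe) / (1 - pe)
}

#' Sleep-architecture metrics from a hypnogram
#'
#' Definitions (no lights-off annotation exists in this pipeline):
#' \itemize{
#'   \item TIB: scored-window duration = non-`PAD` epochs x 0.5 min
#'     (`ARTIFACT` epochs count toward TIB but never toward TST);
#'   \item TST: epochs in \{N1N2, N3, REM\} x 0.5 min;
#'   \item SE: 100 x TST / TIB;
#'   \item SOL: 0.5 x 0-based index of the first sleep-stage epoch,
#'     measured from the start of the scored window (`NA` if no sleep);
#'   \item stage percentages: share of TST (`NA` when TST = 0).
#' }
#'
#' @param hyp [hypnogram].
#' @return data.frame row with `tst_min`, `tib_min`, `se_pct`, `sol_min`,
#'   `pct_n1n2`, `pct_n3`, `pct_rem`.
#' @export
sleep_metrics <- function(hyp) {
  st <- as.character(hyp)
  scored <- st[st != "PAD"]
  if (length(scored) == 0) stop("hypnogram contains no scored epochs")
  tib <- length(scored) * 0.5
  n_sleep <- sum(scored %in% c("N1N2", "N3", "REM"))
  tst <- n_sleep * 0.5
  onset <- which(scored %in% c("N1N2", "N3", "REM"))[1]
  data.frame(
    tst_min = tst,
    tib_min = tib,
    se_pct = 100 * tst / tib,
    sol_min = if (is.na(onset)) NA_real_ else (onset - 1) * 0.5,
    pct_n1n2 = if (tst > 0) 100 * sum(scored == "N1N2") / n_sleep else NA_real_,
    pct_n3 = if (tst > 0) 100 * sum(scored == "N3") / n_sleep else NA_real_,
    pct_rem = if (tst > 0) 100 * sum(scored == "REM") / n_sleep else NA_real_)
}

#' Paired two-tailed t-test on per-participant metric values
#'
#' Each participant contributes one value per condition (nights averaged
#' upstream). Zero variance of the differences is reported as a
#' degenerate case: `p = 1` when all differences are zero (no effect),
#' otherwise `t`/`p` are `NA` with `degenerate = TRUE`.
#'
#' @param before,after Numeric vectors, same participants in the same
#'   order.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_metric_test <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 3)
  d <- after - before
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    return(list(t = NA_real_, p = NA_real_, df = length(d) - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Consistency test on squared deviations from the cohort mean
#'
#' For each condition, computes each participant's squared deviation
#' from that condition's cohort mean accuracy, then applies a paired
#' two-tailed t-test to the squared deviations. A negative `t` indicates
#' reduced inter-participant spread in the second condition. Invariant
#' to adding a constant to either condition (mean-centering).
#'
#' @param acc_a,acc_b Per-participant accuracies under conditions A
#'   and B.
#' @return As [paired_metric_test()].
#' @export
variance_consistency_test <- function(acc_a, acc_b) {
  da <- (acc_a - mean(acc_a))^2
  db <- (acc_b - mean(acc_b))^2
  paired_metric_test(da, db)
}

#' Longitudinal trend table over night labels
#'
#' Cohort mean and standard error per night label and metric, for
#' expert- and model-derived hypnograms side by side.
#'
#' @param records List of lists with `participant_id`, `night_label`,
#'   `truth` ([hypnogram]) and `prediction` ([hypnogram]); predictions
#'   may be `NULL` (expert-only table).
#' @param night_order Display/fit order of night labels.
#' @return Tidy data.frame: `metric`, `night_label`, `source`
#'   (`expert`/`model`), `mean`, `sem`, `n`.
#' @export
longitudinal_trends <- function(records,
                                night_order = c("B1", paste0("I", 1:7), "F1")) {
  rows <- list()
  for (rec in records) {
    if (!(rec$night_label %in% night_order)) {
      message("skipping unrecognized night label: ", rec$night_label)
      next
    }
    srcs <- list(expert = rec$truth)
    if (!is.null(rec$prediction)) srcs$model <- rec$prediction
    for (src in names(srcs)) {
      sm <- sleep_metrics(srcs[[src]])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(participant_id = rec$participant_id,
                   night_label = rec$night_label, source = src), sm)
    }
  }
  per_night <- do.call(rbind, rows)
  metrics <- c("tst_min", "tib_min", "se_pct", "sol_min",
               "pct_n1n2", "pct_n3", "pct_rem")
  out <- list()
  for (metric in metrics) {
    for (lb in intersect(night_order, unique(per_night$night_label))) {
      for (src in unique(per_night$source)) {
        v <- per_night[per_night$night_label == lb & per_night$source == src,
                       metric]
        v <- v[!is.na(v)]
        if (length(v) == 0) next
        out[[length(out) + 1L]] <- data.frame(
          metric = metric, night_label = lb, source = src,
          mean = mean(v),
          sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
          n = length(v))
      }
    }
  }
  do.call(rbind, out)
}

#' Collapse four-class stages to three classes
#'
#' Relabels `N1N2` and `N3` as `NREM` (wake / NREM / REM three-class
#' view); bookkeeping tokens pass through unchanged.
#'
#' @param stages Character vector or [hypnogram].
#' @return Character vector of three-class labels.
#' @export
collapse_stages <- function(stages) {
  st <- as.character(stages)
  st[st %in% c("N1N2", "N3")] <- "NREM"
  st
}
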