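#' @title Model evaluation: ROC, AUC, P-fair and confusion metrics
#' @description Receiver-operating-characteristic analysis of predicted
#'   presence probabilities against observed presence/absence, with bootstrap
#'   AUC confidence intervals, selection of the P-fair threshold (balancing
#'   sensitivity against specificity) and the confusion-matrix summaries
#'   reported for every habitat model.
#' @name evaluation
NULL

check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("ROC analysis undefined: only one class present", call. = FALSE)
  }
  labels
}

#' ROC analysis
#'
#' Candidate thresholds are the distinct scores plus one value above the
#' maximum; at each threshold presence is predicted when `score >= threshold`.
#' Sensitivity is TP / (TP + FN) and specificity TN / (TN + FP). The AUC is
#' the trapezoid area over (1 - specificity, sensitivity), which equals the
#' tie-corrected Mann-Whitney rank-sum statistic.
#'
#' @param scores predicted probabilities (or any monotone score).
#' @param labels observed presence/absence (0/1).
#' @return object of class `benthic_roc`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`.
#' @export
roc <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("length mismatch", call. = FALSE)
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  sens <- vapply(thr, function(t) mean(pos >= t), 0)
  spec <- vapply(thr, function(t) mean(neg < t), 0)
  # trapezoid over ROC points ordered from (1,1) down to (0,0)
  x <- 1 - spec
  y <- sens
  o <- order(x, y)
  auc <- sum(diff(x[o]) * (y[o][-1] + y[o][-length(y)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "benthic_roc")
}

#' @export
print.benthic_roc <- function(x, ...) {
  cat(sprintf("<benthic_roc> AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

# rank-based AUC (tie-corrected Mann-Whitney); used by the bootstrap
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile 2.5/97.5 interval over stratified resamples: presences and
#' absences are resampled with replacement within their own class, so both
#' classes are present in every replicate. Seeded and reproducible.
#'
#' @inheritParams roc
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return numeric `c(lower, upper)`; carries attribute `degenerate = TRUE`
#'   (with a warning) when either class has fewer than 2 members.
#' @export
bootstrap_auc <- function(scores, labels, n_boot = 1000, seed = 1) {
  labels <- check_labels(labels)
  ip <- which(labels == 1L)
  im <- which(labels == 0L)
  degenerate <- length(ip) < 2L || length(im) < 2L
  if (degenerate) {
    warning("a class has fewer than 2 members; bootstrap interval is degenerate")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    sp <- sample(ip, length(ip), replace = TRUE)
    sm <- sample(im, length(im), replace = TRUE)
    idx <- c(sp, sm)
    auc_rank(scores[idx], labels[idx])
  }, 0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  out <- unname(stats::quantile(aucs, c(0.025, 0.975)))
  attr(out, "degenerate") <- degenerate
  out
}

#' P-fair threshold
#'
#' The classification threshold that balances false positives against false
#' negatives: the candidate minimising `|sensitivity - specificity|`. Ties are
#' broken in favour of higher sensitivity, then the lower threshold.
#'
#' @param r a [roc()] result.
#' @return the selected threshold.
#' @export
p_fair <- function(r) {
  d <- abs(r$sensitivity - r$specificity)
  best <- which(d <= min(d) + 1e-12)
  best <- best[r$sensitivity[best] >= max(r$sensitivity[best]) - 1e-12]
  r$thresholds[best[which.min(r$thresholds[best])]]
}

#' Confusion-matrix percentages at a threshold
#'
#' Presence is predicted when `score >= threshold` (a probability exactly at
#' the threshold maps to presence).
#'
#' @inheritParams roc
#' @param threshold classification threshold.
#' @return named numeric: `sensitivity`, `specificity`, `correct` (percent).
#' @export
confusion <- function(scores, labels, threshold) {
  labels <- check_labels(labels)
  pred <- scores >= threshold
  sens <- 100 * mean(pred[labels == 1L])
  spec <- 100 * mean(!pred[labels == 0L])
  corr <- 100 * mean(pred == (labels == 1L))
  c(sensitivity = sens, specificity = spec, correct = corr)
}

#' Assemble a model evaluation report
#'
#' Bundles the evaluation of one binary habitat model on a validation set:
#' AUC with bootstrap CI, the P-fair threshold, sensitivity / specificity /
#' percent correct at P-fair, adjusted D-squared, terminal-node count and the
#' per-variable explained-deviance contributions.
#'
#' @param tree the fitted `benthic_tree`.
#' @param scores predicted probabilities on the validation rows.
#' @param labels validation presence/absence.
#' @param adj_d2 adjusted D-squared value to report (typically the training
#'   fit statistic).
#' @param label model name (class modelled).
#' @param n_boot,seed bootstrap settings.
#' @return object of class `model_report`.
#' @export
model_report <- function(tree, scores, labels, adj_d2, label = "",
                         n_boot = 1000, seed = 1) {
  r <- roc(scores, labels)
  ci <- bootstrap_auc(scores, labels, n_boot = n_boot, seed = seed)
  pf <- p_fair(r)
  cm <- confusion(scores, labels, pf)
  structure(list(label = label, auc = r$auc, auc_lower = ci[1],
                 auc_upper = ci[2], p_fair = pf,
                 sensitivity = unname(cm["sensitivity"]),
                 specificity = unname(cm["specificity"]),
                 correct = unname(cm["correct"]),
                 adj_d2 = adj_d2, terminal_nodes = n_leaves(tree),
                 contributions = variable_contribution(tree)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s\n", x$label))
  cat(sprintf("  AUC %.2f (%.2f-%.2f)  P_fair %.2f\n",
              x$auc, x$auc_lower, x$auc_upper, x$p_fair))
  cat(sprintf("  sens %.0f%%  spec %.0f%%  correct %.0f%%  AdjD2 %.2f  leaves %d\n",
              x$sensitivity, x$specificity, x$correct, x$adj_d2,
              x$terminal_nodes))
  invisible(x)
}

#' @export
as.data.frame.model_report <- function(x, ...) {
  data.frame(model = x$label, auc = x$auc, auc_lower = x$auc_lower,
             auc_upper = x$auc_upper, p_fair = x$p_fair,
             sensitivity = x$sensitivity, specificity = x$specificity,
             correct = x$correct, adj_d2 = x$adj_d2,
             terminal_nodes = x$terminal_nodes, stringsAsFactors = FALSE)
}

#' Write a set of model reports as CSV
#'
#' One row per model with the standard column set (AUC + CI, P-fair,
#' sensitivity, specificity, percent correct, adjusted D-squared, terminal
#' nodes).
#'
#' @param reports list of [model_report()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
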