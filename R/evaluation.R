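#' ROC analysis of percent changes against gold-standard labels
#'
#' A candidate cut `c` calls an evolution a responder when its percent
#' change is below `-c` (a decrease greater than `c` percent). Cuts are
#' swept over the midpoints of consecutive sorted unique decrease values
#' with sentinels beyond both ends, so the empirical curve reaches (0,0)
#' and (1,1). The AUC is computed by the rank (Mann-Whitney) formulation
#' with tie correction on the score `-change` with responders as the
#' positive class; it is identical to trapezoidal integration of the
#' empirical curve. The optimal threshold maximizes the Youden index
#' `J = sensitivity + specificity - 1`, ties broken toward the smaller
#' threshold magnitude.
#'
#' @param changes Numeric percent changes, one per evolution.
#' @param gold Character vector of `"responder"` / `"non_responder"`
#'   labels (both classes must occur).
#' @return An object of class `roc_result`: `curve` (data frame of
#'   threshold, sensitivity, specificity), `auc`, `optimal_threshold`
#'   (required percent decrease), `youden_j`, and the inputs.
#' @export
roc_analysis <- function(changes, gold) {
  stopifnot(length(changes) == length(gold), all(is.finite(changes)))
  stopifnot(all(gold %in% c("responder", "non_responder")))
  pos <- gold == "responder"
  if (!any(pos) || all(pos))
    stop("both classes must be present for ROC analysis", call. = FALSE)
  score <- -changes  # larger = deeper decrease = more responder-like
  u <- sort(unique(score))
  cuts <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cuts, function(ct) mean(score[pos] > ct), numeric(1))
  spec <- vapply(cuts, function(ct) mean(score[!pos] <= ct), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.min(abs(cuts[best]))]
  # Mann-Whitney AUC with tie correction
  r <- rank(score)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(curve = data.frame(threshold = cuts, sensitivity = sens,
                                    specificity = spec),
                 auc = auc, optimal_threshold = cuts[best],
                 youden_j = j[best], changes = changes, gold = gold),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f, optimal decrease threshold %.1f%% (J = %.2f)\n",
    x$auc, x$optimal_threshold, x$youden_j))
  invisible(x)
}

#' Youden-optimal operating point of an ROC result
#'
#' @param roc A [roc_analysis] result.
#' @return List with `threshold` (required percent decrease) and
#'   `youden_j`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- which(j == max(j))
  best <- best[which.min(abs(roc$curve$threshold[best]))]
  list(threshold = roc$curve$threshold[best], youden_j = j[best])
}

#' Confusion-matrix statistics for a 2 x 2 response table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/n`, Youden index
#' `sens + spec - 1`, and the Pearson chi-squared association with the
#' gold standard (1 df, no continuity correction by default). Ratios
#' with a zero denominator are reported as `NA`, not 0.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @param chi_correct Apply the Yates continuity correction.
#' @return An object of class `confusion_stats`.
#' @export
confusion_stats <- function(tp, tn, fp, fn, chi_correct = FALSE) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  chi <- chi_squared_2x2(tp, tn, fp, fn, correct = chi_correct)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = sens, specificity = spec,
                 ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 youden_j = if (is.na(sens) || is.na(spec)) NA_real_
                            else sens + spec - 1,
                 chi2_stat = chi$statistic, chi2_p = chi$p_value,
                 significant = chi$significant),
            class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.0f", 100 * v)
  cat(sprintf(
    "<confusion_stats> TP %d TN %d FP %d FN %d | sens %s%% spec %s%% PPV %s%% NPV %s%% acc %s%% | J %.2f | chi2 p %s\n",
    x$tp, x$tn, x$fp, x$fn, pct(x$sensitivity), pct(x$specificity),
    pct(x$ppv), pct(x$npv), pct(x$accuracy), x$youden_j,
    if (is.na(x$chi2_p)) "NA" else format.pval(x$chi2_p, digits = 3)))
  invisible(x)
}

#' Pearson chi-squared association of a 2 x 2 response table
#'
#' One degree of freedom, type I error 0.05, no continuity correction
#' unless requested. A zero marginal leaves the statistic undefined
#' (`NA`).
#'
#' @param tp,tn,fp,fn Counts (PET call vs gold standard).
#' @param correct Apply the Yates continuity correction.
#' @param alpha Significance level.
#' @return List with `statistic`, `p_value`, `significant`.
#' @export
chi_squared_2x2 <- function(tp, tn, fp, fn, correct = FALSE,
                            alpha = 0.05) {
  m <- matrix(c(tp, fp, fn, tn), nrow = 2)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = NA))
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       significant = unname(ct$p.value) < alpha)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' Compares the AUCs of two metrics measured on the same evolutions with
#' the DeLong test for correlated ROC curves (the MedCalc-era standard).
#'
#' @param changes_a,changes_b Percent changes of the two metrics on the
#'   same cases, in the same case order.
#' @param gold Shared gold-standard labels.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
compare_auc <- function(changes_a, changes_b, gold) {
  stopifnot(length(changes_a) == length(changes_b),
            length(changes_a) == length(gold))
  resp <- factor(gold, levels = c("non_responder", "responder"))
  ra <- pROC::roc(resp, -changes_a, quiet = TRUE,
                  direction = "<", levels = c("non_responder", "responder"))
  rb <- pROC::roc(resp, -changes_b, quiet = TRUE,
                  direction = "<", levels = c("non_responder", "responder"))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)),
       z = unname(tst$statistic), p_value = unname(tst$p.value))
}

#' Group metrics by statistically indistinguishable AUC
#'
#' Performs all pairwise paired DeLong comparisons and reports the
#' connected components of the "not significantly different" graph
#' (transitive closure), the usual way AUC intercomparison diagrams are
#' summarized.
#'
#' @param change_table Data frame / matrix, one column of percent
#'   changes per metric, rows = shared cases.
#' @param gold Gold-standard labels.
#' @param alpha Significance level.
#' @return List of character vectors of metric names, one per group,
#'   ordered by decreasing best AUC.
#' @export
auc_groups <- function(change_table, gold, alpha = 0.05) {
  metrics <- colnames(change_table)
  k <- length(metrics)
  adj <- diag(TRUE, k)
  aucs <- numeric(k)
  for (i in seq_len(k)) {
    aucs[i] <- roc_analysis(change_table[, i], gold)$auc
    for (jj in seq_len(i - 1)) {
      p <- compare_auc(change_table[, i], change_table[, jj], gold)$p_value
      adj[i, jj] <- adj[jj, i] <- is.na(p) || p >= alpha
    }
  }
  # connected components by repeated expansion
  remaining <- seq_len(k)
  groups <- list()
  while (length(remaining) > 0) {
    comp <- remaining[1]
    repeat {
      grow <- remaining[apply(adj[comp, remaining, drop = FALSE], 2, any)]
      if (length(setdiff(grow, comp)) == 0) break
      comp <- union(comp, grow)
    }
    groups[[length(groups) + 1]] <- metrics[comp]
    remaining <- setdiff(remaining, comp)
  }
  ord <- order(-vapply(groups, function(g) max(aucs[match(g, metrics)]),
                       numeric(1)))
  groups[ord]
}
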