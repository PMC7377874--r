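## Classifier evaluation: ROC AUC of the EMT score against known phenotype
## labels, and the confusion table at the 0.5 decision threshold.

#' ROC AUC via the rank-sum identity
#'
#' Area under the ROC curve for the EMT score as a predictor of the
#' mesenchymal phenotype, computed through the Mann-Whitney identity
#' \eqn{AUC = (R_m - n_m(n_m+1)/2) / (n_m n_e)} with midranks, so tied
#' scores contribute half credit. Equal to the fraction of
#' (mesenchymal, epithelial) sample pairs in which the mesenchymal sample
#' scores strictly higher, plus half the tied fraction.
#'
#' @param scores Numeric vector of scores (any monotone scale), named by
#'   sample id, or parallel to \code{labels}.
#' @param labels Phenotype labels ([phenotypeLabels()] or named vector); if
#'   \code{scores} is named, labels are matched by sample id.
#' @return AUC in \code{[0, 1]}.
#' @examples
#' rocAUC(c(a = .9, b = .8, c = .1, d = .2),
#'        phenotypeLabels(c("a", "b", "c", "d"),
#'                        c("mesenchymal", "mesenchymal",
#'                          "epithelial", "epithelial")))  # 1
#' @export
rocAUC <- function(scores, labels) {
  al <- .aligned_scores(scores, labels)
  is_m <- al$labels == "mesenchymal"
  n_m <- sum(is_m); n_e <- sum(!is_m)
  if (n_m == 0L || n_e == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(al$scores, ties.method = "average")
  (sum(r[is_m]) - n_m * (n_m + 1) / 2) / (n_m * n_e)
}

#' Confusion counts at a score threshold
#'
#' Cross-tabulates predicted class (score >= \code{threshold} ->
#' mesenchymal-like) against the true phenotype.
#'
#' @param scores,labels As in [rocAUC()].
#' @param threshold Decision threshold (default 0.5).
#' @return 2x2 integer matrix, rows = predicted, columns = true.
#' @export
confusionAtThreshold <- function(scores, labels, threshold = 0.5) {
  al <- .aligned_scores(scores, labels, require_both = FALSE)
  pred <- factor(ifelse(al$scores >= threshold, "mesenchymal_like",
                        "epithelial_like"),
                 levels = c("epithelial_like", "mesenchymal_like"))
  truth <- factor(as.character(al$labels),
                  levels = c("epithelial", "mesenchymal"))
  tab <- table(predicted = pred, true = truth)
  matrix(as.integer(tab), 2L, 2L, dimnames = dimnames(tab))
}

#' Evaluation report for scored samples
#'
#' @param scores Either the data.frame from [scoreCohort()] or a numeric
#'   vector of scores named by sample id.
#' @param labels Phenotype labels.
#' @param threshold Decision threshold for the confusion table.
#' @return List with \code{auc}, \code{confusion} (2x2),
#'   \code{accuracy}, \code{n_samples}.
#' @export
evaluateScores <- function(scores, labels, threshold = 0.5) {
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$emt_score, scores$sample_id)
  auc <- rocAUC(scores, labels)
  conf <- confusionAtThreshold(scores, labels, threshold)
  list(auc = auc,
       confusion = conf,
       accuracy = sum(diag(conf)) / sum(conf),
       n_samples = sum(conf))
}

## Match scores to labels by sample id when named; otherwise positional.
.aligned_scores <- function(scores, labels, require_both = TRUE) {
  if (!is.factor(labels) || is.null(names(labels)))
    labels <- phenotypeLabels(names(labels), labels)
  if (!is.null(names(scores))) {
    common <- intersect(names(scores), names(labels))
    if (!length(common)) stop("no sample id shared by scores and labels")
    scores <- scores[common]
    labels <- labels[common]
  } else if (length(scores) != length(labels)) {
    stop("unnamed scores must be parallel to labels")
  }
  if (anyNA(scores)) stop("scores contain NA")
  if (require_both && length(unique(labels)) < 2L)
    stop("both classes must be present")
  list(scores = as.numeric(scores), labels = labels)
}

#' Log-rank comparison of survival between predicted EMT classes
#'
#' Convenience wrapper delegating to \code{survival::survdiff}; provided so
#' that scored cohorts with follow-up can be split at the 0.5 threshold and
#' compared, as is standard when a qualitative EMT call is assessed for
#' prognostic value.
#'
#' @param scores data.frame from [scoreCohort()] or named numeric vector.
#' @param time Follow-up time, named by sample id or parallel to scores.
#' @param status Event indicator (1 = event), same alignment as \code{time}.
#' @param threshold Decision threshold (default 0.5).
#' @return List with \code{chisq}, \code{p_value}, \code{n_per_group}.
#' @export
logrankByClass <- function(scores, time, status, threshold = 0.5) {
  if (!requireNamespace("survival", quietly = TRUE))
    stop("the 'survival' package is required for logrankByClass()")
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$emt_score, scores$sample_id)
  if (!is.null(names(scores)) && !is.null(names(time))) {
    common <- intersect(names(scores), names(time))
    scores <- scores[common]; time <- time[common]; status <- status[common]
  }
  grp <- factor(ifelse(scores >= threshold, "mesenchymal_like",
                       "epithelial_like"))
  if (nlevels(droplevels(grp)) < 2L)
    stop("both predicted classes must be present for a log-rank test")
  sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  list(chisq = unname(sd$chisq), p_value = p,
       n_per_group = stats::setNames(as.integer(sd$n), levels(droplevels(grp))))
}
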