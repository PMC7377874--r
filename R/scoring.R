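## Single-sample EMT scoring: for each signature pair the sample shows
## either the epithelial pattern (gene_a > gene_b) or the reversed,
## mesenchymal-indicative pattern (gene_a < gene_b). The EMT score is the
## fraction of pairs in the reversed pattern; scores >= 0.5 call the sample
## mesenchymal-like. Only within-sample comparisons enter, so each sample is
## classified on its own, independent of cohort composition, batch or
## normalisation.

#' Signed rank difference for one pair in one sample
#'
#' Returns \code{rank(gene_a) - rank(gene_b)} within the sample. A strictly
#' negative value is the mesenchymal-indicative (reversed) pattern and
#' counts toward the EMT score; zero (tied values) never counts. Since ranks
#' within one sample are a monotone function of the values, the sign equals
#' the sign of \code{value(gene_a) - value(gene_b)}.
#'
#' @param sample_values Named numeric vector: one sample's expression values
#'   (or within-sample ranks) indexed by gene id.
#' @param pair Character vector \code{c(gene_a, gene_b)}.
#' @return Signed numeric difference; \code{NA} if either gene is absent.
#' @export
rankDifference <- function(sample_values, pair) {
  stopifnot(length(pair) == 2L)
  if (is.null(names(sample_values)))
    stop("sample_values must be named by gene id")
  if (!all(pair %in% names(sample_values))) return(NA_real_)
  r <- rank(sample_values, ties.method = "average")
  unname(r[pair[[1L]]] - r[pair[[2L]]])
}

## Internal vectorised scorer shared by emtScore / scoreCohort.
.score_matrix <- function(x, signature,
                          missing_policy = c("renormalize", "strict"),
                          max_missing_fraction = 0.5) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(is(signature, "GenePairSignature"))
  p <- signaturePairs(signature)
  if (!nrow(p)) stop("signature is empty; nothing to score")
  ia <- match(p$gene_a, rownames(x))
  ib <- match(p$gene_b, rownames(x))
  present <- !is.na(ia) & !is.na(ib)
  miss_genes <- setdiff(unique(c(p$gene_a[is.na(ia)], p$gene_b[is.na(ib)])),
                        character(0))
  if (missing_policy == "strict" && any(!present))
    stop("strict mode: signature gene(s) missing from the matrix: ",
         paste(miss_genes, collapse = ", "))
  if (!any(present))
    stop("no signature pair is evaluable; missing gene(s): ",
         paste(miss_genes, collapse = ", "))
  if (mean(!present) > max_missing_fraction)
    stop(sprintf(paste0("%d of %d signature pairs unevaluable (> %.0f%%); ",
                        "missing gene(s): %s"),
                 sum(!present), nrow(p), 100 * max_missing_fraction,
                 paste(miss_genes, collapse = ", ")))
  va <- x[ia[present], , drop = FALSE]
  vb <- x[ib[present], , drop = FALSE]
  n_rev <- colSums(va < vb)         # strict: ties are not reversed
  denom <- if (missing_policy == "strict") nrow(p) else sum(present)
  score <- n_rev / denom
  data.frame(sample_id = colnames(x),
             emt_score = unname(score),
             n_pairs_total = nrow(p),
             n_pairs_evaluated = sum(present),
             label = ifelse(score >= 0.5, "mesenchymal_like",
                            "epithelial_like"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' EMT score of a single sample
#'
#' Computes the fraction of signature pairs in the reversed
#' (mesenchymal-indicative) ordering \code{gene_a < gene_b}; ties never
#' count as reversed. The score lies in \code{[0, 1]} and a sample with
#' score >= 0.5 is called \code{mesenchymal_like}, otherwise
#' \code{epithelial_like}.
#'
#' When signature genes are absent from the platform, the default
#' \code{renormalize} policy drops the unevaluable pairs and divides by the
#' number actually evaluated, erroring once more than
#' \code{max_missing_fraction} of pairs are lost (scores computed from a
#' small remnant of the signature are not comparable). \code{strict} refuses
#' any missing gene and always divides by the full signature size.
#'
#' @param sample_values Named numeric vector of one sample's expression, or
#'   a one-column matrix.
#' @param signature A [GenePairSignature-class].
#' @param missing_policy \code{"renormalize"} (default) or \code{"strict"}.
#' @param max_missing_fraction Maximum tolerated fraction of unevaluable
#'   pairs under \code{renormalize} (default 0.5).
#' @return One-row data.frame: \code{sample_id}, \code{emt_score},
#'   \code{n_pairs_total}, \code{n_pairs_evaluated}, \code{label}.
#' @examples
#' sig <- builtinSignature()
#' expr <- stats::setNames(seq_along(signatureGenes(sig)),
#'                         signatureGenes(sig))
#' emtScore(expr, sig)
#' @export
emtScore <- function(sample_values, signature,
                     missing_policy = c("renormalize", "strict"),
                     max_missing_fraction = 0.5) {
  if (is.matrix(sample_values)) {
    if (ncol(sample_values) != 1L)
      stop("emtScore takes a single sample; use scoreCohort for matrices")
    x <- sample_values
    if (is.null(colnames(x))) colnames(x) <- "sample_1"
  } else {
    if (is.null(names(sample_values)))
      stop("sample_values must be named by gene id")
    x <- matrix(sample_values, ncol = 1L,
                dimnames = list(names(sample_values), "sample_1"))
  }
  if (is.null(rownames(x))) stop("sample values must be named by gene id")
  .score_matrix(x, signature, missing_policy, max_missing_fraction)
}

#' EMT scores for every sample of a cohort
#'
#' Applies [emtScore()] independently to each column; no cross-sample
#' statistic is used, so a sample's score is identical whether it is scored
#' alone or inside any cohort, before or after per-sample monotone
#' distortions.
#'
#' @param x Expression matrix (or SummarizedExperiment).
#' @param signature A [GenePairSignature-class].
#' @param missing_policy,max_missing_fraction See [emtScore()].
#' @return data.frame with one row per sample, in matrix column order.
#' @export
scoreCohort <- function(x, signature,
                        missing_policy = c("renormalize", "strict"),
                        max_missing_fraction = 0.5) {
  x <- .as_expr_matrix(x)
  .score_matrix(x, signature, missing_policy, max_missing_fraction)
}

#' Write per-sample EMT scores as TSV
#' @param scores data.frame from [scoreCohort()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-sample EMT scores
#' @param path TSV written by [writeScores()].
#' @return data.frame of scores.
#' @export
readScores <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
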