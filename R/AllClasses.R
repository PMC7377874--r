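#' @import methods
#' @importFrom stats median p.adjust phyper dhyper wilcox.test rank rnorm
#'   runif rbinom setNames quantile
#' @importFrom utils read.delim write.table head
#' @useDynLib emtGPS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Gene-pair signature class
#'
#' An ordered collection of gene pairs encoding a qualitative, rank-based
#' classifier. Each pair is stored in the mesenchymal-indicative orientation:
#' within a mesenchymal-like sample the expression of \code{gene_a} is
#' expected to fall below that of \code{gene_b} (the reversed ordering),
#' whereas epithelial samples show the stable ordering
#' \code{gene_a > gene_b}. The per-pair discovery statistics (one-sided
#' Fisher exact P for reversal enrichment and the reversal ratio among
#' mesenchymal samples) are carried along when available.
#'
#' @slot pairs A \code{data.frame} with columns \code{pair_id},
#'   \code{gene_a}, \code{gene_b}, \code{fisher_p}, \code{reversal_ratio}.
#'
#' @seealso [builtinSignature()] for the packaged 16-gene-pair ovarian
#'   cancer EMT signature, [discoverSignature()] to derive a signature from
#'   a labelled cohort, [scoreCohort()] to apply one.
#' @export
setClass("GenePairSignature", representation(pairs = "data.frame"))

setValidity("GenePairSignature", function(object) {
  p <- object@pairs
  req <- c("pair_id", "gene_a", "gene_b", "fisher_p", "reversal_ratio")
  if (!all(req %in% names(p)))
    return(paste("pairs must have columns:", paste(req, collapse = ", ")))
  msgs <- character()
  if (anyDuplicated(p$pair_id))
    msgs <- c(msgs, "duplicate pair_id")
  if (any(p$gene_a == p$gene_b))
    msgs <- c(msgs, "gene_a == gene_b in at least one pair")
  key <- paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b))
  if (anyDuplicated(key))
    msgs <- c(msgs, "the same unordered gene pair appears more than once")
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!ok(p$fisher_p)) msgs <- c(msgs, "fisher_p outside [0, 1]")
  if (!ok(p$reversal_ratio)) msgs <- c(msgs, "reversal_ratio outside [0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a gene-pair signature
#'
#' @param pairs data.frame with at least \code{gene_a} and \code{gene_b};
#'   \code{pair_id}, \code{fisher_p} and \code{reversal_ratio} are filled
#'   with defaults when absent. Orientation convention: \code{gene_a <
#'   gene_b} (by expression, equivalently by within-sample rank) is the
#'   mesenchymal-indicative pattern.
#' @return A [GenePairSignature-class] object.
#' @examples
#' sig <- GenePairSignature(data.frame(gene_a = c("APMAP", "ZNF3"),
#'                                     gene_b = c("COL5A2", "FAP")))
#' nPairs(sig)
#' @export
GenePairSignature <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (is.null(pairs$pair_id))
    pairs$pair_id <- if (nrow(pairs)) paste0("pair_", seq_len(nrow(pairs))) else character()
  if (is.null(pairs$fisher_p)) pairs$fisher_p <- NA_real_
  if (is.null(pairs$reversal_ratio)) pairs$reversal_ratio <- NA_real_
  pairs$pair_id <- as.character(pairs$pair_id)
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  rownames(pairs) <- NULL
  new("GenePairSignature",
      pairs = pairs[, c("pair_id", "gene_a", "gene_b",
                        "fisher_p", "reversal_ratio")])
}

#' Number of pairs in a signature
#' @param x A [GenePairSignature-class].
#' @return Integer pair count (the denominator of the EMT score in strict
#'   mode).
#' @export
nPairs <- function(x) {
  stopifnot(is(x, "GenePairSignature"))
  nrow(x@pairs)
}

#' Distinct genes used by a signature
#' @param x A [GenePairSignature-class].
#' @return Character vector of unique gene identifiers, in order of first use.
#' @export
signatureGenes <- function(x) {
  stopifnot(is(x, "GenePairSignature"))
  unique(c(rbind(x@pairs$gene_a, x@pairs$gene_b)))
}

#' Signature pair table
#' @param x A [GenePairSignature-class].
#' @return The underlying \code{data.frame} of pairs and statistics.
#' @export
signaturePairs <- function(x) {
  stopifnot(is(x, "GenePairSignature"))
  x@pairs
}

#' @describeIn GenePairSignature-class compact display
#' @param object A \code{GenePairSignature}.
#' @export
setMethod("show", "GenePairSignature", function(object) {
  p <- object@pairs
  cat(sprintf("GenePairSignature with %d pair(s), %d gene(s)\n",
              nrow(p), length(signatureGenes(object))))
  cat("mesenchymal-indicative pattern: gene_a < gene_b (within-sample)\n")
  if (nrow(p)) {
    shown <- head(p, 6L)
    cat(paste0("  ", shown$pair_id, ": ", shown$gene_a, " < ", shown$gene_b,
               ifelse(is.na(shown$reversal_ratio), "",
                      sprintf("  (reversal %.2f%%)",
                              100 * shown$reversal_ratio)), "\n"), sep = "")
    if (nrow(p) > 6L) cat(sprintf("  ... and %d more\n", nrow(p) - 6L))
  }
  invisible(object)
})

#' @export
setMethod("length", "GenePairSignature", function(x) nrow(x@pairs))

#' Coerce a signature to a data.frame
#' @param x A [GenePairSignature-class].
#' @param row.names,optional ignored, present for generic compatibility.
#' @param ... ignored.
#' @export
as.data.frame.GenePairSignature <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  signaturePairs(x)
}
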