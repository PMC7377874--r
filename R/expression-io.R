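## Expression-matrix and signature I/O, probe collapsing, within-sample ranks.
##
## An expression matrix is a plain numeric matrix, genes in rows (unique
## rownames), samples in columns (unique colnames), all values finite. Units
## are arbitrary: every downstream computation uses only the within-sample
## ordering of values, so raw intensities, RPKM and counts are all valid.

## Coerce and validate the gene x sample container. Accepts a numeric matrix
## or a SummarizedExperiment (first assay is taken).
.as_expr_matrix <- function(x, what = "expression matrix",
                            drop_na_genes = FALSE) {
  if (is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("SummarizedExperiment input given but the package is not available")
    x <- SummarizedExperiment::assay(x, 1L)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop(what, ": duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop(what, ": duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (drop_na_genes && anyNA(x)) {
    keep <- rowSums(is.na(x)) == 0L
    if (!any(keep)) stop(what, ": every gene has at least one missing value")
    x <- x[keep, , drop = FALSE]
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(what, ": non-finite value at gene '", rownames(x)[bad[1L]],
         "', sample '", colnames(x)[bad[2L]],
         "' (use drop_na_genes = TRUE to drop genes with missing values)")
  }
  x
}

#' Read a gene-by-sample expression matrix
#'
#' Expects a delimited text file with gene identifiers in the first column,
#' a header row of sample identifiers, and a numeric body. Any monotone-
#' comparable scale (microarray intensity, RPKM, counts) is acceptable:
#' downstream logic uses only the within-sample ordering of values.
#'
#' @param path File path.
#' @param delimiter Field delimiter, default tab.
#' @param drop_na_genes If \code{TRUE}, genes with any missing value are
#'   dropped; the default rejects missing values, because a missing value
#'   has no defined rank.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' writeExpressionMatrix(m, f)
#' all.equal(readExpressionMatrix(f), m + 0)
#' @export
readExpressionMatrix <- function(path, delimiter = "\t",
                                 drop_na_genes = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L)
    stop("malformed header in ", path,
         ": need a gene-id column plus at least one sample column")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id row(s) in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (is.character(v) || is.factor(v)) {
      vn <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(vn) & !is.na(v) & as.character(v) != "NA")
      if (length(bad))
        stop("non-numeric cell in ", path, " at gene '", gene_ids[bad[1L]],
             "', column '", names(body)[j], "': '", v[bad[1L]], "'")
      body[[j]] <- vn
    }
  }
  m <- as.matrix(body)
  dimnames(m) <- list(gene_ids, names(body))
  .as_expr_matrix(m, what = path, drop_na_genes = drop_na_genes)
}

#' Write an expression matrix as TSV
#'
#' @param x Expression matrix (or SummarizedExperiment).
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, delimiter = "\t") {
  x <- .as_expr_matrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level values to gene level
#'
#' Probes mapping to more than one gene are discarded; a gene measured by
#' several probes receives the per-sample arithmetic mean of its probes'
#' values.
#'
#' @param probe_matrix Numeric matrix keyed by probe id (rows).
#' @param probe_map Named list: probe id -> character vector of gene ids.
#'   Every probe in the matrix must be present.
#' @return Expression matrix keyed by gene id.
#' @examples
#' m <- matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' collapseProbes(m, list(p1 = "G", p2 = "G"))  # G = 3
#' @export
collapseProbes <- function(probe_matrix, probe_map) {
  probe_matrix <- .as_expr_matrix(probe_matrix, what = "probe matrix")
  probes <- rownames(probe_matrix)
  missing <- setdiff(probes, names(probe_map))
  if (length(missing))
    stop("probe(s) absent from probe_map: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  n_genes <- lengths(probe_map[probes])
  keep <- probes[n_genes == 1L]
  if (!length(keep))
    stop("no probe maps to exactly one gene; nothing to collapse")
  gene_of <- vapply(probe_map[keep], `[[`, character(1L), 1L)
  sub <- probe_matrix[keep, , drop = FALSE]
  out <- rowsum(sub, group = gene_of, reorder = FALSE)
  counts <- as.vector(table(gene_of)[rownames(out)])
  out <- out / counts
  .as_expr_matrix(out, what = "collapsed matrix")
}

#' Within-sample expression ranks
#'
#' Ranks each sample (column) independently, ascending: rank 1 is the
#' lowest-expressed gene in that sample. With no ties each column is a
#' permutation of \code{1..nrow(x)}. The ranking is invariant under any
#' strictly increasing per-sample transform, which is what makes rank-based
#' signatures immune to batch effects and monotone normalisation.
#'
#' Note that all pairwise ordering logic in this package (stable-pair
#' mining, reversal tests, EMT scoring) compares raw values strictly and is
#' unaffected by \code{tie_policy}; ranks are exposed for the rank-based
#' differential expression screen and for reporting.
#'
#' @param x Expression matrix (or SummarizedExperiment).
#' @param tie_policy One of \code{"average"}, \code{"min"}, \code{"dense"}.
#' @return Matrix of the same shape with within-sample ranks.
#' @examples
#' m <- matrix(c(5.1, 2.0, 9.3), 3, 1, dimnames = list(letters[1:3], "s1"))
#' rankWithinSample(m)[, 1]  # 2 1 3
#' @export
rankWithinSample <- function(x, tie_policy = c("average", "min", "dense")) {
  x <- .as_expr_matrix(x)
  tie_policy <- match.arg(tie_policy)
  rank_col <- switch(tie_policy,
    average = function(v) rank(v, ties.method = "average"),
    min     = function(v) rank(v, ties.method = "min"),
    dense   = function(v) match(v, sort(unique(v))))
  r <- apply(x, 2L, rank_col)
  dimnames(r) <- dimnames(x)
  r
}

#' Phenotype labels for a two-class cohort
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param labels Character vector (or factor) with values
#'   \code{"epithelial"} / \code{"mesenchymal"}, parallel to
#'   \code{sample_ids}; a named vector may be given alone.
#' @return Named factor with levels \code{epithelial}, \code{mesenchymal}.
#' @export
phenotypeLabels <- function(sample_ids, labels = NULL) {
  if (is.null(labels)) {
    labels <- sample_ids
    sample_ids <- names(labels)
  }
  if (is.null(sample_ids) || length(sample_ids) != length(labels))
    stop("sample_ids and labels must be parallel vectors")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in labels: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  lv <- c("epithelial", "mesenchymal")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), lv)
  if (length(bad))
    stop("labels must be 'epithelial' or 'mesenchymal'; found: ",
         paste(bad, collapse = ", "))
  stats::setNames(factor(labels, levels = lv), sample_ids)
}

## Align labels with a matrix's samples; both classes must be present when
## require_both = TRUE. Returns the factor restricted/ordered to colnames(x).
.align_labels <- function(x, labels, require_both = TRUE, min_per_class = 1L) {
  if (!is.factor(labels) || is.null(names(labels)))
    labels <- phenotypeLabels(names(labels), labels)
  missing <- setdiff(names(labels), colnames(x))
  if (length(missing))
    stop("labelled sample(s) absent from the matrix: ",
         paste(head(missing, 5L), collapse = ", "))
  common <- intersect(colnames(x), names(labels))
  if (!length(common)) stop("no labelled samples found in the matrix")
  lab <- labels[common]
  if (require_both) {
    n <- table(lab)
    if (any(n < min_per_class))
      stop("need at least ", min_per_class, " sample(s) per class; got ",
           paste(names(n), n, sep = "=", collapse = ", "))
  }
  lab
}

#' Read phenotype labels from a two-column TSV
#'
#' @param path File with columns \code{sample_id}, \code{label}.
#' @return Named factor as from [phenotypeLabels()].
#' @export
readLabels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop("labels file needs columns sample_id, label")
  phenotypeLabels(as.character(df[[1L]]), as.character(df[[2L]]))
}

#' Write phenotype labels
#' @param labels Named factor/character of labels.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeLabels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels),
                   label = as.character(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-pair signature table
#'
#' TSV with columns \code{pair_id}, \code{gene_a}, \code{gene_b},
#' \code{fisher_p}, \code{reversal_ratio}. Convention (recorded as a comment
#' header in files written by [writeSignature()]): the mesenchymal-indicative
#' pattern is \code{rank(gene_a) < rank(gene_b)} within a sample.
#'
#' The packaged ovarian-cancer EMT signature is available as
#' \code{readSignature("builtin:16gps")} or [builtinSignature()].
#'
#' @param path File path, or a \code{builtin:} URI.
#' @return A [GenePairSignature-class].
#' @export
readSignature <- function(path) {
  if (grepl("^builtin:", path))
    return(builtinSignature(sub("^builtin:", "", path)))
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  req <- c("pair_id", "gene_a", "gene_b")
  if (!all(req %in% names(df)))
    stop("signature file must have columns pair_id, gene_a, gene_b")
  GenePairSignature(df)
}

#' Write a gene-pair signature table
#' @param signature A [GenePairSignature-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSignature <- function(signature, path) {
  stopifnot(is(signature, "GenePairSignature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# gene-pair signature;",
                   "mesenchymal-indicative pattern: rank(gene_a) < rank(gene_b)"),
             con)
  utils::write.table(signaturePairs(signature), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 16-gene-pair EMT signature
#'
#' The published ovarian-cancer EMT signature: 16 gene pairs over 18 genes,
#' every pair anchored on \emph{COL5A2} or \emph{FAP}. In an epithelial
#' sample each partner gene outranks its anchor; in mesenchymal samples the
#' ordering flips (\code{gene_a < gene_b}) for most pairs, and the fraction
#' of flipped pairs is the sample's EMT score.
#'
#' @param name Signature name; only \code{"16gps"} is shipped.
#' @return A [GenePairSignature-class] with 16 pairs.
#' @examples
#' sig <- builtinSignature()
#' nPairs(sig)                 # 16
#' length(signatureGenes(sig)) # 18
#' @export
builtinSignature <- function(name = "16gps") {
  if (!identical(name, "16gps"))
    stop("unknown builtin signature: '", name, "' (available: 16gps)")
  path <- system.file("extdata", "signature_16gps.tsv", package = "emtGPS",
                      mustWork = TRUE)
  readSignature(path)
}
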