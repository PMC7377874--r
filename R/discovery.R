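## Signature discovery: rank-based DEG screen, stable-pair mining at the
## 99% concordance threshold, Fisher reversal test, two-step optimisation.

#' Discovery configuration
#'
#' Thresholds of the discovery pipeline. Defaults reproduce the published
#' procedure: gene pairs whose ordering holds in at least 99% of epithelial
#' samples, significantly reversed in mesenchymal samples by a one-sided
#' Fisher exact test at P < 0.05, reversal ratio at least 75%, and at least
#' one member differentially expressed at BH-FDR < 0.05.
#'
#' "More than 99%" and "more than 75%" are implemented inclusively
#' (\code{>=}): the published signature itself contains pairs at a reversal
#' ratio of exactly 75.00%, so the strict reading would contradict it, and
#' the inclusive form behaves sensibly on small cohorts.
#'
#' @param stability_threshold Minimum concordant fraction among epithelial
#'   samples for a stable pair.
#' @param deg_fdr BH-FDR cutoff defining differentially expressed genes.
#' @param fisher_alpha Fisher exact P cutoff for reversal significance.
#' @param reversal_threshold Minimum reversal ratio among mesenchymal
#'   samples.
#' @param require_deg Require at least one pair member to be a DEG.
#' @param fisher_sidedness \code{"one_sided_greater"} (reversal enriched in
#'   mesenchymal; default) or \code{"two_sided"}.
#' @param deg_on_ranks Run the Wilcoxon DEG screen on within-sample ranks
#'   (default) rather than raw expression.
#' @return A list of class \code{discovery_config}.
#' @export
discoveryConfig <- function(stability_threshold = 0.99,
                            deg_fdr = 0.05,
                            fisher_alpha = 0.05,
                            reversal_threshold = 0.75,
                            require_deg = TRUE,
                            fisher_sidedness = c("one_sided_greater",
                                                 "two_sided"),
                            deg_on_ranks = TRUE) {
  fisher_sidedness <- match.arg(fisher_sidedness)
  for (v in c(stability_threshold, deg_fdr, fisher_alpha, reversal_threshold))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("all thresholds must lie in (0, 1)")
  structure(list(stability_threshold = stability_threshold,
                 deg_fdr = deg_fdr,
                 fisher_alpha = fisher_alpha,
                 reversal_threshold = reversal_threshold,
                 require_deg = isTRUE(require_deg),
                 fisher_sidedness = fisher_sidedness,
                 deg_on_ranks = isTRUE(deg_on_ranks)),
            class = "discovery_config")
}

#' Rank-based differential expression screen
#'
#' Per-gene two-sided Wilcoxon rank-sum test comparing the gene's
#' within-sample ranks between epithelial and mesenchymal samples, adjusted
#' by the Benjamini-Hochberg step-up procedure over all tested genes. Genes
#' with FDR below \code{fdr_threshold} are flagged as DEGs. Working on
#' within-sample ranks (rather than raw values) keeps the screen comparable
#' across platforms and normalisations.
#'
#' @param x Expression matrix (or SummarizedExperiment), or a precomputed
#'   within-sample rank matrix with \code{on_ranks = FALSE}.
#' @param labels Phenotype labels ([phenotypeLabels()] or named vector).
#' @param fdr_threshold DEG cutoff on the BH-adjusted p-value.
#' @param on_ranks If \code{TRUE} (default) the matrix is converted to
#'   within-sample ranks before testing; set \code{FALSE} to test the given
#'   values as-is (raw-expression sensitivity mode).
#' @return data.frame with columns \code{gene_id}, \code{p_value},
#'   \code{fdr}, \code{direction} (\code{up_in_mesenchymal} /
#'   \code{down_in_mesenchymal}), \code{is_deg}.
#' @export
identifyDEGs <- function(x, labels, fdr_threshold = 0.05, on_ranks = TRUE) {
  x <- .as_expr_matrix(x)
  lab <- .align_labels(x, labels, min_per_class = 2L)
  x <- x[, names(lab), drop = FALSE]
  v <- if (on_ranks) rankWithinSample(x) else x
  epi <- lab == "epithelial"
  p <- vapply(seq_len(nrow(v)), function(i) {
    suppressWarnings(stats::wilcox.test(v[i, !epi], v[i, epi],
                                        alternative = "two.sided")$p.value)
  }, numeric(1L))
  p[is.na(p)] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  med_diff <- apply(v[, !epi, drop = FALSE], 1L, stats::median) -
    apply(v[, epi, drop = FALSE], 1L, stats::median)
  data.frame(gene_id = rownames(x),
             p_value = p,
             fdr = fdr,
             direction = ifelse(med_diff >= 0, "up_in_mesenchymal",
                                "down_in_mesenchymal"),
             is_deg = fdr < fdr_threshold,
             stringsAsFactors = FALSE)
}

#' Mine gene pairs with stable within-sample ordering
#'
#' Examines every unordered gene pair over the given (epithelial) samples
#' and keeps those whose strict ordering \code{gene_a > gene_b} holds in at
#' least \code{stability_threshold} of the samples. Ties support neither
#' direction. Each unordered pair is emitted at most once, oriented so that
#' \code{gene_a} is the gene that is higher in the stable (epithelial)
#' pattern.
#'
#' The scan uses constant-size counters per pair with early abandonment, so
#' cohorts of tens of thousands of genes are feasible on one core without
#' materialising an all-pairs-by-all-samples array.
#'
#' @param x Expression matrix restricted to the reference-phenotype
#'   (epithelial) samples.
#' @param stability_threshold Minimum concordant fraction (default 0.99).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{n_concordant}, \code{n_reversed}, \code{stable_fraction}
#'   (= n_concordant / number of samples).
#' @export
findStablePairs <- function(x, stability_threshold = 0.99) {
  x <- .as_expr_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 genes")
  if (ncol(x) < 2L) stop("need at least 2 reference samples")
  if (!is.numeric(stability_threshold) || stability_threshold <= 0 ||
      stability_threshold > 1)
    stop("stability_threshold must lie in (0, 1]")
  res <- .stable_pair_mine(t(x), stability_threshold)
  genes <- rownames(x)
  data.frame(gene_a = genes[res$ia],
             gene_b = genes[res$ib],
             n_concordant = res$n_gt,
             n_reversed = res$n_lt,
             stable_fraction = res$n_gt / ncol(x),
             stringsAsFactors = FALSE)
}

#' Fisher exact p-value for reversal enrichment
#'
#' Exact p-value for the 2x2 table \code{[class x reversed?]} with
#' \code{a} reversed of \code{n_epi} epithelial samples and \code{b}
#' reversed of \code{n_mes} mesenchymal samples. One-sided tests enrichment
#' of the reversed ordering in mesenchymal samples
#' (\eqn{P(X \ge b)} under the hypergeometric null); the two-sided form sums
#' all tables at most as probable as the observed one, matching
#' \code{fisher.test}. Vectorised over tables.
#'
#' @param a Reversed count among epithelial samples.
#' @param n_epi Epithelial sample count.
#' @param b Reversed count among mesenchymal samples.
#' @param n_mes Mesenchymal sample count.
#' @param sidedness \code{"one_sided_greater"} or \code{"two_sided"}.
#' @return Numeric vector of p-values.
#' @examples
#' fisherReversalP(0, 10, 9, 10)  # 11 / choose(20, 10)
#' @export
fisherReversalP <- function(a, n_epi, b, n_mes,
                            sidedness = c("one_sided_greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (any(a < 0 | b < 0 | a > n_epi | b > n_mes))
    stop("counts must satisfy 0 <= a <= n_epi and 0 <= b <= n_mes")
  k <- a + b                      # reversed margin
  if (sidedness == "one_sided_greater") {
    # X ~ Hypergeom(white = k, black = n_epi + n_mes - k, drawn = n_mes)
    return(stats::phyper(b - 1, k, n_epi + n_mes - k, n_mes,
                         lower.tail = FALSE))
  }
  mapply(function(ai, bi, ne, nm) {
    ki <- ai + bi
    support <- max(0L, ki - ne):min(ki, nm)
    d <- stats::dhyper(support, ki, ne + nm - ki, nm)
    obs <- stats::dhyper(bi, ki, ne + nm - ki, nm)
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, a, b, n_epi, n_mes)
}

#' Test stable pairs for REO reversal in mesenchymal samples
#'
#' For each epithelial-stable oriented pair (\code{gene_a > gene_b} in the
#' reference pattern), builds the 2x2 table of reversed
#' (\code{gene_a < gene_b}, strictly; ties count as not reversed) versus
#' not-reversed samples by class, computes the Fisher exact p-value, and
#' records the reversal ratio: the proportion of mesenchymal samples showing
#' the reversed ordering.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b}
#'   (oriented as returned by [findStablePairs()]).
#' @param x Expression matrix covering both classes.
#' @param labels Phenotype labels.
#' @param sidedness Fisher sidedness, see [fisherReversalP()].
#' @param chunk_size Pairs processed per block (memory control).
#' @return data.frame: \code{gene_a}, \code{gene_b},
#'   \code{stable_fraction_epithelial}, \code{reversal_ratio_mesenchymal},
#'   \code{fisher_p}, plus the underlying counts.
#' @export
reversalTest <- function(pairs, x, labels,
                         sidedness = c("one_sided_greater", "two_sided"),
                         chunk_size = 50000L) {
  sidedness <- match.arg(sidedness)
  x <- .as_expr_matrix(x)
  lab <- .align_labels(x, labels)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(pairs)))
    stop("pairs must have columns gene_a, gene_b")
  ia <- match(pairs$gene_a, rownames(x))
  ib <- match(pairs$gene_b, rownames(x))
  if (anyNA(ia) || anyNA(ib))
    stop("pair gene(s) absent from the matrix: ",
         paste(head(unique(c(pairs$gene_a[is.na(ia)],
                             pairs$gene_b[is.na(ib)])), 5L), collapse = ", "))
  epi <- names(lab)[lab == "epithelial"]
  mes <- names(lab)[lab == "mesenchymal"]
  xe <- t(x[, epi, drop = FALSE])
  xm <- t(x[, mes, drop = FALSE])
  n <- nrow(pairs)
  rev_epi <- integer(n); con_epi <- integer(n)
  rev_mes <- integer(n); con_mes <- integer(n)
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(n, start + chunk_size - 1L)
    ce <- .pair_order_counts(xe, ia[idx], ib[idx])
    cm <- .pair_order_counts(xm, ia[idx], ib[idx])
    con_epi[idx] <- ce$n_gt; rev_epi[idx] <- ce$n_lt
    con_mes[idx] <- cm$n_gt; rev_mes[idx] <- cm$n_lt
  }
  data.frame(gene_a = pairs$gene_a,
             gene_b = pairs$gene_b,
             stable_fraction_epithelial = con_epi / length(epi),
             reversal_ratio_mesenchymal = rev_mes / length(mes),
             fisher_p = fisherReversalP(rev_epi, length(epi),
                                        rev_mes, length(mes), sidedness),
             n_reversed_epithelial = rev_epi,
             n_reversed_mesenchymal = rev_mes,
             n_epithelial = length(epi),
             n_mesenchymal = length(mes),
             stringsAsFactors = FALSE)
}

#' Two-step optimisation of reversed pairs into a signature
#'
#' Keeps pairs that are significantly reversed (\code{fisher_p <
#' fisher_alpha}), have a reversal ratio of at least
#' \code{reversal_threshold} among mesenchymal samples, and (when
#' \code{require_deg}) contain at least one differentially expressed gene.
#' The result is ordered by Fisher p ascending, ties broken by reversal
#' ratio descending, then lexicographically. Signature pairs are stored in
#' the mesenchymal-indicative orientation \code{gene_a < gene_b}.
#'
#' @param stats data.frame from [reversalTest()].
#' @param degs data.frame from [identifyDEGs()] (may be \code{NULL} when
#'   \code{config$require_deg} is \code{FALSE}).
#' @param config A [discoveryConfig()].
#' @return A [GenePairSignature-class]; empty (with a warning) when no pair
#'   survives.
#' @export
optimizeSignature <- function(stats, degs = NULL, config = discoveryConfig()) {
  stopifnot(inherits(config, "discovery_config"))
  stats <- as.data.frame(stats, stringsAsFactors = FALSE)
  keep <- stats$fisher_p < config$fisher_alpha &
    stats$reversal_ratio_mesenchymal >= config$reversal_threshold
  if (config$require_deg) {
    if (is.null(degs)) stop("require_deg = TRUE but no DEG table given")
    deg_genes <- degs$gene_id[degs$is_deg]
    keep <- keep & (stats$gene_a %in% deg_genes |
                      stats$gene_b %in% deg_genes)
  }
  sel <- stats[keep, , drop = FALSE]
  if (!nrow(sel)) {
    warning("no gene pair passed the signature filters; empty signature")
    return(GenePairSignature(data.frame(gene_a = character(),
                                        gene_b = character(),
                                        fisher_p = numeric(),
                                        reversal_ratio = numeric(),
                                        stringsAsFactors = FALSE)))
  }
  pair_key <- paste(sel$gene_a, sel$gene_b, sep = "|")
  ord <- order(sel$fisher_p, -sel$reversal_ratio_mesenchymal, pair_key)
  sel <- sel[ord, , drop = FALSE]
  # gene_a stays the epithelial-high gene: the signature records the
  # mesenchymal-indicative *pattern* gene_a < gene_b for that same gene_a
  GenePairSignature(data.frame(
    pair_id = sprintf("pair_%02d", seq_len(nrow(sel))),
    gene_a = sel$gene_a,
    gene_b = sel$gene_b,
    fisher_p = sel$fisher_p,
    reversal_ratio = sel$reversal_ratio_mesenchymal,
    stringsAsFactors = FALSE))
}

#' Discover a gene-pair signature from a labelled cohort
#'
#' Runs the full pipeline: rank-based Wilcoxon DEG screen with BH
#' adjustment, stable-pair mining over epithelial samples, Fisher reversal
#' test in mesenchymal samples, and the two-step optimisation. Deterministic
#' given its inputs, and invariant under any per-sample strictly monotone
#' transform of the expression values.
#'
#' @param x Expression matrix (or SummarizedExperiment).
#' @param labels Phenotype labels covering (a subset of) the samples.
#' @param config A [discoveryConfig()].
#' @return A [GenePairSignature-class].
#' @examples
#' set.seed(1)
#' sim <- generateDataset(syntheticSpec(n_epithelial = 30, n_mesenchymal = 20,
#'                                      n_genes = 40, n_planted_pairs = 3,
#'                                      seed = 1))
#' sig <- discoverSignature(sim$matrix, sim$labels)
#' nPairs(sig)
#' @export
discoverSignature <- function(x, labels, config = discoveryConfig()) {
  stopifnot(inherits(config, "discovery_config"))
  x <- .as_expr_matrix(x)
  lab <- .align_labels(x, labels, min_per_class = 2L)
  x <- x[, names(lab), drop = FALSE]
  degs <- if (config$require_deg)
    identifyDEGs(x, lab, fdr_threshold = config$deg_fdr,
                 on_ranks = config$deg_on_ranks)
  else NULL
  epi <- names(lab)[lab == "epithelial"]
  stable <- findStablePairs(x[, epi, drop = FALSE],
                            config$stability_threshold)
  if (!nrow(stable)) {
    warning("no stable pair at the given threshold; empty signature")
    return(GenePairSignature(data.frame(gene_a = character(),
                                        gene_b = character(),
                                        fisher_p = numeric(),
                                        reversal_ratio = numeric(),
                                        stringsAsFactors = FALSE)))
  }
  stats <- reversalTest(stable, x, lab, sidedness = config$fisher_sidedness)
  optimizeSignature(stats, degs, config)
}
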