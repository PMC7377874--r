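## Synthetic two-phenotype cohorts with planted stable/reversed gene pairs.
##
## The generator emulates the data regime the REO method is designed for: a
## reference (epithelial) phenotype in which a set of gene pairs has an
## essentially fixed within-sample ordering, and a contrast (mesenchymal)
## phenotype in which each such pair flips its ordering in a controllable
## fraction of samples. Expression is log-normal with gene-specific means,
## mimicking microarray-intensity scale; the exact distribution is
## irrelevant to any rank-based downstream step.

#' Parameters of a synthetic two-phenotype cohort
#'
#' @param n_epithelial,n_mesenchymal Sample counts per phenotype.
#' @param n_genes Total genes, including the planted pair members.
#' @param n_planted_pairs Number of planted reversed pairs; uses
#'   \code{2 * n_planted_pairs} dedicated genes.
#' @param reversal_prob Per mesenchymal sample probability that a planted
#'   pair shows the reversed ordering (the expected reversal ratio).
#' @param epithelial_concordance Probability that a planted pair shows its
#'   reference ordering in an epithelial sample (default 1.0, i.e. fully
#'   stable).
#' @param noise_sd Per-gene, per-sample Gaussian noise on the log2 scale.
#' @param mean_spread Standard deviation of the background gene means on the
#'   log2 scale; controls how many incidental (non-planted) stable pairs the
#'   background contains.
#' @param deg_shift Additive log2 shift applied to each planted pair's
#'   right-hand gene in mesenchymal samples, making those genes recoverable
#'   as differentially expressed (the analogue of the published signature's
#'   COL5A2/FAP anchors).
#' @param batch_distortion \code{"none"} or \code{"per_sample_monotone"}
#'   (apply [injectBatchEffects()] to the finished matrix).
#' @param seed Integer seed; all randomness derives from it.
#' @return List of class \code{synthetic_spec}.
#' @export
syntheticSpec <- function(n_epithelial = 150L,
                          n_mesenchymal = 100L,
                          n_genes = 500L,
                          n_planted_pairs = 10L,
                          reversal_prob = 0.85,
                          epithelial_concordance = 1.0,
                          noise_sd = 0.4,
                          mean_spread = 1.5,
                          deg_shift = 1.5,
                          batch_distortion = c("none",
                                               "per_sample_monotone"),
                          seed = 1L) {
  batch_distortion <- match.arg(batch_distortion)
  if (2L * n_planted_pairs > n_genes)
    stop("n_genes must be at least 2 * n_planted_pairs")
  if (n_epithelial < 2L || n_mesenchymal < 2L)
    stop("need at least 2 samples per phenotype")
  for (p in c(reversal_prob, epithelial_concordance))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_epithelial = as.integer(n_epithelial),
                 n_mesenchymal = as.integer(n_mesenchymal),
                 n_genes = as.integer(n_genes),
                 n_planted_pairs = as.integer(n_planted_pairs),
                 reversal_prob = reversal_prob,
                 epithelial_concordance = epithelial_concordance,
                 noise_sd = noise_sd,
                 mean_spread = mean_spread,
                 deg_shift = deg_shift,
                 batch_distortion = batch_distortion,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Named sub-streams derived from the spec seed so that each component
## (gene means, sample noise, reversal draws, distortions) is reproducible
## on its own.
.stream_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("genes", "noise", "reversals", "distortion"))
}

#' Generate a synthetic labelled cohort with planted reversed pairs
#'
#' Background genes share their mean between phenotypes (no class signal).
#' Each planted pair (a, b) receives separated means, a above b, so that
#' \code{a > b} holds in an epithelial sample with probability about
#' \code{epithelial_concordance}; in each mesenchymal sample the pair's
#' means are swapped with probability \code{reversal_prob}, flipping the
#' ordering. Right-hand (b) genes additionally gain \code{deg_shift} in all
#' mesenchymal samples so they are recoverable as up-regulated DEGs. Values
#' are on a linear intensity scale (\code{2^log2value}).
#'
#' Each planted pair occupies its own narrow expression band, separated
#' from the background genes and from other pairs by a guard margin of
#' several noise standard deviations. Isolation makes the planted truth
#' exact: a mean swap inside a band cannot drag any third gene across the
#' pair, so the planted pairs are the only reversed pairs in the cohort and
#' recovery counts are well defined. After assembly the whole log-scale
#' matrix is affinely rescaled into a microarray-like log2 range (about 6 to
#' 16); a single global monotone map alters no within-sample ordering.
#'
#' @param spec A [syntheticSpec()].
#' @return List with \code{matrix} (genes x samples), \code{labels}
#'   ([phenotypeLabels()]), and \code{truth}: a list with \code{pairs}
#'   (data.frame \code{gene_a} (higher in epithelial), \code{gene_b},
#'   \code{reversal_prob}) and \code{deg_genes} (data.frame \code{gene_id},
#'   \code{direction}).
#' @examples
#' sim <- generateDataset(syntheticSpec(n_epithelial = 20, n_mesenchymal = 15,
#'                                      n_genes = 60, n_planted_pairs = 4,
#'                                      seed = 7))
#' dim(sim$matrix)
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seeds <- .stream_seeds(spec$seed)
  n_e <- spec$n_epithelial; n_m <- spec$n_mesenchymal
  n <- n_e + n_m; g <- spec$n_genes; k <- spec$n_planted_pairs

  gene_ids <- sprintf("gene_%04d", seq_len(g))
  sample_ids <- c(sprintf("epi_%03d", seq_len(n_e)),
                  sprintf("mes_%03d", seq_len(n_m)))
  labels <- phenotypeLabels(sample_ids,
                            rep(c("epithelial", "mesenchymal"), c(n_e, n_m)))

  # planted pairs occupy the first 2k genes: (1,2), (3,4), ...
  ia <- if (k) seq(1L, 2L * k, by = 2L) else integer()
  ib <- ia + 1L

  # gene means (log2 scale); background genes share means across phenotypes
  set.seed(seeds[["genes"]])
  mu <- stats::rnorm(g, mean = 8, sd = spec$mean_spread)
  # separation delta so P(a > b) ~= epithelial_concordance under
  # a - b ~ N(2*delta, 2*noise_sd^2)
  conc <- max(min(spec$epithelial_concordance, 1 - 1e-6), 0.5)
  delta <- stats::qnorm(conc) * spec$noise_sd / sqrt(2)
  if (k) {
    # isolated bands above the background: guard of 8 noise sd between the
    # background and the first band and between consecutive bands, so no
    # third gene sits inside a pair's swap range
    guard <- 8 * spec$noise_sd
    spacing <- 2 * delta + max(spec$deg_shift, 0) + guard
    bg_top <- if (g > 2L * k) max(mu[-c(ia, ib)]) else max(mu)
    centre <- bg_top + guard + delta + spacing * (seq_len(k) - 1L)
    mu[ia] <- centre + delta
    mu[ib] <- centre - delta
  }

  m_log <- matrix(mu, nrow = g, ncol = n)

  # mesenchymal-sample modifications: per-sample mean swap of planted pairs,
  # plus the DEG shift on the right-hand genes
  set.seed(seeds[["reversals"]])
  if (k && n_m) {
    flip <- matrix(stats::rbinom(k * n_m, 1L, spec$reversal_prob) == 1L,
                   nrow = k, ncol = n_m)
    for (q in seq_len(k)) {
      cols <- n_e + which(flip[q, ])
      if (length(cols)) {
        m_log[ia[q], cols] <- mu[ib[q]]
        m_log[ib[q], cols] <- mu[ia[q]]
      }
    }
    mes_cols <- n_e + seq_len(n_m)
    m_log[ib, mes_cols] <- m_log[ib, mes_cols, drop = FALSE] + spec$deg_shift
  }

  set.seed(seeds[["noise"]])
  m_log <- m_log + matrix(stats::rnorm(g * n, sd = spec$noise_sd), g, n)

  # one global affine map into a microarray-like log2 range; monotone, so
  # every within-sample ordering (and all planted structure) is unchanged
  rng <- range(m_log)
  if (rng[2] > rng[1])
    m_log <- 6 + 10 * (m_log - rng[1]) / (rng[2] - rng[1])
  x <- 2^m_log
  dimnames(x) <- list(gene_ids, sample_ids)

  if (spec$batch_distortion == "per_sample_monotone")
    x <- injectBatchEffects(x, seed = seeds[["distortion"]])

  truth <- list(
    pairs = data.frame(gene_a = gene_ids[ia], gene_b = gene_ids[ib],
                       reversal_prob = rep(spec$reversal_prob, k),
                       stringsAsFactors = FALSE),
    deg_genes = data.frame(gene_id = gene_ids[ib],
                           direction = rep("up_in_mesenchymal", k),
                           stringsAsFactors = FALSE))
  list(matrix = x, labels = labels, truth = truth)
}

#' Apply per-sample strictly monotone batch distortions
#'
#' Each sample column is passed through an independent strictly increasing
#' transform — a random positive-slope affine map plus a soft-saturation
#' term, \eqn{y = a + b x + c s \tanh((x - m)/s)} with \eqn{b > 0},
#' \eqn{c \ge 0} — emulating scanner gain, additive offsets and dynamic-range
#' compression between batches. Within-sample orderings (and hence ranks,
#' REO-based signatures, and EMT scores) are preserved exactly; column means
#' and variances are not.
#'
#' @param x Expression matrix (or SummarizedExperiment).
#' @param seed Integer seed for the per-sample transform parameters.
#' @return Distorted matrix, same dimensions and dimnames.
#' @export
injectBatchEffects <- function(x, seed = 1L) {
  x <- .as_expr_matrix(x)
  set.seed(seed)
  n <- ncol(x)
  a <- stats::runif(n, -50, 50)
  b <- stats::runif(n, 0.5, 3)
  cc <- stats::runif(n, 0, 2)
  out <- x
  for (j in seq_len(n)) {
    col <- x[, j]
    m <- stats::median(col)
    s <- max(stats::mad(col), 1e-6)
    out[, j] <- a[j] + b[j] * col + cc[j] * s * tanh((col - m) / s)
  }
  out
}
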