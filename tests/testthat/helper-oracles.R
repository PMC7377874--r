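# Independent reference implementations used as oracles. Everything here is
# deliberately naive (double loops, direct counting, explicit hypergeometric
# summation) and shares no code path with the package internals.

# Fisher one-sided p by explicit hypergeometric tail summation:
# P(X >= b) for X = reversed count among the n_mes mesenchymal samples given
# margins (a + b reversed in total, n_epi + n_mes samples).
oracle_fisher_greater <- function(a, n_epi, b, n_mes) {
  k <- a + b
  support <- max(0L, k - n_epi):min(k, n_mes)
  sum(stats::dhyper(support[support >= b], k, n_epi + n_mes - k, n_mes))
}

# Two-sided Fisher p: sum of all tables at most as probable as observed
# (fisher.test convention, with its relative tolerance).
oracle_fisher_two_sided <- function(a, n_epi, b, n_mes) {
  k <- a + b
  support <- max(0L, k - n_epi):min(k, n_mes)
  d <- stats::dhyper(support, k, n_epi + n_mes - k, n_mes)
  obs <- d[support == b]
  min(1, sum(d[d <= obs * (1 + 1e-7)]))
}

# Exact two-sided rank-sum p by full enumeration of all C(n, n1) group
# assignments (tiny n only). Two-sided p = P(|W - E[W]| >= |w_obs - E[W]|).
oracle_ranksum_enum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]))
  w_obs <- sum(r[seq_len(n1)])
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Rank-sum p from the standard formulas, coded independently of
# stats::wilcox.test: midrank U statistic; exact distribution when tie-free
# and groups < 50; otherwise normal approximation with tie and continuity
# correction.
oracle_ranksum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  if (!any(ties > 1) && max(n1, n2) < 50) {
    p <- if (u > n1 * n2 / 2)
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    else
      stats::pwilcox(u, n1, n2)
    return(min(1, 2 * p))
  }
  z <- u - n1 * n2 / 2
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
  if (sigma == 0) return(1)   # every pooled value tied: no evidence
  z <- (z - sign(z) * 0.5) / sigma
  min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
}

# BH step-up adjustment written out directly.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Brute-force stable pair mining: double loop over all unordered pairs and
# all samples, direct counting, inclusive threshold, ties support neither.
oracle_stable_pairs <- function(x, threshold) {
  genes <- rownames(x)
  n <- ncol(x)
  out <- list()
  for (i in seq_len(nrow(x) - 1L)) {
    for (j in (i + 1L):nrow(x)) {
      gt <- sum(x[i, ] > x[j, ])
      lt <- sum(x[i, ] < x[j, ])
      if (gt / n >= threshold)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = genes[i], gene_b = genes[j], n_concordant = gt,
          n_reversed = lt, stable_fraction = gt / n,
          stringsAsFactors = FALSE)
      else if (lt / n >= threshold)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = genes[j], gene_b = genes[i], n_concordant = lt,
          n_reversed = gt, stable_fraction = lt / n,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      n_concordant = integer(), n_reversed = integer(),
                      stable_fraction = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Brute-force full discovery: oracle DEGs + oracle mining + oracle Fisher +
# the published filters, returning the signature pair table.
oracle_discover <- function(x, labels, config) {
  epi <- names(labels)[labels == "epithelial"]
  mes <- names(labels)[labels == "mesenchymal"]
  # DEGs on within-sample ranks
  r <- apply(x, 2L, rank)
  p <- vapply(seq_len(nrow(x)), function(i)
    oracle_ranksum_p(r[i, mes], r[i, epi]), numeric(1L))
  fdr <- oracle_bh(p)
  deg_genes <- rownames(x)[fdr < config$deg_fdr]

  stable <- oracle_stable_pairs(x[, epi, drop = FALSE],
                                config$stability_threshold)
  if (!nrow(stable)) return(stable[, c("gene_a", "gene_b")])
  rows <- lapply(seq_len(nrow(stable)), function(k) {
    a <- stable$gene_a[k]; b <- stable$gene_b[k]
    rev_epi <- sum(x[a, epi] < x[b, epi])
    rev_mes <- sum(x[a, mes] < x[b, mes])
    data.frame(gene_a = a, gene_b = b,
               fisher_p = oracle_fisher_greater(rev_epi, length(epi),
                                                rev_mes, length(mes)),
               reversal_ratio = rev_mes / length(mes),
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, rows)
  keep <- st$fisher_p < config$fisher_alpha &
    st$reversal_ratio >= config$reversal_threshold
  if (config$require_deg)
    keep <- keep & (st$gene_a %in% deg_genes | st$gene_b %in% deg_genes)
  sel <- st[keep, , drop = FALSE]
  sel <- sel[order(sel$fisher_p, -sel$reversal_ratio,
                   paste(sel$gene_a, sel$gene_b, sep = "|")), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

# Brute-force AUC: fraction of (mesenchymal, epithelial) score pairs with
# the mesenchymal sample strictly higher, half credit for ties.
oracle_auc <- function(scores, is_mes) {
  sm <- scores[is_mes]; se <- scores[!is_mes]
  tot <- 0
  for (a in sm) for (b in se)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sm) * length(se))
}

# Small labelled random cohort with per-gene mean spread and a few genuinely
# class-shifted genes, used for oracle-equivalence checks.
random_cohort <- function(seed, n_genes = 25, n_epi = 20, n_mes = 20,
                          n_shifted = 4, shift = 3, spread = 2, sd = 1) {
  set.seed(seed)
  g <- n_genes; n <- n_epi + n_mes
  mu <- rnorm(g, 8, spread)
  x <- matrix(rnorm(g * n, mu, sd), g, n)
  if (n_shifted)
    x[seq_len(n_shifted), n_epi + seq_len(n_mes)] <-
      x[seq_len(n_shifted), n_epi + seq_len(n_mes)] + shift
  dimnames(x) <- list(sprintf("g%02d", seq_len(g)),
                      sprintf("s%02d", seq_len(n)))
  labels <- phenotypeLabels(colnames(x),
                            rep(c("epithelial", "mesenchymal"),
                                c(n_epi, n_mes)))
  list(matrix = x, labels = labels)
}

# A strictly increasing transform with random per-sample parameters.
random_monotone <- function(x, seed) {
  set.seed(seed)
  out <- x
  for (j in seq_len(ncol(x))) {
    a <- runif(1, -10, 10); b <- runif(1, 0.2, 4); p <- runif(1, 0.5, 2)
    v <- x[, j]
    out[, j] <- a + b * sign(v) * abs(v)^p
  }
  out
}
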