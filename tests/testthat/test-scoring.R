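# EMT scoring: per-sample score in [0,1], 0.5 decision rule, missing-gene
# policies, and the single-sample sufficiency / monotone-invariance
# guarantees that make the classifier usable on individual patients.

# helper: a sample (named vector) in which exactly k of the signature's
# pairs show the reversed, mesenchymal-indicative ordering gene_a < gene_b.
# The 16-GPS anchors (gene_b: COL5A2, FAP) are shared across pairs, so the
# anchors get fixed values and each unique partner gene_a is placed below
# its anchor (reversed) or above it (epithelial pattern).
sample_with_reversals <- function(signature, k) {
  p <- signaturePairs(signature)
  anchors <- unique(p$gene_b)
  v <- setNames(1000 * seq_along(anchors), anchors)
  for (i in seq_len(nrow(p))) {
    off <- 10 * i
    v[p$gene_a[i]] <- v[p$gene_b[i]] + (if (i <= k) -off else off)
  }
  v
}

test_that("rank differences carry the pairwise ordering sign", {
  v <- c(gA = 10, gB = 40, gC = 40)
  expect_lt(rankDifference(v, c("gA", "gB")), 0)   # reversed pattern
  expect_gt(rankDifference(v, c("gB", "gA")), 0)
  expect_equal(rankDifference(v, c("gB", "gC")), 0)  # tie: never reversed
  expect_true(is.na(rankDifference(v, c("gA", "gZ"))))
})

test_that("EMT score spans [0,1] with the 0.5 rule classifying mesenchymal", {
  sig <- builtinSignature()
  all_rev <- emtScore(sample_with_reversals(sig, 16), sig)
  expect_equal(all_rev$emt_score, 1)
  expect_identical(all_rev$label, "mesenchymal_like")

  none <- emtScore(sample_with_reversals(sig, 0), sig)
  expect_equal(none$emt_score, 0)
  expect_identical(none$label, "epithelial_like")

  # 8 of 16 reversed -> score exactly 0.5 -> mesenchymal-like (>= rule)
  half <- emtScore(sample_with_reversals(sig, 8), sig)
  expect_equal(half$emt_score, 0.5)
  expect_identical(half$label, "mesenchymal_like")

  # ties are not reversed: force value equality on one pair
  v <- sample_with_reversals(sig, 0)
  p <- signaturePairs(sig)
  v[p$gene_a[1]] <- v[p$gene_b[1]]
  expect_equal(emtScore(v, sig)$emt_score, 0)
})

test_that("scores are quantised to multiples of 1/k and complementary", {
  sig <- builtinSignature()
  set.seed(12)
  flipped <- GenePairSignature(within(signaturePairs(sig), {
    tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp; tmp <- NULL
  })[, c("pair_id", "gene_a", "gene_b", "fisher_p", "reversal_ratio")])
  for (i in 1:10) {
    v <- setNames(runif(18, 1, 100), signatureGenes(sig))
    r <- emtScore(v, sig)
    expect_true(r$emt_score %in% (0:16 / 16))
    # no ties (continuous draws): flipping every pair complements the score
    expect_equal(emtScore(v, flipped)$emt_score, 1 - r$emt_score)
  }
})

test_that("a sample's score is independent of the rest of the cohort", {
  sim <- generateDataset(syntheticSpec(n_epithelial = 15, n_mesenchymal = 15,
                                       n_genes = 60, n_planted_pairs = 4,
                                       seed = 8))
  sig <- discoverSignature(sim$matrix, sim$labels)
  full <- scoreCohort(sim$matrix, sig)
  # single-sample call equals the cohort row
  one <- emtScore(sim$matrix[, 7], sig)
  expect_equal(one$emt_score, full$emt_score[7])
  # random cohort subsets leave every retained sample's score unchanged
  set.seed(5)
  for (i in 1:5) {
    keep <- sort(sample(ncol(sim$matrix), 10))
    sub <- scoreCohort(sim$matrix[, keep], sig)
    expect_equal(sub$emt_score, full$emt_score[keep])
    expect_identical(sub$sample_id, full$sample_id[keep])
  }
})

test_that("scores are invariant under per-sample monotone distortion", {
  sim <- generateDataset(syntheticSpec(n_epithelial = 12, n_mesenchymal = 12,
                                       n_genes = 50, n_planted_pairs = 3,
                                       seed = 9))
  sig <- discoverSignature(sim$matrix, sim$labels)
  base <- scoreCohort(sim$matrix, sig)
  for (s in 1:5) {
    expect_identical(scoreCohort(random_monotone(sim$matrix, s), sig),
                     base)
    expect_identical(scoreCohort(injectBatchEffects(sim$matrix, s), sig),
                     base)
  }
})

test_that("missing signature genes follow the chosen policy", {
  sig <- builtinSignature()
  v <- sample_with_reversals(sig, 16)
  # drop COL5A2: its 6 pairs become unevaluable, 10 of 16 remain
  v_missing <- v[setdiff(names(v), "COL5A2")]
  r <- emtScore(v_missing, sig)                     # renormalize (default)
  expect_identical(r$n_pairs_evaluated, 10L)
  expect_identical(r$n_pairs_total, 16L)
  expect_equal(r$emt_score, 1)                      # 10/10 reversed
  # strict mode refuses any missing gene
  expect_error(emtScore(v_missing, sig, missing_policy = "strict"),
               "strict.*COL5A2")
  # more than half the pairs unevaluable -> hard error naming the genes
  v_few <- v[setdiff(names(v), "FAP")]              # 10 of 16 pairs lost
  expect_error(emtScore(v_few, sig), "10 of 16.*FAP")
  # zero evaluable pairs -> error
  expect_error(emtScore(c(X = 1, Y = 2), sig), "no signature pair")
})

test_that("scoring the packaged signature on expression data works end to end", {
  sig <- builtinSignature()
  set.seed(77)
  genes <- c(signatureGenes(sig), sprintf("filler_%02d", 1:20))
  x <- matrix(2^rnorm(length(genes) * 6, 8, 2), length(genes), 6,
              dimnames = list(genes, paste0("s", 1:6)))
  sc <- scoreCohort(x, sig)
  expect_identical(nrow(sc), 6L)
  expect_true(all(sc$emt_score >= 0 & sc$emt_score <= 1))
  expect_identical(sc$label,
                   ifelse(sc$emt_score >= 0.5, "mesenchymal_like",
                          "epithelial_like"))
})
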