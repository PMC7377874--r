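# Discovery pipeline: DEG screen, stable-pair mining, reversal test,
# two-step optimisation.

test_that("rank-sum DEG screen reproduces exact small-sample p-values", {
  # gene with within-sample ranks 1,2,3 (epithelial) vs 4,5,6 (mesenchymal):
  # enumeration of all C(6,3) = 20 assignments gives two-sided p = 0.1
  expect_equal(oracle_ranksum_enum(c(4, 5, 6), c(1, 2, 3)), 0.1)

  x <- rbind(gA = c(1, 2, 3, 4, 5, 6),
             gB = c(6, 5, 4, 3, 2, 1),
             gC = c(2, 2, 2, 2, 2, 2))
  colnames(x) <- paste0("s", 1:6)
  lab <- phenotypeLabels(colnames(x),
                         rep(c("epithelial", "mesenchymal"), each = 3))
  res <- identifyDEGs(x, lab, fdr_threshold = 0.05, on_ranks = FALSE)
  expect_equal(res$p_value[res$gene_id == "gA"], 0.1)
  expect_equal(res$p_value[res$gene_id == "gB"], 0.1)
  # identical distributions in both classes -> p = 1, not a DEG
  expect_equal(res$p_value[res$gene_id == "gC"], 1)
  expect_false(res$is_deg[res$gene_id == "gC"])
  expect_identical(res$direction[res$gene_id == "gA"], "up_in_mesenchymal")
  expect_identical(res$direction[res$gene_id == "gB"], "down_in_mesenchymal")
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  # frozen example: p = (0.01, 0.02, 0.03, 0.04), m = 4 -> all adjusted 0.04
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(7)
  for (i in 1:10) {
    p <- runif(50)^2
    adj <- p.adjust(p, "BH")
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("DEG screen requires two samples per class", {
  x <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  lab <- phenotypeLabels(colnames(x),
                         c("epithelial", rep("mesenchymal", 3)))
  expect_error(identifyDEGs(x, lab), "at least 2")
})

test_that("stable-pair mining counts strict orderings with an inclusive threshold", {
  # consistent order A > B > C in all 5 samples -> all 3 pairs stable
  x <- matrix(rep(c(30, 20, 10), 5), nrow = 3,
              dimnames = list(c("A", "B", "C"), paste0("s", 1:5)))
  st <- findStablePairs(x, 0.99)
  expect_identical(nrow(st), 3L)
  expect_setequal(paste(st$gene_a, st$gene_b), c("A B", "A C", "B C"))
  expect_true(all(st$stable_fraction == 1))

  # concordant in 4 of 5 samples: 0.8 < 0.99 -> not stable
  x2 <- x
  x2["A", "s5"] <- 15  # now B > A in s5
  st2 <- findStablePairs(x2, 0.99)
  expect_false("A B" %in% paste(st2$gene_a, st2$gene_b))
  # ... but stable at a 0.8 threshold (inclusive reading)
  st3 <- findStablePairs(x2, 0.8)
  expect_true("A B" %in% paste(st3$gene_a, st3$gene_b))
  expect_equal(st3$stable_fraction[paste(st3$gene_a, st3$gene_b) == "A B"],
               0.8)

  # ties support neither direction
  xt <- matrix(c(1, 1, 1, 1, 2, 1), nrow = 2,
               dimnames = list(c("A", "B"), paste0("s", 1:3)))
  expect_identical(nrow(findStablePairs(xt, 0.9)), 0L)
})

test_that("stable-pair mining equals the brute-force double loop", {
  for (s in 1:8) {
    co <- random_cohort(seed = 100 + s, n_genes = 20, n_epi = 30, n_mes = 0,
                        n_shifted = 0)
    for (thr in c(0.99, 0.9, 0.75)) {
      got <- findStablePairs(co$matrix, thr)
      want <- oracle_stable_pairs(co$matrix, thr)
      key <- function(d) d[order(d$gene_a, d$gene_b), , drop = FALSE]
      got <- key(got); want <- key(want)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  }
})

test_that("Fisher reversal p-values match exact hypergeometric summation", {
  # epithelial 0/10 reversed, mesenchymal 9/10 reversed
  p <- fisherReversalP(0, 10, 9, 10)
  expect_equal(p, 11 / choose(20, 10))       # = 10 / choose(20, 9)
  expect_equal(p, oracle_fisher_greater(0, 10, 9, 10))
  # no association: 5/10 vs 5/10 -> two-sided p = 1; the one-sided tail
  # includes the symmetric middle term (~0.67), never signalling enrichment
  expect_equal(fisherReversalP(5, 10, 5, 10, "two_sided"), 1)
  expect_equal(fisherReversalP(5, 10, 5, 10),
               oracle_fisher_greater(5, 10, 5, 10))
  expect_gt(fisherReversalP(5, 10, 5, 10), 0.6)
  # agreement with fisher.test on both sidedness settings
  set.seed(3)
  for (i in 1:25) {
    ne <- sample(2:40, 1); nm <- sample(2:40, 1)
    a <- sample(0:ne, 1); b <- sample(0:nm, 1)
    tab <- matrix(c(ne - a, a, nm - b, b), 2)
    expect_equal(fisherReversalP(a, ne, b, nm),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(fisherReversalP(a, ne, b, nm, "two_sided"),
                 fisher.test(tab)$p.value, tolerance = 1e-12)
    expect_equal(fisherReversalP(a, ne, b, nm, "two_sided"),
                 oracle_fisher_two_sided(a, ne, b, nm), tolerance = 1e-12)
  }
})

test_that("reversalTest builds the published statistics per pair", {
  # 10 epithelial samples all A > B; 9 of 10 mesenchymal reversed
  xe <- rbind(A = rep(10, 10), B = rep(5, 10))
  xm <- rbind(A = c(rep(1, 9), 10), B = c(rep(5, 9), 5))
  x <- cbind(xe, xm)
  colnames(x) <- paste0("s", 1:20)
  lab <- phenotypeLabels(colnames(x),
                         rep(c("epithelial", "mesenchymal"), each = 10))
  st <- reversalTest(data.frame(gene_a = "A", gene_b = "B"), x, lab)
  expect_equal(st$stable_fraction_epithelial, 1)
  expect_equal(st$reversal_ratio_mesenchymal, 0.9)
  expect_equal(st$fisher_p, 11 / choose(20, 10))
  # the published reversal ratio of the leading pair: 138 of 172
  # mesenchymal samples reversed -> 80.23%
  expect_equal(round(138 / 172, 4), 0.8023)
  expect_error(reversalTest(data.frame(gene_a = "A", gene_b = "Z"), x, lab),
               "absent")
})

test_that("two-step optimisation applies all three filters and the ordering", {
  degs <- data.frame(gene_id = c("D1", "D2"), p_value = 0, fdr = 0,
                     direction = "up_in_mesenchymal", is_deg = TRUE)
  stats <- data.frame(
    gene_a = c("D1", "D2", "N1", "D1", "D2"),
    gene_b = c("N2", "N3", "N4", "N5", "N6"),
    stable_fraction_epithelial = 1,
    reversal_ratio_mesenchymal = c(0.80, 0.70, 0.80, 0.75, 0.90),
    fisher_p = c(1e-6, 1e-6, 1e-6, 1e-6, 0.2))
  sig <- optimizeSignature(stats, degs, discoveryConfig())
  p <- signaturePairs(sig)
  # kept: row 1 (all filters), row 4 (ratio exactly 0.75 is inclusive);
  # dropped: row 2 (ratio < .75), row 3 (no DEG member), row 5 (p >= alpha)
  expect_identical(paste(p$gene_a, p$gene_b), c("D1 N2", "D1 N5"))
  # ordering: fisher_p ascending, ties by reversal ratio descending
  expect_true(all(diff(p$fisher_p) >= 0))
  # require_deg off keeps the non-DEG pair
  sig2 <- optimizeSignature(stats, NULL, discoveryConfig(require_deg = FALSE))
  expect_true("N1 N4" %in% with(signaturePairs(sig2), paste(gene_a, gene_b)))
  # nothing survives -> warning and an empty signature, not an error
  expect_warning(
    empty <- optimizeSignature(stats[5, ], degs, discoveryConfig()),
    "no gene pair")
  expect_identical(nPairs(empty), 0L)
})

test_that("discovery recovers planted pairs, is deterministic, and nulls out", {
  sim <- generateDataset(syntheticSpec(n_epithelial = 60, n_mesenchymal = 40,
                                       n_genes = 120, n_planted_pairs = 5,
                                       reversal_prob = 0.9, seed = 21))
  sig <- discoverSignature(sim$matrix, sim$labels)
  truth <- paste(sim$truth$pairs$gene_a, sim$truth$pairs$gene_b)
  found <- with(signaturePairs(sig), paste(gene_a, gene_b))
  expect_setequal(found, truth)            # all 5 planted, nothing else

  # determinism
  sig2 <- discoverSignature(sim$matrix, sim$labels)
  expect_identical(signaturePairs(sig), signaturePairs(sig2))

  # permuted labels -> empty or near-empty signature
  set.seed(99)
  perm <- setNames(sample(as.character(sim$labels)), names(sim$labels))
  sigp <- suppressWarnings(
    discoverSignature(sim$matrix, phenotypeLabels(perm)))
  expect_lte(nPairs(sigp), 1L)
})

test_that("discovered signatures are invariant under monotone distortion", {
  sim <- generateDataset(syntheticSpec(n_epithelial = 40, n_mesenchymal = 30,
                                       n_genes = 80, n_planted_pairs = 4,
                                       seed = 31))
  s0 <- discoverSignature(sim$matrix, sim$labels)
  for (s in 1:3) {
    xd <- random_monotone(sim$matrix, seed = 400 + s)
    expect_identical(signaturePairs(discoverSignature(xd, sim$labels)),
                     signaturePairs(s0))
  }
})
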