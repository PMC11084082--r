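test_that("fold enrichment follows the IP/Input definition", {
  expect_equal(compute_fold_enrichment(100, 100, 1, 1, pseudocount = 0),
               1.0)
  # library-size normalization: chip library twice as deep
  expect_equal(compute_fold_enrichment(50, 10, 2, 1, pseudocount = 0),
               2.5)
  # pseudocount keeps empty-input windows finite
  expect_true(is.finite(compute_fold_enrichment(10, 0, 1, 1,
                                                pseudocount = 0.5)))
  expect_error(compute_fold_enrichment(-1, 5), "non-negative")
})

test_that("strain-specificity thresholds are inclusive and symmetric", {
  expect_equal(classify_strain_specificity(2.5, 1.5), "A_specific")
  expect_equal(classify_strain_specificity(1.5, 2.5), "B_specific")
  expect_equal(classify_strain_specificity(2.0, 2.0), "conserved")
  expect_equal(classify_strain_specificity(2.49, 1.5), "conserved")
})

test_that("classifier equals direct inequality evaluation on an FE grid", {
  g <- seq(0, 4, by = 0.1)
  fe <- expand.grid(a = g, b = g)
  got <- classify_strain_specificity(fe$a, fe$b)
  want <- ifelse(fe$a >= 2.5 & fe$b <= 1.5, "A_specific",
                 ifelse(fe$b >= 2.5 & fe$a <= 1.5, "B_specific",
                        "conserved"))
  expect_identical(got, want)
})

test_that("classification is invariant to replicate order and library scale", {
  set.seed(9)
  fe_a <- matrix(runif(60, 0, 4), 20)
  fe_b <- matrix(runif(60, 0, 4), 20)
  expect_identical(classify_strain_specificity(fe_a, fe_b),
                   classify_strain_specificity(fe_a[, c(3, 1, 2)],
                                               fe_b[, c(2, 3, 1)]))
  # joint library scaling cancels inside FE
  chip <- rpois(20, 100); input <- rpois(20, 50)
  fe1 <- compute_fold_enrichment(chip, input, 1e6, 1e6)
  fe2 <- compute_fold_enrichment(chip, input, 3e6, 3e6)
  expect_equal(fe1, fe2)
})

test_that("SNP density arithmetic and the no-SNP exclusion flag", {
  peaks <- genomic_intervals("chr1", c(0, 20000), c(10000, 21000))
  snps <- snp_table("chr1", sort(sample(0:9999, 63)),
                    rep("A", 63), rep("G", 63))
  sd <- snp_density_summary(peaks, snps)
  expect_equal(sd$per_peak$snp_density[1], 6.3)
  expect_true(sd$per_peak$no_snp[2])
  expect_equal(sd$per_peak$n_snps[2], 0)
})

test_that("CRE overlap fraction matches a naive pairwise check", {
  set.seed(11)
  peaks <- random_intervals(200)
  cres <- random_intervals(150)
  cres$name <- sample(c("dELS", "PLS"), 150, replace = TRUE)
  got <- cre_overlap_fraction(peaks, cres)
  expect_equal(got$fraction, mean(naive_overlaps_any(peaks, cres)))
  # disjoint sets give zero
  far <- genomic_intervals("chr9", 0, 10)
  far$name <- "dELS"
  expect_equal(cre_overlap_fraction(peaks, far)$fraction, 0)
})

test_that("permutation p-values respect the add-one floor", {
  set.seed(13)
  gs <- c(chr1 = 1e6)
  target <- genomic_intervals("chr1", seq(0, 9000, 1000), seq(0, 9000, 1000) + 500)
  query <- target  # perfect overlap; shuffled queries rarely hit
  pt <- permutation_association_test(query, target, gs, n_perm = 999,
                                     seed = 1)
  expect_true(max(pt$null) < pt$observed)
  expect_equal(pt$p_value, 0.001)
  pt99 <- permutation_association_test(query, target, gs, n_perm = 99,
                                       seed = 1)
  expect_equal(pt99$p_value, 0.01)
  expect_true(pt$p_value >= 1 / (pt$n_perm + 1))
  expect_error(permutation_association_test(
    genomic_intervals("chr1", 0, 2e6), target, gs, n_perm = 9),
    "longer than its chromosome")
})

test_that("planted strain effects are recovered from simulated counts", {
  recalls <- precisions <- numeric(3)
  for (i in 1:3) {
    cfg <- tiny_config(seed = 20 + i, n_peaks = 100,
                       chrom_length = 1e6)
    sim <- simulate_genome_pair(cfg)
    chip <- simulate_chip_counts(sim, cfg)
    pk <- analyze_peaks(chip, snps = sim$truth$snps,
                        cres = sim$truth$cres)
    tr <- sim$truth$peaks
    spec <- tr$strain_true != "conserved"
    recalls[i] <- mean(pk$strain_class[spec] == tr$strain_true[spec])
    called <- pk$strain_class != "conserved"
    precisions[i] <- mean(tr$strain_true[called] ==
                            pk$strain_class[called])
  }
  expect_gte(mean(recalls), 0.9)
  expect_gte(mean(precisions), 0.9)
})
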