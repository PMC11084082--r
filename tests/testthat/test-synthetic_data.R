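test_that("the generator is bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 31)
  s1 <- simulate_genome_pair(cfg)
  s2 <- simulate_genome_pair(cfg)
  expect_identical(s1$genome_a, s2$genome_a)
  expect_identical(s1$genome_b, s2$genome_b)
  expect_identical(s1$truth$snps, s2$truth$snps)
  expect_identical(simulate_chip_counts(s1, cfg)$counts,
                   simulate_chip_counts(s2, cfg)$counts)
})

test_that("SNP divergence matches the configured rate", {
  cfg <- tiny_config(seed = 32, chrom_length = 1e6,
                     n_motif_gain_hyper = 0, n_motif_loss_hypo = 0)
  sim <- simulate_genome_pair(cfg)
  n <- nrow(sim$truth$snps)
  expected <- cfg$snp_rate * cfg$chrom_length
  sd3 <- 3 * sqrt(expected * (1 - cfg$snp_rate))
  expect_lt(abs(n - expected), sd3)
  # outgroup carries the ancestral base at every SNP
  snps <- sim$truth$snps
  i <- sample(nrow(snps), 50)
  og <- substring(sim$outgroup[["chr1"]], snps$anc_pos[i] + 1,
                  snps$anc_pos[i] + 1)
  expect_identical(og, snps$ancestral[i])
})

test_that("L1 truncation lengths follow the configured fractions", {
  set.seed(33)
  lens <- acetylodiff:::sample_l1_length(
    1000, c(0.60, 0.26, 0.09, 0.03, 0.02), 6000)
  p_hat <- mean(lens < 400)
  expect_lt(abs(p_hat - 0.60), 3 * sqrt(0.6 * 0.4 / 1000))
  expect_true(all(lens >= 100 & lens <= 6000))
})

test_that("every planted L1 insertion is a 3'-anchored consensus suffix", {
  cfg <- tiny_config(seed = 34)
  sim <- simulate_genome_pair(cfg)
  lib <- sim$truth$library
  ins <- sim$truth$insertions
  l1 <- ins[ins$class == "L1", ]
  for (i in seq_len(nrow(l1))) {
    s <- if (l1$strand[i] == "-") rc(l1$seq[i]) else l1$seq[i]
    expect_identical(s, substr(lib$L1, nchar(lib$L1) - nchar(s) + 1,
                               nchar(lib$L1)))
  }
  # and the planted sequence really sits in the carrier genome
  a1 <- l1[l1$carrier == "A", ][1, ]
  expect_identical(substr(sim$genome_a[[a1$chrom]], a1$start_a + 1,
                          a1$end_a), a1$seq)
})

test_that("generative allele-frequency expectations hold", {
  cfg <- tiny_config(seed = 35, n_peaks = 150, chrom_length = 1.2e6,
                     fraction_cis_effect = 0.3,
                     fraction_trans_effect = 0.3,
                     cis_effect_size = 5)
  sim <- simulate_genome_pair(cfg)
  chip <- simulate_chip_counts(sim, cfg)
  tr <- sim$truth$peaks
  fr <- allele_frequency(chip$counts[, "F1a_alleleA"],
                         chip$counts[, "F1a_alleleB"])
  cis_a <- tr$effect_type == "cis" & tr$cis_a > tr$cis_b &
    tr$dip_a == 1 & tr$dip_b == 1
  # cis ratio 5:1 implies an expected hyper-allele frequency of 5/6
  expect_lt(abs(mean(fr[cis_a], na.rm = TRUE) - 5 / 6), 0.02)
  trans <- tr$effect_type == "trans"
  # trans effects cancel between the alleles of one hybrid nucleus
  expect_lt(abs(mean(fr[trans], na.rm = TRUE) - 0.5), 0.03)
})

test_that("a dip-adjacent peak shows the expected strain FE ratio", {
  cfg <- tiny_config(seed = 36, n_peaks = 80, chrom_length = 1e6,
                     n_peaks_near_insertion = 6)
  sim <- simulate_genome_pair(cfg)
  tr <- sim$truth$peaks
  near <- tr$near_insertion
  expect_true(any(near))
  # dip applies to the A allele only: FE_B / FE_A = 1 / dip_factor
  expect_equal(tr$fe_b_true[near] / tr$fe_a_true[near],
               rep(1 / cfg$dip_factor, sum(near)))
})

test_that("read simulation respects coverage, origin names, and purity", {
  cfg <- tiny_config(seed = 37, chrom_length = 4e5, coverage = 2)
  sim <- simulate_genome_pair(cfg)
  reads <- simulate_reads(sim$genome_b, cfg)
  expected_n <- ceiling(cfg$coverage * sum(nchar(sim$genome_b)) /
                          cfg$read_length)
  expect_equal(length(reads), expected_n)
  # error-free reads are exact substrings (up to reverse complement)
  i <- sample(length(reads), 25)
  meta <- strsplit(names(reads)[i], "|", fixed = TRUE)
  for (j in seq_along(i)) {
    m <- meta[[j]]
    sub <- substr(sim$genome_b[[m[2]]], as.numeric(m[3]) + 1,
                  as.numeric(m[3]) + cfg$read_length)
    expect_identical(reads[[i[j]]], if (m[4] == "-") rc(sub) else sub)
  }
  expect_identical(simulate_reads(sim$genome_b, cfg), reads)
  cfg2 <- tiny_config(read_length = 1e6)
  expect_error(simulate_reads(sim$genome_b, cfg2), "read_length")
})

test_that("expression ratios couple to promoter cis effects", {
  cfg <- tiny_config(seed = 38, coupling = 1)
  sim <- simulate_genome_pair(cfg)
  g <- sim$truth$genes
  pk <- sim$truth$peaks
  cis_ratio <- pk$cis_a[match(g$promoter_peak, pk$feature_id)] /
    pk$cis_b[match(g$promoter_peak, pk$feature_id)]
  expect_equal(stats::cor(rank(g$expr_ratio), rank(cis_ratio)), 1,
               tolerance = 1e-9)
  # a 4:1 ratio sits exactly at the A-biased boundary frequency of 0.8
  expect_equal(4 / (1 + 4), 0.8)
  ec <- simulate_expression_counts(sim, cfg)
  fr <- allele_frequency(ec$counts[, "F1a_alleleA"],
                         ec$counts[, "F1a_alleleB"])
  neutral <- abs(g$expr_ratio - 1) < 1e-9
  expect_lt(abs(mean(fr[neutral]) - 0.5), 0.03)
})
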