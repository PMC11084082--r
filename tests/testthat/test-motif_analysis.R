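test_that("PWM construction: log-odds identities and pseudocount shrinkage", {
  # uniform counts against a uniform background score zero everywhere
  p <- pwm_from_counts(matrix(10, 4, 6), pseudocount = 0.1)
  expect_true(all(abs(p$log_odds) < 1e-12))
  # a pure column at pseudocount 0: log2(1 / 0.25) = 2, rest sentinel
  p2 <- pwm_from_counts(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(p2$log_odds[1, 1]), 2)
  expect_true(all(p2$log_odds[2:4, 1] <= -30))
  # increasing pseudocount shrinks every log-odds toward zero
  set.seed(51)
  cnt <- matrix(rpois(4 * 8, 6), 4, 8)
  lo1 <- pwm_from_counts(cnt, pseudocount = 0.1)$log_odds
  lo2 <- pwm_from_counts(cnt, pseudocount = 2)$log_odds
  expect_true(all(abs(lo2) <= abs(lo1) + 1e-12))
})

test_that("width-1 tail probabilities are the summed background mass", {
  p <- pwm_from_counts(matrix(c(6, 2, 1, 1), 4, 1), pseudocount = 0)
  d <- score_pvalue_distribution(p, granularity = 1e-4)
  for (b in 1:4) {
    s <- p$log_odds[b, 1]
    want <- sum(p$background[p$log_odds[, 1] >= s - 1e-9])
    expect_equal(pwm_tail_p(d, s), want, tolerance = 1e-9)
  }
})

test_that("DP score null equals brute-force enumeration up to width 8", {
  set.seed(52)
  for (w in c(5, 8)) {
    cnt <- matrix(rpois(4 * w, 8) + 1, 4, w)
    bg <- c(0.3, 0.2, 0.2, 0.3)
    p <- pwm_from_counts(cnt, pseudocount = 0.25, background = bg)
    g <- 1e-3
    d <- score_pvalue_distribution(p, granularity = g)
    scores <- sort(sample(seq(sum(apply(p$log_odds, 2, min)),
                              sum(apply(p$log_odds, 2, max)),
                              length.out = 25)))
    # exact agreement when the oracle uses the same discretized scores
    bf_disc <- brute_force_tail(p, scores, granularity = g)
    dp <- pwm_tail_p(d, scores)
    expect_equal(dp, bf_disc, tolerance = 1e-9)
    # and agreement within the discretization bound on raw scores
    bf_raw <- brute_force_tail(p, scores)
    lo_bracket <- brute_force_tail(p, scores + g * w)
    hi_bracket <- brute_force_tail(p, scores - g * w)
    expect_true(all(dp >= lo_bracket - 1e-9 & dp <= hi_bracket + 1e-9))
    expect_true(all(bf_raw >= lo_bracket - 1e-9 &
                      bf_raw <= hi_bracket + 1e-9))
  }
})

test_that("Monte-Carlo hit rate matches the exact null at the threshold", {
  set.seed(53)
  cnt <- matrix(rpois(4 * 10, 8) + 1, 4, 10)
  p <- pwm_from_counts(cnt, pseudocount = 0.25)
  d <- score_pvalue_distribution(p)
  thr_idx <- min(which(d$tail <= 1e-4))
  exact_rate <- d$tail[thr_idx]
  seq1 <- random_dna(4e5)
  hits <- scan_sequence(p, seq1, p_threshold = 1e-4, dist = d)
  n_pos <- 2 * (nchar(seq1) - p$width + 1)
  expect_lt(abs(nrow(hits) - n_pos * exact_rate),
            3 * sqrt(n_pos * exact_rate) + 1)
})

test_that("allele scanning flips on a single high-information SNP", {
  pw <- default_pwm()
  cons <- paste(apply(pw$prob, 2, function(x)
    c("A", "C", "G", "T")[which.max(x)]), collapse = "")
  pad <- function(m) paste0(strrep("A", 30), m, strrep("C", 30))
  broken <- paste0("A", substr(cons, 2, nchar(cons)))
  sc <- scan_alleles(pw, pad(cons), pad(broken))
  expect_true(sc$presence_a)
  expect_false(sc$presence_b)
  expect_true(sc$differential)
  # identical alleles are never differential
  sc2 <- scan_alleles(pw, pad(cons), pad(cons))
  expect_false(sc2$differential)
  # reverse-complementing both sequences leaves presence unchanged
  sc3 <- scan_alleles(pw, rc(pad(cons)), rc(pad(broken)))
  expect_equal(c(sc3$presence_a, sc3$presence_b),
               c(sc$presence_a, sc$presence_b))
})

test_that("association chi-square is symmetric and degenerate-safe", {
  a <- motif_acetylation_association(14, 4)
  expect_equal(a$chisq, 50 / 9)
  expect_lt(a$p_value, 0.05)
  b <- motif_acetylation_association(4, 14)
  expect_equal(a$chisq, b$chisq)
  expect_equal(motif_acetylation_association(9, 9)$chisq, 0)
  z <- motif_acetylation_association(0, 0)
  expect_true(is.na(z$chisq) && is.na(z$p_value))
  # 2x2 variant runs and needs totals
  expect_error(motif_acetylation_association(3, 1, method = "2x2"),
               "totals")
  t22 <- motif_acetylation_association(14, 4, method = "2x2",
                                       n_hyper = 141, n_hypo = 141)
  expect_true(is.finite(t22$chisq))
})

test_that("gain/loss inference follows the outgroup logic", {
  got <- infer_gain_loss(
    present_hyper = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    present_hypo = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    present_outgroup = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, NA))
  expect_equal(got, c("gain_in_hyper", "loss_in_hypo", "gain_in_hypo",
                      "loss_in_hyper", "none", "none", "ambiguous"))
})

test_that("MEME minimal format round-trips a PWM", {
  set.seed(54)
  p <- pwm_from_counts(matrix(rpois(4 * 7, 20) + 1, 4, 7),
                       pseudocount = 0, id = "TESTMOTIF")
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(p, f)
  back <- read_meme(f)[["TESTMOTIF"]]
  expect_equal(back$prob, p$prob, tolerance = 1e-4)
  expect_equal(back$width, p$width)
})

test_that("count-matrix TSV reader builds the same PWM", {
  cnt <- matrix(c(8, 1, 1, 0, 0, 10, 0, 0), 4, 2,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tC\tG\tT", "8\t1\t1\t0", "0\t10\t0\t0"), f)
  p <- read_pwm_tsv(f, pseudocount = 0.1)
  expect_equal(unname(p$prob),
               unname(pwm_from_counts(cnt, pseudocount = 0.1)$prob))
})
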