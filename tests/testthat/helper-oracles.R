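# Independent oracles and fixture builders shared across tests.

# naive O(n*m) interval-overlap oracles
naive_overlaps_any <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    any(target$chrom == query$chrom[i] &
          target$start < query$end[i] &
          target$end > query$start[i])
  }, TRUE)
}

naive_count_points <- function(intervals, chrom, pos) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sum(chrom == intervals$chrom[i] &
          pos >= intervals$start[i] & pos < intervals$end[i])
  }, 0L)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             genome_len = 1e5, max_len = 2000) {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n, 0, genome_len - max_len))
  genomic_intervals(sample(chroms, n, replace = TRUE), start, start + len)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) chartr("ACGT", "TGCA",
                         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))

# brute-force PWM score tail over all 4^w sequences. With `granularity`
# it reproduces the DP's discretization exactly: per-position scores are
# rounded to integer grid units and the query score is mapped to a grid
# index the same way pwm_tail_p does.
brute_force_tail <- function(pwm, score, granularity = NULL) {
  lo <- pwm$log_odds
  w <- ncol(lo)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  pr <- apply(grid, 1, function(r) prod(pwm$background[r]))
  if (is.null(granularity)) {
    sc <- apply(grid, 1, function(r) sum(lo[cbind(r, seq_len(w))]))
    return(vapply(score, function(s) sum(pr[sc >= s - 1e-9]), 0))
  }
  k <- round(lo / granularity)
  sc_int <- apply(grid, 1, function(r) sum(k[cbind(r, seq_len(w))]))
  min_int <- sum(apply(k, 2, min))
  iq <- round((score - min_int * granularity) / granularity)
  vapply(iq, function(i) sum(pr[sc_int - min_int >= i]), 0)
}

# local alignment score oracle (affine gaps) via Biostrings
dp_local_score <- function(query, subject, match = 1, mismatch = -2,
                           gap_open = 2, gap_ext = 0.1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_ext))
}

# small deterministic sim config for fast tests
tiny_config <- function(seed = 1, ...) {
  args <- list(chrom_length = 4e5, n_peaks = 40, n_shared_l1_short = 6,
               n_shared_l1_other = 2, anchor_min_gap = 6000,
               n_peaks_near_insertion = 3,
               n_insertions = list(A = c(L1 = 4, SINE = 2, LTR = 1),
                                   B = c(L1 = 1, SINE = 2, LTR = 0)),
               n_genes = 15, n_motif_gain_hyper = 3,
               n_motif_loss_hypo = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

score_indel_calls <- function(truth_ins, calls, tol = 25) {
  tr <- truth_ins[truth_ins$carrier == "A", , drop = FALSE]
  ca <- calls[calls$carrier == "A", , drop = FALSE]
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    any(ca$chrom == tr$chrom[i] &
          abs(ca$ref_start - tr$start_a[i]) <= tol &
          abs(ca$ref_end - tr$end_a[i]) <= tol)
  }, TRUE)
  fp <- vapply(seq_len(nrow(ca)), function(i) {
    !any(tr$chrom == ca$chrom[i] &
           abs(tr$start_a - ca$ref_start[i]) <= tol &
           abs(tr$end_a - ca$ref_end[i]) <= tol)
  }, TRUE)
  list(recall = mean(hit), precision = 1 - mean(fp),
       n_truth = nrow(tr), n_calls = nrow(ca))
}
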