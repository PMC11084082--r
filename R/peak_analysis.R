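# Per-peak fold enrichment, strain-specificity classification, SNP
# density, CRE overlap, and the interval permutation association test.

#' Classification thresholds
#'
#' Bundles every cutoff used by the classifiers. Defaults follow the
#' study design: a peak is strain-specific when mean fold enrichment is
#' >= 2.5 in one strain and <= 1.5 in the other; ChIP allele bias is
#' called at an A-allele frequency >= 0.68 (B-biased <= 0.32); expression
#' bias at >= 0.8 / <= 0.2.
#'
#' @param fe_high,fe_low fold-enrichment cutoffs for strain specificity.
#' @param allele_hi ChIP allele-frequency cutoff for an A-biased call;
#'   the B-biased cutoff is `1 - allele_hi`.
#' @param expr_hi expression allele-frequency cutoff for an A-biased
#'   gene; B-biased at `1 - expr_hi`.
#' @param min_allelic_reads minimum informative reads per hybrid for a
#'   feature to enter allelic analysis.
#' @param inclusive if `TRUE` (default) bias thresholds are inclusive
#'   (>= / <=); if `FALSE`, strict.
#' @param both_hybrids if `TRUE` (default) an allele-bias call requires
#'   the average *and* each reciprocal hybrid to pass; if `FALSE`, only
#'   the average.
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(fe_high = 2.5, fe_low = 1.5,
                                  allele_hi = 0.68, expr_hi = 0.8,
                                  min_allelic_reads = 20,
                                  inclusive = TRUE, both_hybrids = TRUE) {
  stopifnot(fe_high > fe_low, allele_hi > 0.5, expr_hi > 0.5)
  # round the complements so that 1 - 0.68 is exactly 0.32: the lower
  # thresholds are printed values, not floating-point residues
  structure(list(fe_high = fe_high, fe_low = fe_low,
                 allele_hi = allele_hi,
                 allele_lo = round(1 - allele_hi, 10),
                 expr_hi = expr_hi, expr_lo = round(1 - expr_hi, 10),
                 min_allelic_reads = min_allelic_reads,
                 inclusive = inclusive, both_hybrids = both_hybrids),
            class = "classifier_thresholds")
}

#' Fold enrichment of ChIP over input
#'
#' `FE = ((chip + pc) / chip_lib) / ((input + pc) / input_lib)`. The
#' pseudocount keeps FE finite for empty input windows. Vectorized.
#'
#' @param chip,input read counts (non-negative).
#' @param chip_lib,input_lib library sizes (> 0); leave both at 1 to skip
#'   library-size normalization.
#' @param pseudocount added to both counts (default 0.5).
#' @return numeric vector of fold enrichments.
#' @export
compute_fold_enrichment <- function(chip, input, chip_lib = 1,
                                    input_lib = 1, pseudocount = 0.5) {
  if (any(chip < 0) || any(input < 0)) stop("counts must be non-negative")
  if (any(chip_lib <= 0) || any(input_lib <= 0))
    stop("library sizes must be > 0")
  ((chip + pseudocount) / chip_lib) / ((input + pseudocount) / input_lib)
}

#' Classify peaks as strain-specific or conserved
#'
#' Replicate fold enrichments are summarized per strain (mean by
#' default), then a peak is `A_specific` iff `FE_A >= fe_high` and
#' `FE_B <= fe_low`, `B_specific` symmetrically, otherwise `conserved`.
#' Boundaries are inclusive.
#'
#' @param fe_a,fe_b numeric matrices (peaks x replicates) or vectors of
#'   per-peak fold enrichments for strains A and B.
#' @param thresholds a [classifier_thresholds()].
#' @param summarize how replicate FEs are combined.
#' @return character vector in `{conserved, A_specific, B_specific}`.
#' @export
classify_strain_specificity <- function(fe_a, fe_b,
                                        thresholds = classifier_thresholds(),
                                        summarize = c("mean", "min", "max")) {
  summarize <- match.arg(summarize)
  f <- switch(summarize, mean = rowMeans, min = function(m) apply(m, 1, min),
              max = function(m) apply(m, 1, max))
  a <- if (is.matrix(fe_a)) f(fe_a) else as.numeric(fe_a)
  b <- if (is.matrix(fe_b)) f(fe_b) else as.numeric(fe_b)
  hi <- thresholds$fe_high; lo <- thresholds$fe_low
  ifelse(a >= hi & b <= lo, "A_specific",
         ifelse(b >= hi & a <= lo, "B_specific", "conserved"))
}

#' Per-peak SNP counts and densities
#'
#' Counts SNPs per peak by binary search over sorted positions and
#' reports density per kb. Peaks without a SNP are flagged (`no_snp`);
#' these are excluded from allelic analysis downstream. When a
#' `strain_class` column is present on `peaks`, per-class median
#' densities are reported.
#'
#' @param peaks interval `data.frame`, optionally with `strain_class`.
#' @param snps a `snp_table`.
#' @return list with `per_peak` (`n_snps`, `snp_density`, `no_snp`) and
#'   `median_density_by_class` (or `NULL`).
#' @export
snp_density_summary <- function(peaks, snps) {
  n <- count_points_in_intervals(peaks, snps$chrom, snps$pos)
  dens <- 1000 * n / (peaks$end - peaks$start)
  per_peak <- data.frame(n_snps = n, snp_density = dens, no_snp = n == 0L)
  med <- NULL
  if (!is.null(peaks$strain_class))
    med <- tapply(dens, peaks$strain_class, stats::median)
  list(per_peak = per_peak, median_density_by_class = med)
}

#' Fraction of peaks overlapping candidate regulatory elements
#'
#' Overlap means >= 1 shared base. Per-type fractions are multi-label and
#' may sum above 1.
#'
#' @param peaks interval `data.frame`.
#' @param cres interval `data.frame` with a `name` column holding the CRE
#'   type (e.g. PLS, pELS, dELS, DNase_H3K4me3, CTCF).
#' @return list with `fraction`, `n_overlapping`, `n_peaks`, and
#'   `per_type` (named fractions).
#' @export
cre_overlap_fraction <- function(peaks, cres) {
  any_hit <- overlaps_any(peaks, cres)
  types <- unique(cres$name)
  per_type <- vapply(types, function(tp) {
    mean(overlaps_any(peaks, cres[cres$name == tp, , drop = FALSE]))
  }, 0)
  list(fraction = mean(any_hit), n_overlapping = sum(any_hit),
       n_peaks = nrow(peaks), per_type = per_type)
}

#' Permutation association test for two interval sets
#'
#' Each permutation re-places every query interval uniformly at random on
#' its own chromosome, preserving its length, and recomputes the
#' statistic: `overlap_count` (queries overlapping >= 1 target) or
#' `proximity_count` (queries whose boundaries come within `proximity_bp`
#' of a target boundary, inclusive). The empirical p-value uses the
#' add-one rule `p = (1 + #{null >= observed}) / (n_perm + 1)`, so p is
#' never 0 and is at least `1/(n_perm+1)`.
#'
#' @param query,target interval `data.frame`s.
#' @param genome_sizes named numeric vector of chromosome lengths.
#' @param n_perm number of permutations (>= 1).
#' @param statistic which statistic to permute.
#' @param proximity_bp window for `proximity_count`.
#' @param seed optional integer seed for the permutation stream.
#' @return list of class `permutation_test`: `observed`, `null`
#'   (numeric vector length `n_perm`), `p_value`, `n_perm`, `statistic`.
#' @export
permutation_association_test <- function(query, target, genome_sizes,
                                         n_perm = 999,
                                         statistic = c("overlap_count",
                                                       "proximity_count"),
                                         proximity_bp = 2000,
                                         seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_perm >= 1)
  if (!all(query$chrom %in% names(genome_sizes)))
    stop("genome_sizes must name every query chromosome")
  len <- query$end - query$start
  maxpos <- genome_sizes[query$chrom] - len
  if (any(maxpos < 0))
    stop("query interval longer than its chromosome")
  if (!is.null(seed)) set.seed(seed)
  stat_fun <- if (statistic == "overlap_count") {
    function(q) sum(overlaps_any(q, target))
  } else {
    tgt <- expand_intervals(target, proximity_bp, genome_sizes)
    function(q) sum(overlaps_any(q, tgt))
  }
  observed <- stat_fun(query)
  null <- vapply(seq_len(n_perm), function(i) {
    q2 <- query
    q2$start <- floor(stats::runif(nrow(query), 0, maxpos + 1))
    q2$end <- q2$start + len
    stat_fun(q2)
  }, 0)
  structure(list(observed = observed, null = null,
                 p_value = (1 + sum(null >= observed)) / (n_perm + 1),
                 n_perm = n_perm, statistic = statistic),
            class = "permutation_test")
}

# widen intervals by w on both sides so that boundary-proximity within w
# (inclusive) becomes plain overlap
expand_intervals <- function(x, w, genome_sizes = NULL) {
  x$start <- pmax(0, x$start - w)
  x$end <- x$end + w + 1  # +1: half-open end, inclusive distance
  if (!is.null(genome_sizes))
    x$end <- pmin(x$end, genome_sizes[x$chrom] + w + 1)
  x
}

#' @param x a `permutation_test`.
#' @param ... unused.
#' @rdname permutation_association_test
#' @export
print.permutation_test <- function(x, ...) {
  cat("Permutation association test (", x$statistic, ")\n", sep = "")
  cat("observed:", x$observed, " null mean:", mean(x$null),
      " p =", format(x$p_value, digits = 3),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Run the per-peak strain-specificity analysis on a count table
#'
#' Convenience wrapper: computes per-sample fold enrichments from ChIP
#' and input columns, classifies strain specificity, and attaches SNP
#' density and CRE overlap columns.
#'
#' @param counts a `count_table` with samples `A_input`, `A_rep1`,
#'   `A_rep2`, `B_input`, `B_rep1`, `B_rep2` (replicate count may vary).
#' @param snps optional `snp_table`.
#' @param cres optional CRE interval `data.frame` with `name` types.
#' @param thresholds a [classifier_thresholds()].
#' @param normalize_libsize divide counts by library sizes inside FE.
#' @param pseudocount passed to [compute_fold_enrichment()].
#' @return `data.frame` of peaks with FE columns, `strain_class`,
#'   `n_snps`, `snp_density`, and `cre` (logical) when `cres` given.
#' @export
analyze_peaks <- function(counts, snps = NULL, cres = NULL,
                          thresholds = classifier_thresholds(),
                          normalize_libsize = TRUE, pseudocount = 0.5) {
  sn <- colnames(counts$counts)
  a_reps <- grep("^A_rep", sn, value = TRUE)
  b_reps <- grep("^B_rep", sn, value = TRUE)
  if (!length(a_reps) || !length(b_reps) ||
      !all(c("A_input", "B_input") %in% sn))
    stop("count table must contain A_input/B_input and A_rep*/B_rep* samples")
  lib <- if (normalize_libsize) counts$library_sizes else
    stats::setNames(rep(1, length(sn)), sn)
  fe_of <- function(rep, inp) compute_fold_enrichment(
    counts$counts[, rep], counts$counts[, inp], lib[rep], lib[inp],
    pseudocount)
  fe_a <- sapply(a_reps, fe_of, inp = "A_input")
  fe_b <- sapply(b_reps, fe_of, inp = "B_input")
  if (is.null(dim(fe_a))) { fe_a <- rbind(fe_a); fe_b <- rbind(fe_b) }
  out <- counts$intervals
  out$feature_id <- counts$feature_id
  colnames(fe_a) <- paste0("fe_", a_reps); colnames(fe_b) <- paste0("fe_", b_reps)
  out <- cbind(out, fe_a, fe_b)
  out$fe_a_mean <- rowMeans(fe_a); out$fe_b_mean <- rowMeans(fe_b)
  out$strain_class <- classify_strain_specificity(fe_a, fe_b, thresholds)
  if (!is.null(snps)) {
    sd <- snp_density_summary(out, snps)
    out$n_snps <- sd$per_peak$n_snps
    out$snp_density <- sd$per_peak$snp_density
  }
  if (!is.null(cres)) out$cre <- overlaps_any(out, cres)
  out
}
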