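# Allele-frequency calls for peaks and genes from SNP-assigned read
# counts in reciprocal F1 hybrids, and the acetylation-expression
# association tests.

#' Allele frequency of the A allele
#'
#' `n_a / (n_a + n_b)`; `NA` where the total is zero (the caller must
#' exclude such features). Vectorized; the identity
#' `allele_frequency(a, b) + allele_frequency(b, a) == 1` holds exactly.
#'
#' @param n_a,n_b informative read counts per allele.
#' @return numeric vector in `[0, 1]` (or `NA`).
#' @export
allele_frequency <- function(n_a, n_b) {
  tot <- n_a + n_b
  ifelse(tot > 0, n_a / tot, NA_real_)
}

#' Classify allele bias of features from reciprocal-hybrid counts
#'
#' For each feature the A-allele frequency is computed per hybrid and
#' averaged over the two reciprocal hybrids. ChIP peaks (`kind="peak"`)
#' are called `A_biased` when the average frequency passes `allele_hi`
#' and — under the default both-hybrids rule — each hybrid passes
#' individually; `B_biased` symmetrically at `allele_lo`. Genes
#' (`kind="gene"`) use the `expr_hi`/`expr_lo` cutoffs applied to the
#' average only. Features with no SNP are `excluded_no_snp`; features
#' where a hybrid has fewer than `min_allelic_reads` informative reads
#' are `excluded_low_coverage`.
#'
#' @param counts `data.frame` with columns `feature_id`, `na_f1a`,
#'   `nb_f1a`, `na_f1b`, `nb_f1b` (informative reads per allele per
#'   hybrid), optionally `n_snps`.
#' @param kind `"peak"` or `"gene"`.
#' @param thresholds a [classifier_thresholds()].
#' @param strain_class optional per-feature strain classification
#'   (`A_specific`/`B_specific`/`conserved`); when given, a `consistent`
#'   flag marks bias calls whose direction matches it.
#' @return `data.frame` with per-hybrid frequencies, `freq_avg`,
#'   `bias_class`, and `consistent` when `strain_class` was supplied.
#' @export
classify_allele_bias <- function(counts, kind = c("peak", "gene"),
                                 thresholds = classifier_thresholds(),
                                 strain_class = NULL) {
  kind <- match.arg(kind)
  thr <- thresholds
  hi <- if (kind == "peak") thr$allele_hi else thr$expr_hi
  lo <- if (kind == "peak") thr$allele_lo else thr$expr_lo
  f1 <- allele_frequency(counts$na_f1a, counts$nb_f1a)
  f2 <- allele_frequency(counts$na_f1b, counts$nb_f1b)
  low <- (counts$na_f1a + counts$nb_f1a) < thr$min_allelic_reads |
    (counts$na_f1b + counts$nb_f1b) < thr$min_allelic_reads
  no_snp <- if (!is.null(counts$n_snps)) counts$n_snps == 0L else
    (counts$na_f1a + counts$nb_f1a + counts$na_f1b + counts$nb_f1b) == 0
  avg <- (f1 + f2) / 2
  ge <- if (thr$inclusive) `>=` else `>`
  le <- if (thr$inclusive) `<=` else `<`
  pass_a <- ge(avg, hi)
  pass_b <- le(avg, lo)
  if (kind == "peak" && thr$both_hybrids) {
    pass_a <- pass_a & ge(f1, hi) & ge(f2, hi)
    pass_b <- pass_b & le(f1, lo) & le(f2, lo)
  }
  cls <- ifelse(pass_a, "A_biased",
                ifelse(pass_b, "B_biased",
                       if (kind == "peak") "non_allelic" else "non_biased"))
  cls[low] <- "excluded_low_coverage"
  cls[no_snp] <- "excluded_no_snp"
  avg[low | no_snp] <- NA_real_
  out <- data.frame(feature_id = counts$feature_id,
                    freq_f1a = f1, freq_f1b = f2, freq_avg = avg,
                    bias_class = cls, stringsAsFactors = FALSE)
  if (!is.null(strain_class)) {
    dir_bias <- ifelse(cls == "A_biased", "A",
                       ifelse(cls == "B_biased", "B", NA))
    dir_strain <- ifelse(strain_class == "A_specific", "A",
                         ifelse(strain_class == "B_specific", "B", NA))
    out$consistent <- !is.na(dir_bias) & !is.na(dir_strain) &
      dir_bias == dir_strain
  }
  out
}

#' @rdname classify_allele_bias
#' @export
classify_gene_expression_bias <- function(counts,
                                          thresholds = classifier_thresholds()) {
  classify_allele_bias(counts, kind = "gene", thresholds = thresholds)
}

#' Promoter acetylation vs expression bias (rank-sum test)
#'
#' Compares promoter H3K9ac A-allele frequencies between A-biased and
#' B-biased genes with a one-sided two-sample Wilcoxon rank-sum test
#' (alternative: the A-biased group has the higher promoter frequency).
#'
#' @param gene_bias character vector of gene bias classes
#'   (`A_biased`/`B_biased`/other).
#' @param promoter_freq numeric vector of promoter ChIP A-allele
#'   frequencies, aligned with `gene_bias`.
#' @return list with `statistic` (U for the A-biased group), `p_value`,
#'   and group sizes.
#' @export
promoter_acetylation_association <- function(gene_bias, promoter_freq) {
  a <- promoter_freq[gene_bias == "A_biased"]
  b <- promoter_freq[gene_bias == "B_biased"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 genes with promoter data in each bias group")
  # ties fall back to the normal approximation; the warning is expected
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater", exact = NULL))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Proximity of allele-specific peaks to allele-biased genes
#'
#' For each gene, tests whether a same-direction allele-specific peak has
#' its midpoint within `window_bp` (inclusive) of the gene's TSS, then
#' compares proximity rates between biased and non-biased genes with a
#' 1-df chi-square test on the 2x2 table, without continuity correction.
#'
#' @param genes `data.frame` with `chrom`, `tss` (0-based position), and
#'   `bias_class` (`A_biased`/`B_biased`/other = non-biased).
#' @param peaks `data.frame` of allele-specific peaks with `chrom`,
#'   `start`, `end`, and `bias_class` in `{A_biased, B_biased}`.
#' @param window_bp proximity window (> 0), boundary inclusive.
#' @return list with the 2x2 `table`, `chisq`, `p_value`, and per-gene
#'   `matched` flags.
#' @export
enhancer_proximity_test <- function(genes, peaks, window_bp = 50000) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  mid <- (peaks$start + peaks$end) / 2
  near_dir <- function(g_chrom, g_tss, dir) {
    sel <- peaks$bias_class == dir
    vapply(seq_along(g_tss), function(i) {
      any(sel & peaks$chrom == g_chrom[i] &
            abs(mid - g_tss[i]) <= window_bp)
    }, TRUE)
  }
  matched <- rep(FALSE, nrow(genes))
  for (dir in c("A_biased", "B_biased")) {
    gi <- genes$bias_class == dir
    if (any(gi))
      matched[gi] <- near_dir(genes$chrom[gi], genes$tss[gi], dir)
  }
  # non-biased genes: matched if any allele-specific peak (either
  # direction) is within the window
  gi <- !(genes$bias_class %in% c("A_biased", "B_biased"))
  if (any(gi))
    matched[gi] <- near_dir(genes$chrom[gi], genes$tss[gi], "A_biased") |
      near_dir(genes$chrom[gi], genes$tss[gi], "B_biased")
  biased <- genes$bias_class %in% c("A_biased", "B_biased")
  tab <- rbind(biased = c(matched = sum(matched & biased),
                          unmatched = sum(!matched & biased)),
               non_biased = c(sum(matched & !biased),
                              sum(!matched & !biased)))
  ct <- proximity_chisq(tab)
  list(table = tab, chisq = ct$chisq, p_value = ct$p_value,
       matched = matched)
}

#' @param tab a 2x2 count matrix.
#' @rdname enhancer_proximity_test
#' @export
proximity_chisq <- function(tab) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p_value = ct$p.value)
}
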