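# End-to-end orchestration of the synthetic-mode analysis: simulate ->
# peaks -> alleles -> indels -> motifs -> profile -> report, with a
# machine-readable summary embedding the exact configuration and seed.

#' Round-half-up percentage reporting
#'
#' Report percentages the way the study prints them: round half up at
#' the stated precision (R's `round()` rounds half to even, which is not
#' what printed tables use).
#'
#' @param numerator,denominator counts (`denominator > 0`).
#' @param precision decimal places (default 0).
#' @return list with `value` (rounded percentage as a number) and
#'   `label` (the printed string).
#' @export
report_percentages <- function(numerator, denominator, precision = 0) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  pct <- 100 * unname(numerator) / unname(denominator)
  f <- 10^precision
  value <- floor(pct * f + 0.5) / f
  list(value = value,
       label = formatC(value, format = "f", digits = precision))
}

#' Run the full synthetic-mode pipeline
#'
#' Simulates a genome pair with planted truth, then runs every analysis
#' stage: strain-specific peak classification with SNP density and CRE
#' overlap (plus permutation test), allele-bias calling for ChIP peaks,
#' split-read indel detection from simulated strain-B shotgun reads with
#' repeat annotation and DAR proximity, allele-specific motif scanning
#' with association and outgroup gain/loss inference, allelic expression
#' analysis with the promoter and enhancer-proximity tests, and the
#' 3' L1 metaprofile with its dip statistic. Identical `config` (and
#' therefore seed) gives an identical summary.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; stage outputs (TSV/BED/FASTA) and
#'   `summary.json` are written there.
#' @param thresholds a [classifier_thresholds()].
#' @param n_perm permutations for the association tests.
#' @param stages character vector of stage names to run (dependencies are
#'   not auto-added; `peaks` is always run). Default: all.
#' @return list with per-stage results and `summary` (the flat summary
#'   that is serialized to JSON).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         thresholds = classifier_thresholds(),
                         n_perm = 199,
                         stages = c("peaks", "alleles", "indels",
                                    "motifs", "expression", "profile")) {
  res <- list()
  sim <- simulate_genome_pair(config)
  truth <- sim$truth
  res$sim <- sim
  chip <- simulate_chip_counts(sim, config)
  res$chip_counts <- chip

  ## ---- peaks ----
  peaks <- analyze_peaks(chip, snps = truth$snps, cres = truth$cres,
                         thresholds = thresholds)
  res$peaks <- peaks
  class_counts <- table(factor(peaks$strain_class,
                               c("conserved", "A_specific", "B_specific")))
  cre_frac <- cre_overlap_fraction(peaks, truth$cres)
  set.seed(config$seed + 5L)
  cre_perm <- permutation_association_test(
    peaks, truth$cres, truth$genome_sizes, n_perm = n_perm)
  res$cre_perm <- cre_perm
  summary <- list(
    seed = config$seed,
    n_peaks = nrow(peaks),
    n_conserved = unname(class_counts["conserved"]),
    n_a_specific = unname(class_counts["A_specific"]),
    n_b_specific = unname(class_counts["B_specific"]),
    pct_a_specific = report_percentages(class_counts["A_specific"],
                                        nrow(peaks), 1)$value,
    pct_b_specific = report_percentages(class_counts["B_specific"],
                                        nrow(peaks), 1)$value,
    cre_overlap_pct = report_percentages(cre_frac$n_overlapping,
                                         cre_frac$n_peaks, 0)$value,
    cre_perm_p = cre_perm$p_value,
    snp_density_median = stats::median(peaks$snp_density))

  ## ---- alleles ----
  allele_bias <- NULL
  if ("alleles" %in% stages) {
    ac <- data.frame(feature_id = chip$feature_id,
                     na_f1a = chip$counts[, "F1a_alleleA"],
                     nb_f1a = chip$counts[, "F1a_alleleB"],
                     na_f1b = chip$counts[, "F1b_alleleA"],
                     nb_f1b = chip$counts[, "F1b_alleleB"],
                     n_snps = peaks$n_snps)
    allele_bias <- classify_allele_bias(ac, kind = "peak",
                                        thresholds = thresholds,
                                        strain_class = peaks$strain_class)
    res$allele_bias <- allele_bias
    strain_spec <- peaks$strain_class != "conserved"
    summary$n_allele_biased <- sum(allele_bias$bias_class %in%
                                     c("A_biased", "B_biased"))
    summary$n_consistent_cis <- sum(allele_bias$consistent & strain_spec)
    summary$pct_strain_specific_cis <- if (any(strain_spec))
      report_percentages(sum(allele_bias$consistent & strain_spec),
                         sum(strain_spec), 0)$value else NA
  }

  ## ---- indels ----
  merged_calls <- NULL
  if ("indels" %in% stages) {
    reads <- simulate_reads(sim$genome_b, config)
    alns <- align_reads(reads, sim$genome_a)
    calls <- do.call(rbind, lapply(alns, function(a) {
      rbind(call_short_indels(a), call_long_insertions(a))
    }))
    if (is.null(calls)) calls <- indel_calls_empty()
    merged_calls <- merge_and_annotate(
      calls, repeats = truth$repeats, l1_consensus = truth$library$L1,
      reference = sim$genome_a)
    res$indel_calls <- merged_calls
    dars_b <- peaks[peaks$strain_class == "B_specific", , drop = FALSE]
    a_calls <- merged_calls[merged_calls$carrier == "A", , drop = FALSE]
    if (nrow(dars_b) && nrow(a_calls)) {
      set.seed(config$seed + 6L)
      prox <- dar_indel_proximity(dars_b, a_calls, truth$genome_sizes,
                                  n_perm = n_perm)
      res$dar_proximity <- prox
      summary$dar_insertion_matched <- prox$n_matched
      summary$dar_insertion_pct <- report_percentages(
        prox$n_matched, nrow(dars_b), 1)$value
      summary$dar_insertion_perm_p <- prox$perm$p_value
    }
    summary$n_indel_calls <- nrow(merged_calls)
    summary$n_carrier_a <- sum(merged_calls$carrier == "A")
    summary$indel_class_counts <- as.list(table(merged_calls$element_class))
  }

  ## ---- motifs ----
  if ("motifs" %in% stages && !is.null(allele_bias)) {
    biased <- which(allele_bias$bias_class %in% c("A_biased", "B_biased"))
    pres_hyper <- pres_hypo <- pres_out <- logical(length(biased))
    dist <- score_pvalue_distribution(truth$pwm)
    for (j in seq_along(biased)) {
      i <- biased[j]
      seqs <- allele_sequences(sim$genome_a, peaks[i, ], truth$snps)
      sc <- scan_alleles(truth$pwm, seqs$a, seqs$b, dist = dist)
      hyper_is_a <- allele_bias$bias_class[i] == "A_biased"
      pres_hyper[j] <- if (hyper_is_a) sc$presence_a else sc$presence_b
      pres_hypo[j] <- if (hyper_is_a) sc$presence_b else sc$presence_a
      pres_out[j] <- nrow(scan_sequence(truth$pwm, seqs$outgroup,
                                        dist = dist)) > 0
    }
    a <- sum(pres_hyper & !pres_hypo)
    b <- sum(pres_hypo & !pres_hyper)
    assoc <- motif_acetylation_association(a, b)
    gl <- infer_gain_loss(pres_hyper, pres_hypo, pres_out)
    res$motif <- list(a = a, b = b, assoc = assoc, gain_loss = gl)
    summary$motif_hyper_only <- a
    summary$motif_hypo_only <- b
    summary$motif_chisq <- assoc$chisq
    summary$motif_p <- assoc$p_value
    summary$motif_gain_in_hyper <- sum(gl == "gain_in_hyper")
    summary$motif_loss_in_hypo <- sum(gl == "loss_in_hypo")
  }

  ## ---- expression ----
  if ("expression" %in% stages && !is.null(allele_bias)) {
    expr <- simulate_expression_counts(sim, config)
    ec <- data.frame(feature_id = expr$feature_id,
                     na_f1a = expr$counts[, "F1a_alleleA"],
                     nb_f1a = expr$counts[, "F1a_alleleB"],
                     na_f1b = expr$counts[, "F1b_alleleA"],
                     nb_f1b = expr$counts[, "F1b_alleleB"])
    gene_bias <- classify_gene_expression_bias(ec, thresholds)
    res$gene_bias <- gene_bias
    genes <- truth$genes
    prom_freq <- allele_bias$freq_avg[match(genes$promoter_peak,
                                            allele_bias$feature_id)]
    assoc <- tryCatch(promoter_acetylation_association(
      gene_bias$bias_class, prom_freq), error = function(e) NULL)
    gdf <- data.frame(chrom = genes$chrom, tss = genes$tss,
                      bias_class = gene_bias$bias_class)
    pk_biased <- cbind(peaks[match(allele_bias$feature_id,
                                   peaks$feature_id),
                             c("chrom", "start", "end")],
                       bias_class = allele_bias$bias_class)
    pk_biased <- pk_biased[pk_biased$bias_class %in%
                             c("A_biased", "B_biased"), , drop = FALSE]
    prox <- tryCatch(enhancer_proximity_test(gdf, pk_biased),
                     error = function(e) NULL)
    res$expression <- list(promoter_assoc = assoc, enhancer_prox = prox)
    summary$n_genes_a_biased <- sum(gene_bias$bias_class == "A_biased")
    summary$n_genes_b_biased <- sum(gene_bias$bias_class == "B_biased")
    if (!is.null(assoc)) summary$promoter_assoc_p <- assoc$p_value
    if (!is.null(prox)) summary$enhancer_prox_p <- prox$p_value
  }

  ## ---- profile ----
  if ("profile" %in% stages) {
    track_counts <- simulate_chip_track(sim, config)
    track50 <- bin_genome_fe(track_counts$chip, track_counts$input,
                             track_counts$bin_size, bin_size = 50000,
                             genome_sizes = truth$genome_sizes)
    hyper <- select_hyperacetylated(track50)
    fine <- bin_genome_fe(track_counts$chip, track_counts$input,
                          track_counts$bin_size,
                          bin_size = track_counts$bin_size)
    anchors <- select_short_3prime_l1(truth$repeats)
    if (nrow(anchors)) {
      prof <- anchor_profile(fine, anchors)
      res$profile <- prof
      summary$dip_ratio <- dip_statistic(prof, config$dip_radius)
      summary$n_anchors <- nrow(anchors)
    }
    summary$hyperacetylated_fraction <- hyper$fraction
  }

  summary$config <- unclass(config)
  res$summary <- summary

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$genome_a, file.path(out_dir, "genome_A.fa"))
    write_fasta(sim$genome_b, file.path(out_dir, "genome_B.fa"))
    write_fasta(sim$outgroup, file.path(out_dir, "outgroup.fa"))
    write_snp_table(truth$snps, file.path(out_dir, "snps.tsv"))
    write_count_table(chip, file.path(out_dir, "chip_counts.tsv"))
    utils::write.table(peaks, file.path(out_dir, "peaks_classified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(allele_bias))
      utils::write.table(allele_bias,
                         file.path(out_dir, "allele_bias.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(merged_calls))
      utils::write.table(merged_calls,
                         file.path(out_dir, "indel_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(res)
}

#' Load a run configuration from YAML or JSON
#'
#' Fields mirror [sim_config()] arguments; unknown fields are rejected.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON config file.
#' @return a [sim_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(cfg$n_insertions))
    cfg$n_insertions <- lapply(cfg$n_insertions, unlist)
  do.call(sim_config, cfg)
}
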