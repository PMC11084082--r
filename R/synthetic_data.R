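# Synthetic genome-pair generator: an ancestral genome diverged into two
# strains (A = reference carrier, B = alternative) plus an outgroup that
# keeps the ancestral state, with planted retroelement insertions,
# cis/trans acetylation effects, motif gains/losses, an acetylation dip
# around 3' L1 fragments, and allele-biased expression. Everything is
# recorded in a truth table so downstream calls can be scored.

#' Simulation configuration
#'
#' Defaults encode the study conditions: SNP divergence of 6.3 per kb, L1
#' 5'-truncation fractions of 60/26/9/3/2 percent for <0.4 / 0.4-1 / 1-2 /
#' 2-5.8 / >5.8 kb copies (always retaining the consensus 3' end), an
#' acetylation dip of factor 0.3 within 2 kb of a 3' L1 fragment, and
#' 700-bp Sanger-like shotgun reads.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param snp_rate SNP divergence per bp (default 6.3e-3).
#' @param gc ancestral GC content.
#' @param n_peaks number of acetylation peaks per chromosome.
#' @param peak_length_range min/max peak length (bp).
#' @param fraction_cis_effect,fraction_trans_effect fractions of peaks
#'   given a cis (allelic) or trans (strain-background) effect.
#' @param cis_effect_size,trans_effect_size fold-ratio of the planted
#'   effects (hyper vs hypo side).
#' @param n_insertions list with elements `A` and `B`, each a named
#'   vector of insertion counts per element class (`L1`, `SINE`, `LTR`),
#'   planted on every chromosome.
#' @param l1_truncation_fractions probabilities of the five L1 length
#'   bins `<0.4k, 0.4-1k, 1-2k, 2-5.8k, full`.
#' @param l1_len_range optional `c(min, max)`; L1 insertion lengths are
#'   redrawn until inside this range (used to plant only long copies).
#' @param n_shared_l1_short,n_shared_l1_other shared (non-polymorphic)
#'   L1 fragments planted in the ancestor of every chromosome: short
#'   100-400 bp 3' fragments (the metaprofile anchors), and a mix of
#'   long suffix copies plus middle fragments without the 3' end.
#' @param anchor_min_gap minimum spacing between shared fragments (bp).
#' @param n_peaks_near_insertion peaks deliberately placed with their
#'   midpoint within `dip_radius` of an A-carrier 3' L1 insertion.
#' @param dip_factor multiplier applied to ChIP signal within
#'   `dip_radius` of a 3' L1 fragment present on that allele (default
#'   0.3; set to 1 for a no-dip control).
#' @param dip_radius radius of the dip (bp, default 2000).
#' @param read_length,coverage,sequencing_error_rate shotgun read
#'   simulation parameters.
#' @param nb_dispersion negative-binomial dispersion of counts (0 =
#'   Poisson).
#' @param chip_input_mean expected input reads per kb of peak.
#' @param allelic_depth expected SNP-assignable ChIP reads per peak per
#'   hybrid (both alleles together).
#' @param expr_depth expected informative mRNA reads per gene per hybrid.
#' @param n_genes number of genes per chromosome (each tied to a
#'   promoter peak).
#' @param coupling coupling in `[0,1]` between a promoter's cis effect
#'   and the gene's allelic expression ratio (1 = deterministic).
#' @param cre_fraction fraction of peaks covered by a synthetic CRE.
#' @param n_motif_gain_hyper,n_motif_loss_hypo cis peaks given a planted
#'   motif gain on the hyperacetylated allele / motif loss on the
#'   hypoacetylated allele (ancestral state set accordingly).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 1, chrom_length = 2e6,
                       snp_rate = 6.3e-3, gc = 0.42,
                       n_peaks = 300, peak_length_range = c(600, 1400),
                       fraction_cis_effect = 0.15,
                       fraction_trans_effect = 0.10,
                       cis_effect_size = 5, trans_effect_size = 5,
                       n_insertions = list(A = c(L1 = 15, SINE = 10,
                                                 LTR = 5),
                                           B = c(L1 = 3, SINE = 5,
                                                 LTR = 0)),
                       l1_truncation_fractions = c(0.60, 0.26, 0.09,
                                                   0.03, 0.02),
                       l1_len_range = NULL,
                       n_shared_l1_short = 40, n_shared_l1_other = 10,
                       anchor_min_gap = 24000,
                       n_peaks_near_insertion = 8,
                       dip_factor = 0.3, dip_radius = 2000,
                       read_length = 700, coverage = 5,
                       sequencing_error_rate = 0,
                       nb_dispersion = 0.02,
                       chip_input_mean = 100, allelic_depth = 120,
                       expr_depth = 200, n_genes = 80, coupling = 1,
                       cre_fraction = 0.89,
                       n_motif_gain_hyper = 9, n_motif_loss_hypo = 5,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(l1_truncation_fractions) - 1) < 1e-8,
            all(l1_truncation_fractions >= 0),
            fraction_cis_effect + fraction_trans_effect <= 1,
            coupling >= 0, coupling <= 1,
            dip_factor > 0, dip_radius > 0,
            snp_rate > 0, snp_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

# consensus element sequences; the final l1_utr bases of the L1 are its
# "3' UTR". Deterministic given the seed.
element_library <- function(seed, l1_len = 6000, sine_len = 200,
                            ltr_len = 5000, l1_utr = 500) {
  set.seed(seed)
  rseq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE,
                                   prob = c(0.3, 0.2, 0.2, 0.3)),
                            collapse = "")
  list(L1 = rseq(l1_len), SINE = rseq(sine_len), LTR = rseq(ltr_len),
       l1_utr = l1_utr)
}

#' The bundled synthetic TF motif used in simulations
#'
#' A sharp width-9 motif (97% consensus base per position), standing in
#' for an activator whose binding-site gain is coupled to
#' hyperacetylation. At the default scan threshold of p = 1e-4 a single
#' consensus-breaking substitution abolishes the site, so SNP-level
#' gains and losses are detectable.
#'
#' @param pseudocount passed to [pwm_from_counts()].
#' @return a `pwm`.
#' @export
default_pwm <- function(pseudocount = 0.1) {
  consensus <- "TGACGTCAT"
  idx <- match(strsplit(consensus, "")[[1L]], DNA_BASES)
  counts <- matrix(1, 4, nchar(consensus))
  counts[cbind(idx, seq_along(idx))] <- 97
  pwm_from_counts(counts, pseudocount = pseudocount, id = "SYNTF1")
}

draw_counts <- function(n, mu, disp) {
  if (disp <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / disp)
}

sample_l1_length <- function(n, fractions, full_len, len_range = NULL) {
  bins <- rbind(c(100, 399), c(400, 999), c(1000, 1999), c(2000, 5799),
                c(full_len, full_len))
  draw <- function(m) {
    b <- sample.int(5, m, replace = TRUE, prob = fractions)
    floor(stats::runif(m, bins[b, 1], bins[b, 2] + 1))
  }
  out <- draw(n)
  if (!is.null(len_range)) {
    for (i in 1:200) {
      bad <- out < len_range[1] | out > len_range[2]
      if (!any(bad)) break
      out[bad] <- draw(sum(bad))
    }
    if (any(out < len_range[1] | out > len_range[2]))
      stop("could not draw L1 lengths inside l1_len_range")
  }
  out
}

# sequential non-overlapping placement of intervals of given lengths on
# [margin, L - margin), keeping min_gap from previously occupied spans;
# each start is drawn uniformly from the exact feasible set, so dense
# packings succeed whenever they are possible
place_intervals <- function(lens, L, occupied, min_gap, margin = 1000) {
  starts <- numeric(length(lens))
  for (i in seq_along(lens)) {
    lo <- margin; hi <- L - margin - lens[i]
    if (nrow(occupied)) {
      # forbidden start ranges from each occupied span
      fs <- occupied$start - min_gap - lens[i]
      fe <- occupied$end + min_gap
      o <- order(fs); fs <- fs[o]; fe <- fe[o]
      # merge and subtract from [lo, hi]
      free_lo <- lo; free <- NULL
      for (j in seq_along(fs)) {
        if (fs[j] > free_lo) free <- rbind(free, c(free_lo, min(fs[j], hi)))
        free_lo <- max(free_lo, fe[j])
        if (free_lo > hi) break
      }
      if (free_lo <= hi) free <- rbind(free, c(free_lo, hi))
      if (!is.null(free)) free <- free[free[, 2] > free[, 1], , drop = FALSE]
      if (is.null(free) || !nrow(free))
        stop("could not place interval without overlap; ",
             "reduce counts or lengths")
      wl <- free[, 2] - free[, 1]
      g <- sample.int(nrow(free), 1L, prob = wl)
      s <- floor(stats::runif(1, free[g, 1], free[g, 2]))
    } else {
      if (hi <= lo) stop("could not place interval without overlap; ",
                         "reduce counts or lengths")
      s <- floor(stats::runif(1, lo, hi))
    }
    starts[i] <- s
    occupied <- rbind(occupied, data.frame(start = s, end = s + lens[i]))
  }
  list(starts = starts, occupied = occupied)
}

# evenly spaced placement with uniform jitter: one interval per lattice
# slot, guaranteeing at least min_gap between neighbours; used for the
# shared anchor fragments, which need clean, non-overlapping flanks
place_lattice <- function(lens, L, min_gap, margin = 12000) {
  n <- length(lens)
  if (!n) return(numeric(0))
  slot <- (L - 2 * margin) / n
  if (slot < max(lens) + min_gap)
    stop("could not place ", n, " lattice intervals with min_gap ",
         min_gap, " on length ", L)
  jitter <- slot - lens - min_gap
  floor(margin + (seq_len(n) - 1) * slot + min_gap / 2 +
          stats::runif(n, 0, pmax(1, jitter)))
}

# map ancestral coordinates to a derived genome that received insertions
# of lengths `lens` immediately before ancestral offsets `pos`
make_coord_map <- function(pos, lens) {
  o <- order(pos); pos <- pos[o]; lens <- lens[o]
  cum <- cumsum(lens)
  function(x) x + c(0, cum)[findInterval(x, pos) + 1L]
}

#' Simulate a diverged genome pair with an outgroup and full truth table
#'
#' Draws an ancestral genome, plants shared 3' L1 fragments and
#' strain-specific element insertions (L1 copies 5'-truncated so that the
#' inserted sequence is always a suffix of the consensus), assigns SNPs
#' to the two lineages at `snp_rate`, plants acetylation peaks with cis /
#' trans effects and motif gains/losses, and assembles the three genomes.
#' The outgroup keeps the ancestral state throughout.
#'
#' @param config a [sim_config()].
#' @return list with `genome_a`, `genome_b`, `outgroup` (named character
#'   vectors), and `truth` (lists `snps`, `insertions`, `repeats`,
#'   `peaks`, `genes`, `cres`, `library`, `config`). All truth
#'   coordinates are 0-based half-open in reference (strain A) space
#'   unless suffixed `_anc` or `_b`.
#' @export
simulate_genome_pair <- function(config) {
  set.seed(config$seed)
  lib <- element_library(config$seed + 7)
  pwm <- default_pwm()
  consensus <- apply(pwm$prob, 2, function(p) DNA_BASES[which.max(p)])
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome_a <- genome_b <- outgroup <- stats::setNames(
    character(length(chroms)), chroms)
  snps_list <- list(); ins_all <- list(); rep_all <- list()
  peaks_all <- list(); genes_all <- list(); cre_all <- list()
  gene_counter <- 0L
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    L <- config$chrom_length
    anc <- sample(DNA_BASES, L, replace = TRUE,
                  prob = c((1 - config$gc) / 2, config$gc / 2,
                           config$gc / 2, (1 - config$gc) / 2))
    occupied <- data.frame(start = numeric(), end = numeric())

    ## ---- shared 3' L1 fragments in the ancestor (overwritten in
    ## place, so coordinates stay colinear across all three genomes);
    ## placed on a jittered lattice so every anchor has clean flanks ----
    sh_lens <- c(floor(stats::runif(config$n_shared_l1_short, 100, 401)),
                 floor(stats::runif(config$n_shared_l1_other, 500,
                                    nchar(lib$L1) / 2)))
    sh_3p <- c(rep(TRUE, config$n_shared_l1_short),
               stats::runif(config$n_shared_l1_other) < 0.5)
    shared <- NULL
    if (length(sh_lens)) {
      ord <- sample.int(length(sh_lens))  # interleave short/other
      sh_lens <- sh_lens[ord]; sh_3p <- sh_3p[ord]
      sh_start <- place_lattice(sh_lens, L, config$anchor_min_gap)
      occupied <- rbind(occupied,
                        data.frame(start = sh_start,
                                   end = sh_start + sh_lens))
      shared <- data.frame(chrom = ch, anc_start = sh_start,
                           anc_end = sh_start + sh_lens,
                           len = sh_lens, has_3prime_end = sh_3p,
                           strand = sample(c("+", "-"), length(sh_lens),
                                           replace = TRUE),
                           stringsAsFactors = FALSE)
      for (i in seq_len(nrow(shared))) {
        frag <- if (shared$has_3prime_end[i])
          substr(lib$L1, nchar(lib$L1) - shared$len[i] + 1, nchar(lib$L1))
        else
          substr(lib$L1, 2000, 2000 + shared$len[i] - 1)
        if (shared$strand[i] == "-") frag <- revcomp(frag)
        anc[(shared$anc_start[i] + 1):shared$anc_end[i]] <-
          strsplit(frag, "", fixed = TRUE)[[1L]]
      }
    }

    ## ---- strain-specific insertions (points in ancestor coords) ----
    mk_ins <- function(carrier) {
      counts <- config$n_insertions[[carrier]]
      counts <- counts[counts > 0]
      if (!length(counts)) return(NULL)
      cls <- rep(names(counts), counts)
      lens <- numeric(length(cls))
      lens[cls == "SINE"] <- nchar(lib$SINE)
      lens[cls == "LTR"] <- nchar(lib$LTR)
      nl1 <- sum(cls == "L1")
      if (nl1) lens[cls == "L1"] <- sample_l1_length(
        nl1, config$l1_truncation_fractions, nchar(lib$L1),
        config$l1_len_range)
      data.frame(carrier = carrier, class = cls, len = lens,
                 stringsAsFactors = FALSE)
    }
    ins <- rbind(mk_ins("A"), mk_ins("B"))
    if (!is.null(ins) && nrow(ins)) {
      # insertion points need clearance so junction-spanning reads are
      # unambiguous; footprint is a point in ancestor coordinates
      pl <- place_intervals(rep(1, nrow(ins)), L, occupied,
                            min_gap = 2 * config$read_length + 6000,
                            margin = 2 * config$read_length)
      ins$anc_pos <- pl$starts
      occupied <- pl$occupied
      ins$strand <- sample(c("+", "-"), nrow(ins), replace = TRUE)
      ins$seq <- vapply(seq_len(nrow(ins)), function(i) {
        s <- switch(ins$class[i],
                    L1 = substr(lib$L1, nchar(lib$L1) - ins$len[i] + 1,
                                nchar(lib$L1)),
                    SINE = lib$SINE, LTR = lib$LTR)
        if (ins$strand[i] == "-") revcomp(s) else s
      }, "")
      ins$has_3prime_end <- ins$class == "L1"
      ins$chrom <- ch
    } else ins <- NULL

    ## ---- peaks (ancestor coords) ----
    n_pk <- config$n_peaks
    pk_len <- floor(stats::runif(n_pk, config$peak_length_range[1],
                                 config$peak_length_range[2] + 1))
    n_near <- 0L
    near_ins_idx <- integer(0)
    if (!is.null(ins)) {
      cand <- which(ins$carrier == "A" & ins$class == "L1" &
                      ins$has_3prime_end)
      n_near <- min(config$n_peaks_near_insertion, length(cand), n_pk)
      near_ins_idx <- cand[seq_len(n_near)]
    }
    pk_start <- numeric(n_pk)
    # deliberately dip-adjacent peaks: downstream edge close to the
    # insertion point, midpoint within dip_radius
    for (j in seq_len(n_near)) {
      p <- ins$anc_pos[near_ins_idx[j]]
      d <- floor(stats::runif(1, 100, max(101, config$dip_radius -
                                            pk_len[j] / 2 - 200)))
      pk_start[j] <- p - d - pk_len[j]
    }
    if (n_pk > n_near) {
      pl <- place_intervals(pk_len[(n_near + 1):n_pk], L, occupied,
                            min_gap = config$dip_radius + 500,
                            margin = 12000)
      pk_start[(n_near + 1):n_pk] <- pl$starts
    }
    peaks <- data.frame(chrom = rep(ch, n_pk), anc_start = pk_start,
                        anc_end = pk_start + pk_len,
                        stringsAsFactors = FALSE)
    peaks <- peaks[order(peaks$anc_start), , drop = FALSE]
    peaks$near_insertion <- peaks$anc_start %in% pk_start[seq_len(n_near)]

    ## ---- planted regulatory effects ----
    n_cis <- round(config$fraction_cis_effect * n_pk)
    n_trans <- round(config$fraction_trans_effect * n_pk)
    free <- which(!peaks$near_insertion)
    eff <- rep("none", n_pk)
    eff[free[seq_len(n_cis)]] <- "cis"
    eff[free[n_cis + seq_len(n_trans)]] <- "trans"
    peaks$effect_type <- eff
    hyper <- ifelse(stats::runif(n_pk) < 0.5, "A", "B")
    r_cis <- config$cis_effect_size
    r_trans <- config$trans_effect_size
    peaks$cis_a <- ifelse(eff == "cis" & hyper == "A", 1,
                          ifelse(eff == "cis", 1 / r_cis, 1))
    peaks$cis_b <- ifelse(eff == "cis" & hyper == "B", 1,
                          ifelse(eff == "cis", 1 / r_cis, 1))
    peaks$trans_a <- ifelse(eff == "trans" & hyper == "A", 1,
                            ifelse(eff == "trans", 1 / r_trans, 1))
    peaks$trans_b <- ifelse(eff == "trans" & hyper == "B", 1,
                            ifelse(eff == "trans", 1 / r_trans, 1))
    peaks$lambda <- ifelse(eff == "none" & !peaks$near_insertion,
                           exp(stats::rnorm(n_pk, log(3), 0.3)), 4)

    ## ---- motif planting (realized through SNP records) ----
    mid_of <- function(i) floor((peaks$anc_start[i] + peaks$anc_end[i]) / 2)
    cis_idx <- which(peaks$effect_type == "cis")
    n_gain <- min(config$n_motif_gain_hyper, length(cis_idx))
    gain_idx <- cis_idx[seq_len(n_gain)]
    rest <- setdiff(cis_idx, gain_idx)
    n_loss <- min(config$n_motif_loss_hypo, length(rest))
    loss_idx <- rest[seq_len(n_loss)]
    peaks$motif_status <- rep("none", n_pk)
    peaks$motif_status[gain_idx] <- "gain_in_hyper"
    peaks$motif_status[loss_idx] <- "loss_in_hypo"
    w <- length(consensus)
    motif_snps <- list()
    motif_footprint <- integer(0)
    for (i in gain_idx) {
      site <- mid_of(i); pos <- site:(site + w - 1L)
      hyp <- if (peaks$cis_a[i] >= peaks$cis_b[i]) "A" else "B"
      diffp <- which(anc[pos + 1L] != consensus)
      for (d in diffp) {
        p <- pos[d]
        motif_snps[[length(motif_snps) + 1L]] <- data.frame(
          chrom = ch, anc_pos = p, ancestral = anc[p + 1L],
          allele_a = if (hyp == "A") consensus[d] else anc[p + 1L],
          allele_b = if (hyp == "B") consensus[d] else anc[p + 1L],
          stringsAsFactors = FALSE)
      }
      motif_footprint <- c(motif_footprint, pos)
    }
    for (i in loss_idx) {
      site <- mid_of(i); pos <- site:(site + w - 1L)
      anc[pos + 1L] <- consensus  # ancestor (and outgroup) carry the motif
      hyp <- if (peaks$cis_a[i] >= peaks$cis_b[i]) "A" else "B"
      # disrupt two informative positions on the hypoacetylated lineage
      for (d in c(3L, 7L)) {
        p <- pos[d]
        worst <- DNA_BASES[which.min(pwm$prob[, d])]
        motif_snps[[length(motif_snps) + 1L]] <- data.frame(
          chrom = ch, anc_pos = p, ancestral = consensus[d],
          allele_a = if (hyp == "A") consensus[d] else worst,
          allele_b = if (hyp == "B") consensus[d] else worst,
          stringsAsFactors = FALSE)
      }
      motif_footprint <- c(motif_footprint, pos)
    }

    ## ---- background SNPs ----
    n_snp <- stats::rbinom(1, L, config$snp_rate)
    snp_pos <- sample.int(L, n_snp) - 1L
    snp_pos <- setdiff(snp_pos, motif_footprint)
    anc_base <- anc[snp_pos + 1L]
    derived <- vapply(anc_base, function(b)
      sample(setdiff(DNA_BASES, b), 1L), "")
    to_a <- stats::runif(length(snp_pos)) < 0.5
    snps <- data.frame(chrom = ch, anc_pos = snp_pos,
                       ancestral = anc_base,
                       allele_a = ifelse(to_a, derived, anc_base),
                       allele_b = ifelse(to_a, anc_base, derived),
                       stringsAsFactors = FALSE)
    if (length(motif_snps)) snps <- rbind(snps, do.call(rbind, motif_snps))
    snps <- snps[order(snps$anc_pos), , drop = FALSE]

    ## ---- assemble the three genomes ----
    vec_a <- anc; vec_b <- anc
    da <- snps$allele_a != snps$ancestral
    db <- snps$allele_b != snps$ancestral
    vec_a[snps$anc_pos[da] + 1L] <- snps$allele_a[da]
    vec_b[snps$anc_pos[db] + 1L] <- snps$allele_b[db]
    assemble <- function(vec, my_ins) {
      if (is.null(my_ins) || !nrow(my_ins))
        return(paste(vec, collapse = ""))
      o <- order(my_ins$anc_pos)
      pieces <- character(2 * nrow(my_ins) + 1)
      prev <- 0L
      for (k in seq_len(nrow(my_ins))) {
        i <- o[k]
        pieces[2 * k - 1] <- paste(vec[(prev + 1):my_ins$anc_pos[i]],
                                   collapse = "")
        pieces[2 * k] <- my_ins$seq[i]
        prev <- my_ins$anc_pos[i]
      }
      pieces[2 * nrow(my_ins) + 1] <- paste(vec[(prev + 1):length(vec)],
                                            collapse = "")
      paste(pieces, collapse = "")
    }
    ins_a <- if (!is.null(ins)) ins[ins$carrier == "A", , drop = FALSE] else NULL
    ins_b <- if (!is.null(ins)) ins[ins$carrier == "B", , drop = FALSE] else NULL
    genome_a[ch] <- assemble(vec_a, ins_a)
    genome_b[ch] <- assemble(vec_b, ins_b)
    outgroup[ch] <- paste(anc, collapse = "")

    map_a <- make_coord_map(
      if (!is.null(ins_a) && nrow(ins_a)) ins_a$anc_pos else numeric(0),
      if (!is.null(ins_a) && nrow(ins_a)) ins_a$len else numeric(0))
    map_b <- make_coord_map(
      if (!is.null(ins_b) && nrow(ins_b)) ins_b$anc_pos else numeric(0),
      if (!is.null(ins_b) && nrow(ins_b)) ins_b$len else numeric(0))

    ## ---- truth tables in reference (A) coordinates ----
    snps$pos <- map_a(snps$anc_pos)
    snps_list[[length(snps_list) + 1L]] <- snps
    if (!is.null(ins) && nrow(ins)) {
      # carrier=A: the inserted sequence occupies an interval of genome
      # A; map_a(anc_pos) includes the insertion's own length, so its
      # start is map_a(anc_pos) - len. carrier=B: a point on genome A.
      ins$start_a <- ifelse(ins$carrier == "A",
                            map_a(ins$anc_pos) - ins$len,
                            map_a(ins$anc_pos))
      ins$end_a <- ifelse(ins$carrier == "A", ins$start_a + ins$len,
                          ins$start_a)
      ins_all[[length(ins_all) + 1L]] <- ins
    }
    # repeat annotation of the reference genome: shared fragments plus
    # A-carrier element insertions
    reps <- NULL
    if (!is.null(shared) && nrow(shared))
      reps <- data.frame(chrom = ch, start = map_a(shared$anc_start),
                         end = map_a(shared$anc_start) + shared$len,
                         name = "L1_syn", class = "L1",
                         strand = shared$strand,
                         has_3prime_end = shared$has_3prime_end,
                         shared = TRUE, stringsAsFactors = FALSE)
    if (!is.null(ins_a) && nrow(ins_a)) {
      ia <- ins[ins$carrier == "A", , drop = FALSE]
      reps <- rbind(reps, data.frame(
        chrom = ch, start = ia$start_a, end = ia$end_a,
        name = paste0(ia$class, "_syn"), class = ia$class,
        strand = ia$strand, has_3prime_end = ia$has_3prime_end,
        shared = FALSE, stringsAsFactors = FALSE))
    }
    if (!is.null(reps)) rep_all[[length(rep_all) + 1L]] <- reps

    ## dip multipliers per allele: 3' L1 fragments on that allele within
    ## dip_radius of the peak midpoint
    pk_mid <- (peaks$anc_start + peaks$anc_end) / 2
    frag_anc <- c(if (!is.null(shared))
      (shared$anc_start + shared$anc_end)[shared$has_3prime_end] / 2,
      numeric(0))
    frag_a <- c(frag_anc, if (!is.null(ins_a) && nrow(ins_a))
      ins_a$anc_pos[ins_a$class == "L1"] else numeric(0))
    frag_b <- c(frag_anc, if (!is.null(ins_b) && nrow(ins_b))
      ins_b$anc_pos[ins_b$class == "L1"] else numeric(0))
    near <- function(mid, frags) {
      if (!length(frags)) return(rep(FALSE, length(mid)))
      vapply(mid, function(m) any(abs(frags - m) <= config$dip_radius),
             TRUE)
    }
    peaks$dip_a <- ifelse(near(pk_mid, frag_a), config$dip_factor, 1)
    peaks$dip_b <- ifelse(near(pk_mid, frag_b), config$dip_factor, 1)
    peaks$fe_a_true <- peaks$lambda * peaks$cis_a * peaks$trans_a *
      peaks$dip_a
    peaks$fe_b_true <- peaks$lambda * peaks$cis_b * peaks$trans_b *
      peaks$dip_b
    peaks$start <- map_a(peaks$anc_start)
    peaks$end <- peaks$start + (peaks$anc_end - peaks$anc_start)
    peaks$feature_id <- sprintf("%s_peak%04d", ch,
                                seq_len(nrow(peaks)))
    peaks_all[[length(peaks_all) + 1L]] <- peaks

    ## ---- genes tied to promoter peaks ----
    n_g <- min(config$n_genes, n_pk)
    cis_first <- order(peaks$effect_type != "cis")  # cis peaks first
    prom_idx <- cis_first[seq_len(n_g)]
    ratio <- (peaks$cis_a[prom_idx] / peaks$cis_b[prom_idx]) ^
      config$coupling *
      exp(stats::rnorm(n_g, 0, 0.4 * (1 - config$coupling)))
    genes_all[[length(genes_all) + 1L]] <- data.frame(
      gene_id = sprintf("gene%04d", gene_counter + seq_len(n_g)),
      chrom = rep(ch, n_g),
      tss = floor((peaks$start[prom_idx] + peaks$end[prom_idx]) / 2),
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      promoter_peak = peaks$feature_id[prom_idx],
      expr_ratio = ratio, expr_freq_true = ratio / (1 + ratio),
      stringsAsFactors = FALSE)
    gene_counter <- gene_counter + n_g

    ## ---- synthetic CRE annotation ----
    with_cre <- stats::runif(n_pk) < config$cre_fraction
    if (any(with_cre)) {
      ctypes <- sample(c("dELS", "pELS", "PLS", "DNase_H3K4me3", "CTCF"),
                       sum(with_cre), replace = TRUE,
                       prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
      cs <- floor((peaks$start[with_cre] + peaks$end[with_cre]) / 2) - 150
      cre_all[[length(cre_all) + 1L]] <- data.frame(
        chrom = ch, start = pmax(0, cs), end = pmax(0, cs) + 300,
        name = ctypes, stringsAsFactors = FALSE)
    }
  }

  snp_df <- do.call(rbind, snps_list)
  snp_tab <- snp_table(snp_df$chrom, snp_df$pos, snp_df$allele_a,
                       snp_df$allele_b)
  # re-attach ancestral bases in the sorted order of the snp_table
  o <- order(snp_df$chrom, snp_df$pos)
  snp_tab$ancestral <- snp_df$ancestral[o]
  snp_tab$anc_pos <- snp_df$anc_pos[o]
  peaks <- do.call(rbind, peaks_all)
  rownames(peaks) <- NULL
  thr <- classifier_thresholds()
  peaks$strain_true <- classify_strain_specificity(
    peaks$fe_a_true, peaks$fe_b_true, thr)
  ins <- if (length(ins_all)) do.call(rbind, ins_all) else NULL
  if (!is.null(ins)) rownames(ins) <- NULL
  truth <- list(
    snps = snp_tab,
    insertions = ins,
    repeats = if (length(rep_all)) do.call(rbind, rep_all) else NULL,
    peaks = peaks,
    genes = do.call(rbind, genes_all),
    cres = if (length(cre_all)) do.call(rbind, cre_all) else NULL,
    genome_sizes = stats::setNames(nchar(genome_a), names(genome_a)),
    library = lib, pwm = pwm, config = config)
  list(genome_a = genome_a, genome_b = genome_b, outgroup = outgroup,
       truth = truth)
}

#' Simulate per-peak ChIP and input counts
#'
#' Expected ChIP count of a sample is `input_mean x lambda x cis(allele)
#' x trans(strain background) x dip`, where the dip multiplier applies
#' when the peak midpoint lies within `dip_radius` of a 3' L1 fragment
#' present on that allele; input counts are proportional to interval
#' length. Pure-strain replicates are independent negative-binomial
#' draws; F1 allelic counts are drawn as a negative-binomial total split
#' binomially at the cis ratio (trans effects cancel between the alleles
#' of a hybrid). Peaks containing no SNP get zero allelic counts (their
#' reads cannot be assigned).
#'
#' @param sim output of [simulate_genome_pair()].
#' @param config the same [sim_config()].
#' @return a `count_table` with samples `A_input`, `A_rep1`, `A_rep2`,
#'   `B_input`, `B_rep1`, `B_rep2`, `F1a_alleleA`, `F1a_alleleB`,
#'   `F1b_alleleA`, `F1b_alleleB`.
#' @export
simulate_chip_counts <- function(sim, config = sim$truth$config) {
  set.seed(config$seed + 1L)
  pk <- sim$truth$peaks
  n <- nrow(pk)
  disp <- config$nb_dispersion
  input_mu <- config$chip_input_mean * (pk$end - pk$start) / 1000
  trans_f1 <- sqrt(pk$trans_a * pk$trans_b)
  mu_a <- input_mu * pk$fe_a_true
  mu_b <- input_mu * pk$fe_b_true
  counts <- cbind(
    A_input = draw_counts(n, input_mu, disp),
    A_rep1 = draw_counts(n, mu_a, disp),
    A_rep2 = draw_counts(n, mu_a, disp),
    B_input = draw_counts(n, input_mu, disp),
    B_rep1 = draw_counts(n, mu_b, disp),
    B_rep2 = draw_counts(n, mu_b, disp))
  # SNP-assignable allelic reads per hybrid
  n_snps <- count_points_in_intervals(
    data.frame(chrom = pk$chrom, start = pk$start, end = pk$end),
    sim$truth$snps$chrom, sim$truth$snps$pos)
  wa <- pk$cis_a * pk$dip_a
  wb <- pk$cis_b * pk$dip_b
  p_a <- wa / (wa + wb)
  tot_mu <- config$allelic_depth * trans_f1 * (wa + wb) / 2 *
    pk$lambda / 3
  for (h in c("F1a", "F1b")) {
    tot <- draw_counts(n, tot_mu, disp)
    tot[n_snps == 0L] <- 0L
    na <- stats::rbinom(n, tot, p_a)
    counts <- cbind(counts, na, tot - na)
    colnames(counts)[ncol(counts) - 1:0] <-
      paste0(h, c("_alleleA", "_alleleB"))
  }
  lib <- stats::setNames(rep(1e6, ncol(counts)), colnames(counts))
  count_table(pk$feature_id,
              genomic_intervals(pk$chrom, pk$start, pk$end),
              counts, lib)
}

#' Simulate a fine-binned ChIP/input track of the reference strain
#'
#' Generates per-bin input and ChIP counts over the reference (strain A)
#' genome. The expected ChIP density is the input density times a
#' regional fold-enrichment field (lognormal per 50-kb window, calibrated
#' so that about 3% of windows exceed 1.5), times the peak enrichment
#' where a bin falls inside a peak, times the dip factor within
#' `dip_radius` of a 3' L1 fragment present on the reference.
#'
#' @param sim output of [simulate_genome_pair()].
#' @param config the same [sim_config()].
#' @param bin_size fine bin width in bp (default 100).
#' @param input_mean expected input reads per fine bin.
#' @param region_size width of the regional-enrichment field (default
#'   50 kb).
#' @param region_sdlog lognormal sdlog of the regional field; the
#'   default is calibrated so about 3% of regions exceed FE 1.5. Set to
#'   0 for a homogeneous background (the clean no-dip control).
#' @return list with `chip` and `input`: per-chromosome integer vectors
#'   of binned counts (class `binned_counts`), plus `bin_size`.
#' @export
simulate_chip_track <- function(sim, config = sim$truth$config,
                                bin_size = 100, input_mean = 50,
                                region_size = 50000,
                                region_sdlog = NULL) {
  set.seed(config$seed + 2L)
  disp <- config$nb_dispersion
  sdlog <- if (is.null(region_sdlog))
    log(1.5) / stats::qnorm(0.97) else region_sdlog
  chip <- list(); input <- list()
  pk <- sim$truth$peaks
  reps <- sim$truth$repeats
  for (ch in names(sim$genome_a)) {
    L <- nchar(sim$genome_a[[ch]])
    nb <- ceiling(L / bin_size)
    mid <- (seq_len(nb) - 0.5) * bin_size
    region <- pmin(ceiling(mid / region_size), ceiling(L / region_size))
    reg_fe <- exp(stats::rnorm(ceiling(L / region_size), 0, sdlog))
    fe <- reg_fe[region]
    pc <- pk[pk$chrom == ch, , drop = FALSE]
    if (nrow(pc)) {
      idx <- findInterval(mid, sort(pc$start))
      # bins inside a peak get the peak's strain-A enrichment
      for (i in seq_len(nrow(pc))) {
        sel <- mid >= pc$start[i] & mid < pc$end[i]
        fe[sel] <- fe[sel] * pc$fe_a_true[i] / pc$dip_a[i]
      }
    }
    if (!is.null(reps)) {
      rc <- reps[reps$chrom == ch & reps$class == "L1" &
                   reps$has_3prime_end, , drop = FALSE]
      if (nrow(rc)) {
        anchor <- (rc$start + rc$end) / 2
        dip <- rep(FALSE, nb)
        for (a in anchor)
          dip <- dip | abs(mid - a) <= config$dip_radius
        fe[dip] <- fe[dip] * config$dip_factor
      }
    }
    input[[ch]] <- draw_counts(nb, input_mean, disp)
    chip[[ch]] <- draw_counts(nb, input_mean * fe, disp)
  }
  list(chip = chip, input = input, bin_size = bin_size)
}

#' Simulate Sanger-like shotgun reads from a genome
#'
#' Reads of `read_length` bp are sampled uniformly from either strand;
#' per-base substitution errors are applied at `sequencing_error_rate`.
#' Read names encode the true origin (`read|chrom|start|strand`) for test
#' introspection. The number of reads is `ceiling(coverage * genome /
#' read_length)`.
#'
#' @param genome named character vector of sequences (e.g. `sim$genome_b`).
#' @param config a [sim_config()].
#' @return named character vector of read sequences.
#' @export
simulate_reads <- function(genome, config) {
  set.seed(config$seed + 3L)
  rl <- config$read_length
  if (any(nchar(genome) < rl))
    stop("read_length exceeds a chromosome length")
  lens <- nchar(genome)
  n_reads <- ceiling(config$coverage * sum(lens) / rl)
  ch <- sample(names(genome), n_reads, replace = TRUE,
               prob = lens / sum(lens))
  start <- floor(stats::runif(n_reads, 0, lens[ch] - rl + 1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- substring(genome[ch], start + 1, start + rl)
  neg <- strand == "-"
  if (any(neg)) reads[neg] <- revcomp(reads[neg])
  er <- config$sequencing_error_rate
  if (er > 0) {
    n_err <- stats::rbinom(n_reads, rl, er)
    for (i in which(n_err > 0)) {
      v <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
      pos <- sample.int(rl, n_err[i])
      v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(DNA_BASES, b), 1L), "")
      reads[i] <- paste(v, collapse = "")
    }
  }
  names(reads) <- sprintf("read%06d|%s|%d|%s", seq_len(n_reads), ch,
                          start, strand)
  reads
}

#' Simulate allelic mRNA counts per gene in the reciprocal hybrids
#'
#' Per gene and hybrid, a negative-binomial total around `expr_depth` is
#' split binomially at the gene's true allelic ratio. With `coupling = 1`
#' the ratio equals the promoter peak's cis ratio exactly.
#'
#' @param sim output of [simulate_genome_pair()].
#' @param config the same [sim_config()].
#' @return a `count_table` over genes with samples `F1a_alleleA`,
#'   `F1a_alleleB`, `F1b_alleleA`, `F1b_alleleB` (intervals are 1-bp TSS
#'   anchors).
#' @export
simulate_expression_counts <- function(sim, config = sim$truth$config) {
  set.seed(config$seed + 4L)
  g <- sim$truth$genes
  n <- nrow(g)
  disp <- config$nb_dispersion
  p_a <- g$expr_freq_true
  counts <- NULL
  for (h in c("F1a", "F1b")) {
    tot <- draw_counts(n, config$expr_depth, disp)
    na <- stats::rbinom(n, tot, p_a)
    counts <- cbind(counts, na, tot - na)
    colnames(counts)[ncol(counts) - 1:0] <-
      paste0(h, c("_alleleA", "_alleleB"))
  }
  lib <- stats::setNames(rep(1e6, ncol(counts)), colnames(counts))
  count_table(g$gene_id,
              genomic_intervals(g$chrom, g$tss, g$tss + 1, g$strand),
              counts, lib)
}
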