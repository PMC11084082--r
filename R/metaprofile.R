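# Genome-binned fold enrichment, hyperacetylated-region selection,
# element-anchored average profiles, and the dip statistic quantifying
# hypoacetylation around short 3' L1 fragments.

#' Binned fold-enrichment track
#'
#' Bins are non-overlapping, tiled from coordinate 0; a trailing partial
#' bin is kept and flagged in `partial`. Bins without data are masked.
#'
#' @param values named list (per chromosome) of per-bin FE vectors.
#' @param bin_size bin width in bp.
#' @param mask named list of logical vectors (`TRUE` = no data).
#' @param partial named list of logical vectors flagging partial bins.
#' @return list of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, mask = NULL, partial = NULL) {
  if (is.null(mask))
    mask <- lapply(values, function(v) is.na(v))
  structure(list(values = values, bin_size = bin_size, mask = mask,
                 partial = partial), class = "binned_track")
}

#' @param x a `binned_track`.
#' @param ... unused.
#' @rdname binned_track
#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track:", length(x$values), "chromosome(s), bin",
      x$bin_size, "bp,", sum(lengths(x$values)), "bins\n")
  invisible(x)
}

#' Genome-wide binned fold enrichment from binned counts
#'
#' Computes per-bin `FE = (chip + pc) / (input + pc)` (with optional
#' library-size normalization) from per-bin ChIP and input counts, e.g.
#' at the 50-kb resolution used to find hyperacetylated regions.
#' Counts at a finer resolution are aggregated to `bin_size` first.
#'
#' @param chip_counts,input_counts named lists of per-bin counts (as
#'   from [simulate_chip_track()]).
#' @param counts_bin_size bin width of the input count vectors.
#' @param bin_size target bin width (multiple of `counts_bin_size`).
#' @param chip_lib,input_lib library sizes (default: totals of the
#'   supplied counts).
#' @param genome_sizes optional named chromosome lengths (to flag the
#'   trailing partial bin).
#' @param pseudocount passed to [compute_fold_enrichment()].
#' @return a [binned_track()].
#' @export
bin_genome_fe <- function(chip_counts, input_counts, counts_bin_size,
                          bin_size = 50000, chip_lib = NULL,
                          input_lib = NULL, genome_sizes = NULL,
                          pseudocount = 0.5) {
  if (bin_size %% counts_bin_size != 0)
    stop("bin_size must be a multiple of counts_bin_size")
  fold <- bin_size / counts_bin_size
  if (is.null(chip_lib)) chip_lib <- sum(unlist(chip_counts))
  if (is.null(input_lib)) input_lib <- sum(unlist(input_counts))
  values <- list(); partial <- list()
  for (ch in names(chip_counts)) {
    n <- length(chip_counts[[ch]])
    grp <- ceiling(seq_len(n) / fold)
    chip <- tapply(chip_counts[[ch]], grp, sum)
    input <- tapply(input_counts[[ch]], grp, sum)
    values[[ch]] <- as.numeric(compute_fold_enrichment(
      chip, input, chip_lib, input_lib, pseudocount))
    nb <- length(values[[ch]])
    p <- rep(FALSE, nb)
    if (!is.null(genome_sizes) && genome_sizes[[ch]] %% bin_size != 0)
      p[nb] <- TRUE
    else if (n %% fold != 0) p[nb] <- TRUE
    partial[[ch]] <- p
  }
  binned_track(values, bin_size, partial = partial)
}

#' Select hyperacetylated bins
#'
#' Bins with `FE >= fe_min` (inclusive), returned as intervals, together
#' with the selected fraction so the expected correspondence (about the
#' top 3% at FE 1.5) can be checked.
#'
#' @param track a `binned_track`.
#' @param fe_min minimum fold enrichment (default 1.5).
#' @return list with `regions` (interval `data.frame`) and `fraction`.
#' @export
select_hyperacetylated <- function(track, fe_min = 1.5) {
  regions <- list(); n_sel <- 0L; n_tot <- 0L
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    ok <- !is.na(v) & !track$mask[[ch]]
    sel <- which(ok & v >= fe_min)
    n_sel <- n_sel + length(sel); n_tot <- n_tot + sum(ok)
    if (length(sel))
      regions[[ch]] <- data.frame(chrom = ch,
                                  start = (sel - 1) * track$bin_size,
                                  end = sel * track$bin_size,
                                  score = v[sel],
                                  stringsAsFactors = FALSE)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               score = numeric())
  rownames(regions) <- NULL
  list(regions = regions, fraction = if (n_tot) n_sel / n_tot else 0)
}

#' Select short 3' L1 fragments as profile anchors
#'
#' L1-class elements whose length is within `[min_len, max_len]` and
#' which contain the consensus 3' end; optionally restricted to those
#' inside hyperacetylated regions.
#'
#' @param repeats repeat annotation `data.frame` with `chrom`, `start`,
#'   `end`, `class` (or `name`), `has_3prime_end`, `strand`.
#' @param min_len,max_len length bounds in bp (defaults 100 and 400).
#' @param within optional interval `data.frame`; anchors must overlap it.
#' @return subset of `repeats` (the anchors).
#' @export
select_short_3prime_l1 <- function(repeats, min_len = 100, max_len = 400,
                                   within = NULL) {
  lab <- if (!is.null(repeats$class)) repeats$class else repeats$name
  len <- repeats$end - repeats$start
  sel <- grepl("^L1", lab, ignore.case = TRUE) & len >= min_len &
    len <= max_len & repeats$has_3prime_end
  out <- repeats[sel, , drop = FALSE]
  if (!is.null(within) && nrow(out))
    out <- out[overlaps_any(out, within), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average fold-enrichment profile around anchor elements
#'
#' Resamples a fine-binned FE signal at `profile_bin` resolution around
#' each anchor midpoint (minus-strand anchors are flipped) and averages
#' across anchors, ignoring masked or out-of-range bins.
#'
#' @param track a `binned_track` of fine-binned FE (bin size must divide
#'   `profile_bin` or equal it).
#' @param anchors interval `data.frame` with optional `strand`.
#' @param flank half-window in bp (default 10000).
#' @param profile_bin profile resolution in bp (default 100).
#' @return list of class `meta_profile`: `offset` (bin-center offsets),
#'   `values` (mean FE per profile bin), `n` (anchors contributing per
#'   bin), `n_anchors`, `flank`, `profile_bin`.
#' @export
anchor_profile <- function(track, anchors, flank = 10000,
                           profile_bin = 100) {
  if (!nrow(anchors)) stop("need at least one anchor")
  if (profile_bin %% track$bin_size != 0)
    stop("profile_bin must be a multiple of the track bin size")
  nb <- 2 * flank / profile_bin
  if (nb != round(nb)) stop("flank must be a multiple of profile_bin")
  nb <- as.integer(nb)
  acc <- numeric(nb); cnt <- numeric(nb)
  strand <- if (!is.null(anchors$strand)) anchors$strand else
    rep("+", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    ch <- anchors$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) next
    mid <- (anchors$start[i] + anchors$end[i]) / 2
    edges <- mid - flank + (0:nb) * profile_bin
    # mean of fine bins whose centers fall in each profile bin
    fine_per <- profile_bin / track$bin_size
    fine_idx <- floor((mid - flank) / track$bin_size) +
      seq_len(nb * fine_per)
    ok <- fine_idx >= 1 & fine_idx <= length(v)
    val <- rep(NA_real_, nb * fine_per)
    val[ok] <- v[fine_idx[ok]]
    val[!ok] <- NA
    m <- matrix(val, nrow = fine_per)
    prof <- colMeans(m, na.rm = TRUE)
    prof[is.nan(prof)] <- NA
    if (strand[i] == "-") prof <- rev(prof)
    has <- !is.na(prof)
    acc[has] <- acc[has] + prof[has]
    cnt[has] <- cnt[has] + 1
  }
  values <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(offset = -flank + (seq_len(nb) - 0.5) * profile_bin,
                 values = values, n = cnt, n_anchors = nrow(anchors),
                 flank = flank, profile_bin = profile_bin),
            class = "meta_profile")
}

#' Dip statistic of a metaprofile
#'
#' Ratio of the mean FE within `center_radius` of the anchor to the mean
#' FE over the remaining flank; values below 1 indicate a local dip. The
#' statistic is invariant to rescaling the whole track.
#'
#' @param profile a `meta_profile`.
#' @param center_radius bp (default 2000; must be < flank).
#' @return the dip ratio (numeric scalar).
#' @export
dip_statistic <- function(profile, center_radius = 2000) {
  if (profile$flank <= center_radius)
    stop("flank must exceed center_radius")
  inside <- abs(profile$offset) <= center_radius
  mean(profile$values[inside], na.rm = TRUE) /
    mean(profile$values[!inside], na.rm = TRUE)
}

#' @param x a `meta_profile`.
#' @param ... passed to [plot()].
#' @rdname anchor_profile
#' @export
plot.meta_profile <- function(x, ...) {
  graphics::plot(x$offset, x$values, type = "l",
                 xlab = "distance from anchor (bp)",
                 ylab = "mean fold enrichment", ...)
  graphics::abline(v = 0, lty = 2, col = "grey")
  invisible(x)
}

#' @rdname anchor_profile
#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", x$n_anchors, "anchors, flank", x$flank,
      "bp, bin", x$profile_bin, "bp\n")
  cat("dip ratio (2 kb):",
      round(dip_statistic(x, min(2000, x$flank / 2)), 3), "\n")
  invisible(x)
}
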