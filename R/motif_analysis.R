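# PWM scanning with an exact (discretized) score null, allele-specific
# presence calls, acetylation association, and outgroup gain/loss
# inference.

DNA_BASES <- c("A", "C", "G", "T")
LOGODDS_FLOOR <- -30  # sentinel for log2(0) cells

#' Build a position weight matrix from base counts
#'
#' Probabilities are `(count + pseudocount) / (column_total +
#' 4 * pseudocount)`; log-odds are `log2(p / q)` against the background
#' `q`. Zero-probability cells (possible only at `pseudocount = 0`) get a
#' finite sentinel of -30.
#'
#' @param counts 4 x width numeric matrix (rows A, C, G, T) or width x 4
#'   (auto-transposed when rownames/ncol indicate).
#' @param pseudocount added to every cell (default 0.1).
#' @param background length-4 base probabilities (default uniform).
#' @param id motif identifier.
#' @return An object of class `pwm` with elements `id`, `width`, `prob`,
#'   `log_odds` (both 4 x width, rows A,C,G,T), `background`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.1,
                            background = rep(0.25, 4), id = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4 && ncol(counts) == 4) counts <- t(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A,C,G,T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(sum(background) - 1) > 1e-8) || any(background <= 0))
    stop("background must be positive and sum to 1")
  rownames(counts) <- DNA_BASES
  prob <- sweep(counts + pseudocount, 2,
                colSums(counts) + 4 * pseudocount, "/")
  lo <- log2(prob / background)
  lo[!is.finite(lo)] <- LOGODDS_FLOOR
  lo <- pmax(lo, LOGODDS_FLOOR)
  structure(list(id = id, width = ncol(prob), prob = prob,
                 log_odds = lo, background = stats::setNames(background,
                                                             DNA_BASES)),
            class = "pwm")
}

#' @param x a `pwm`.
#' @param ... unused.
#' @rdname pwm_from_counts
#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", x$width, "\n")
  print(round(x$prob, 3))
  invisible(x)
}

#' Exact score null of a PWM under the background model
#'
#' Per-position log-odds are discretized at `granularity` bits and the
#' per-position score distributions are convolved across positions by
#' dynamic programming, giving the exact-within-discretization tail
#' probability `P(score' >= s)` for an i.i.d. background sequence.
#'
#' @param pwm a [pwm_from_counts()] object.
#' @param granularity discretization step in bits (> 0), default 1e-3.
#' @return list of class `pwm_score_dist`: `granularity`, `min_score`,
#'   `tail` (vector: `tail[i] = P(S >= min_score + (i-1)*granularity)`).
#' @export
score_pvalue_distribution <- function(pwm, granularity = 1e-3) {
  if (granularity <= 0) stop("granularity must be > 0")
  k <- round(pwm$log_odds / granularity)  # 4 x w integer scores
  lo_sum <- sum(apply(k, 2, min)); hi_sum <- sum(apply(k, 2, max))
  n <- hi_sum - lo_sum + 1
  dist <- numeric(n)
  # dist over offsets relative to running minimum sum
  dist[1L] <- 1
  cur_min <- 0
  cur_len <- 1L
  q <- pwm$background
  for (j in seq_len(pwm$width)) {
    kj <- k[, j]
    new_min <- cur_min + min(kj)
    new_len <- cur_len + (max(kj) - min(kj))
    nd <- numeric(new_len)
    for (b in 1:4) {
      off <- kj[b] - min(kj)
      idx <- seq_len(cur_len) + off
      nd[idx] <- nd[idx] + q[b] * dist[seq_len(cur_len)]
    }
    dist <- nd; cur_min <- new_min; cur_len <- new_len
  }
  tail <- rev(cumsum(rev(dist)))
  structure(list(granularity = granularity,
                 min_score = cur_min * granularity,
                 tail = tail),
            class = "pwm_score_dist")
}

#' @param dist a `pwm_score_dist`.
#' @param score raw log-odds score(s).
#' @return [pwm_tail_p()] returns `P(S >= score)` under the background.
#' @rdname score_pvalue_distribution
#' @export
pwm_tail_p <- function(dist, score) {
  i <- round((score - dist$min_score) / dist$granularity) + 1
  i <- pmin(pmax(i, 1L), length(dist$tail) + 1L)
  c(dist$tail, 0)[i]
}

#' @param p_threshold p-value cutoff.
#' @return [pwm_score_threshold()] returns the minimal raw score whose
#'   tail probability is `<= p_threshold`.
#' @rdname score_pvalue_distribution
#' @export
pwm_score_threshold <- function(pwm, p_threshold = 1e-4,
                                granularity = 1e-3) {
  dist <- score_pvalue_distribution(pwm, granularity)
  i <- which(dist$tail <= p_threshold)
  if (!length(i)) return(Inf)
  dist$min_score + (min(i) - 1) * dist$granularity
}

encode_dna <- function(seq) {
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], DNA_BASES)
  v
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
           ""))
}

scan_one_strand <- function(lo, codes) {
  w <- ncol(lo); L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  sc <- numeric(n)
  ok <- rep(TRUE, n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    bad <- is.na(cj)
    ok <- ok & !bad
    cj[bad] <- 1L
    sc <- sc + lo[cbind(cj, j)]
  }
  sc[!ok] <- -Inf
  sc
}

#' Scan a sequence for PWM occurrences
#'
#' Scores every position on both strands and reports hits whose exact
#' tail p-value is `<= p_threshold`. Positions containing `N` are
#' skipped.
#'
#' @param pwm a `pwm`.
#' @param seq a single DNA string.
#' @param p_threshold per-position p-value cutoff (default 1e-4).
#' @param both_strands scan the reverse complement too.
#' @param dist optional precomputed [score_pvalue_distribution()].
#' @return `data.frame` of occurrences: `offset` (0-based start on the
#'   forward sequence), `strand`, `score`, `p_value`.
#' @export
scan_sequence <- function(pwm, seq, p_threshold = 1e-4,
                          both_strands = TRUE, dist = NULL) {
  if (is.null(dist)) dist <- score_pvalue_distribution(pwm)
  thr_idx <- which(dist$tail <= p_threshold)
  thr <- if (length(thr_idx))
    dist$min_score + (min(thr_idx) - 1) * dist$granularity else Inf
  L <- nchar(seq)
  res <- list()
  codes <- encode_dna(seq)
  sc <- scan_one_strand(pwm$log_odds, codes)
  hit <- which(sc >= thr - 1e-12)
  if (length(hit))
    res[[1L]] <- data.frame(offset = hit - 1L, strand = "+",
                            score = sc[hit])
  if (both_strands) {
    sc2 <- scan_one_strand(pwm$log_odds, encode_dna(revcomp(seq)))
    hit2 <- which(sc2 >= thr - 1e-12)
    if (length(hit2))
      res[[length(res) + 1L]] <- data.frame(
        offset = L - pwm$width - (hit2 - 1L), strand = "-",
        score = sc2[hit2])
  }
  if (!length(res))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric(), p_value = numeric()))
  out <- do.call(rbind, res)
  out$p_value <- pwm_tail_p(dist, out$score)
  out[order(out$offset), , drop = FALSE]
}

#' Scan the two allelic versions of a peak
#'
#' @param seq_a,seq_b allelic sequences of one peak (SNP-substituted).
#' @inheritParams scan_sequence
#' @return list with `occurrences_a`, `occurrences_b`, `presence_a`,
#'   `presence_b`, and `differential` (`presence_a != presence_b`).
#' @export
scan_alleles <- function(pwm, seq_a, seq_b, p_threshold = 1e-4,
                         dist = NULL) {
  if (is.null(dist)) dist <- score_pvalue_distribution(pwm)
  oa <- scan_sequence(pwm, seq_a, p_threshold, dist = dist)
  ob <- scan_sequence(pwm, seq_b, p_threshold, dist = dist)
  list(occurrences_a = oa, occurrences_b = ob,
       presence_a = nrow(oa) > 0, presence_b = nrow(ob) > 0,
       differential = (nrow(oa) > 0) != (nrow(ob) > 0))
}

#' Association of differential motif presence with acetylation state
#'
#' Given, per allele-specific peak, whether a motif is present only in
#' the hyperacetylated allele (`a` such peaks) or only in the
#' hypoacetylated allele (`b`), tests the symmetry of (`a`, `b`) with a
#' 1-df goodness-of-fit chi-square against equal expected counts.
#' `method = "2x2"` instead tests a 2x2 table of differential vs
#' non-differential peaks by direction.
#'
#' @param a count of hyper-only peaks.
#' @param b count of hypo-only peaks.
#' @param method `"gof"` (default) or `"2x2"`.
#' @param n_hyper,n_hypo totals needed for `method = "2x2"`.
#' @return list with `chisq`, `p_value`, `a`, `b` (`NA` statistics when
#'   `a + b == 0`).
#' @export
motif_acetylation_association <- function(a, b, method = c("gof", "2x2"),
                                          n_hyper = NULL, n_hypo = NULL) {
  method <- match.arg(method)
  if (a + b == 0)
    return(list(chisq = NA_real_, p_value = NA_real_, a = a, b = b))
  if (method == "gof") {
    ct <- suppressWarnings(stats::chisq.test(c(a, b), p = c(0.5, 0.5)))
  } else {
    if (is.null(n_hyper) || is.null(n_hypo))
      stop("2x2 method needs n_hyper and n_hypo totals")
    tab <- rbind(c(a, n_hyper - a), c(b, n_hypo - b))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  list(chisq = unname(ct$statistic), p_value = ct$p.value, a = a, b = b)
}

#' Outgroup-based gain/loss inference for differential motifs
#'
#' For each differential peak, compares motif presence in the
#' hyperacetylated allele, the hypoacetylated allele, and the outgroup
#' (ancestral proxy): a motif present in one derived allele but absent
#' from the outgroup is a gain on that lineage; present in the outgroup
#' but absent from one allele is a loss. Non-differential peaks and
#' peaks with no alignable outgroup are `ambiguous`/`none`. Vectorized.
#'
#' @param present_hyper,present_hypo,present_outgroup logical vectors
#'   (`NA` outgroup = unalignable).
#' @return character vector in `{gain_in_hyper, loss_in_hypo,
#'   gain_in_hypo, loss_in_hyper, ambiguous, none}`.
#' @export
infer_gain_loss <- function(present_hyper, present_hypo,
                            present_outgroup) {
  out <- rep("none", length(present_hyper))
  diffp <- present_hyper != present_hypo
  out[diffp & is.na(present_outgroup)] <- "ambiguous"
  ok <- diffp & !is.na(present_outgroup)
  out[ok & present_hyper & !present_outgroup] <- "gain_in_hyper"
  out[ok & present_hyper & present_outgroup] <- "loss_in_hypo"
  out[ok & present_hypo & !present_outgroup] <- "gain_in_hypo"
  out[ok & present_hypo & present_outgroup] <- "loss_in_hyper"
  out
}

#' Extract the two allelic (and ancestral) sequences of an interval
#'
#' Takes the reference (strain A) sequence of the interval and builds the
#' B-allele version by substituting the B allele at every SNP inside the
#' interval; when the SNP table carries an `ancestral` column, an
#' outgroup version is built the same way.
#'
#' @param genome named character vector (reference genome, strain A).
#' @param interval single-row interval `data.frame`.
#' @param snps a `snp_table` in reference coordinates, optionally with an
#'   `ancestral` base column.
#' @return list with `a`, `b`, and (if available) `outgroup` strings.
#' @export
allele_sequences <- function(genome, interval, snps) {
  s <- substr(genome[[interval$chrom]], interval$start + 1, interval$end)
  sel <- snps$chrom == interval$chrom & snps$pos >= interval$start &
    snps$pos < interval$end
  rel <- snps$pos[sel] - interval$start + 1
  sub_at <- function(str, pos, bases) {
    v <- strsplit(str, "", fixed = TRUE)[[1L]]
    v[pos] <- bases
    paste(v, collapse = "")
  }
  out <- list(a = sub_at(s, rel, snps$allele_a[sel]),
              b = sub_at(s, rel, snps$allele_b[sel]))
  if (!is.null(snps$ancestral))
    out$outgroup <- sub_at(s, rel, snps$ancestral[sel])
  out
}

#' Read and write PWMs
#'
#' `read_meme()` parses MEME minimal motif format (letter-probability
#' matrices); `read_pwm_tsv()` reads a plain count-matrix TSV (columns
#' A, C, G, T; one row per position; `#` comments).
#'
#' @param path file path.
#' @param pseudocount,background passed to [pwm_from_counts()].
#' @return a list of `pwm` objects (`read_meme`) or a single `pwm`
#'   (`read_pwm_tsv`).
#' @export
read_meme <- function(path, pseudocount = 0, background = NULL) {
  lines <- readLines(path)
  bg <- background
  bgi <- grep("^Background letter frequencies", lines)
  if (is.null(bg) && length(bgi)) {
    f <- strsplit(trimws(lines[bgi + 1L]), "\\s+")[[1L]]
    bg <- as.numeric(f[c(2, 4, 6, 8)])
  }
  if (is.null(bg)) bg <- rep(0.25, 4)
  starts <- grep("^MOTIF\\b", lines)
  pwms <- list()
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1L]][2L]
    hi <- grep("^letter-probability matrix", lines[s:length(lines)])[1L] + s - 1L
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
    rows <- lines[(hi + 1L):(hi + w)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(f) as.numeric(f[1:4]), numeric(4)))
    # probabilities scaled to pseudo-counts of 1000 sites
    pwms[[id]] <- pwm_from_counts(t(m) * 1000, pseudocount = pseudocount,
                                  background = bg, id = id)
  }
  pwms
}

#' @param pwms a list of `pwm` objects (or a single one).
#' @rdname read_meme
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  bg <- pwms[[1L]]$background
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "", "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f",
                   bg[1], bg[2], bg[3], bg[4]), "")
  for (p in pwms) {
    out <- c(out, paste("MOTIF", p$id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1000 E= 0",
                     p$width),
             apply(p$prob, 2, function(col)
               sprintf(" %.6f %.6f %.6f %.6f", col[1], col[2], col[3],
                       col[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname read_meme
#' @export
read_pwm_tsv <- function(path, pseudocount = 0.1,
                         background = rep(0.25, 4)) {
  m <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#")
  pwm_from_counts(t(as.matrix(m[, c("A", "C", "G", "T")])),
                  pseudocount = pseudocount, background = background,
                  id = tools::file_path_sans_ext(basename(path)))
}
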