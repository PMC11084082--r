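# Split-read indel discovery from long (Sanger-like) shotgun reads
# aligned to the reference genome of strain A: exact k-mer seeding
# against a sorted reference index, diagonal clustering into local
# segments, deterministic base-wise junction refinement, and insertion
# calling from the gap structure. Insertions present in the reference
# (carrier A, i.e. deletions in the read's strain) appear as split
# matches sandwiching a reference interval; insertions carried by the
# read's strain (carrier B) appear as read-side gaps and are length-
# limited by the read length.

#' Alignment parameters for the split-read caller
#'
#' @param k seed k-mer length.
#' @param stride spacing between seed start positions along the read.
#' @param min_seed minimum read length accepted.
#' @param diag_tol maximum diagonal scatter within one segment.
#' @param read_adjacency_tol maximum read-coordinate gap between the two
#'   matched parts of a split read for a carrier-A call.
#' @param ref_adjacency_tol maximum reference-coordinate gap for a
#'   carrier-B (read-side) insertion call.
#' @param max_seed_hits seeds hitting more reference positions than this
#'   are discarded as repetitive.
#' @param match,mismatch alignment scoring used for segment scores.
#' @return list of class `align_params`.
#' @export
align_params <- function(k = 15, stride = 20, min_seed = 50,
                         diag_tol = 30, read_adjacency_tol = 20,
                         ref_adjacency_tol = 20, max_seed_hits = 8,
                         match = 1, mismatch = -2) {
  structure(as.list(environment()), class = "align_params")
}

# encode a DNA string as a numeric vector of k-mer codes (base-4),
# one per start position; NA where any base is not ACGT
kmer_codes <- function(seq, k) {
  b <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES) - 1
  n <- length(b) - k + 1L
  if (n < 1L) return(numeric(0))
  code <- numeric(n)
  for (j in seq_len(k)) code <- code * 4 + b[j:(j + n - 1L)]
  code
}

#' Build a k-mer index of a reference genome
#'
#' @param reference named character vector of chromosome sequences.
#' @param k k-mer length.
#' @return list used by [align_reads()]; contains the sorted code array
#'   with chromosome and position lookups.
#' @export
build_reference_index <- function(reference, k = 15) {
  codes <- list(); chrom <- list(); pos <- list()
  for (i in seq_along(reference)) {
    cc <- kmer_codes(reference[[i]], k)
    keep <- which(!is.na(cc))
    codes[[i]] <- cc[keep]
    chrom[[i]] <- rep.int(i, length(keep))
    pos[[i]] <- keep - 1L
  }
  codes <- unlist(codes); chrom <- unlist(chrom); pos <- unlist(pos)
  o <- order(codes)
  list(codes = codes[o], chrom = chrom[o], pos = pos[o],
       chrom_names = names(reference), k = k)
}

# look up one vector of query codes; returns data.frame(query index,
# chrom index, ref pos), capped at max_hits per query
index_lookup <- function(index, q, max_hits) {
  lo <- findInterval(q - 0.5, index$codes)
  hi <- findInterval(q + 0.5, index$codes)
  n <- pmin(hi - lo, max_hits)
  n[is.na(q)] <- 0L
  qi <- rep.int(seq_along(q), n)
  ii <- sequence(n) + rep.int(lo, n)
  data.frame(query = qi, chrom = index$chrom[ii], pos = index$pos[ii])
}

# cluster one read-orientation's seed hits into segments by diagonal
cluster_hits <- function(read_pos, chrom, ref_pos, k, diag_tol) {
  diag <- ref_pos - read_pos
  o <- order(chrom, diag, read_pos)
  read_pos <- read_pos[o]; chrom <- chrom[o]; ref_pos <- ref_pos[o]
  diag <- diag[o]
  brk <- c(TRUE, diff(chrom) != 0 | diff(diag) > diag_tol)
  gid <- cumsum(brk)
  segs <- do.call(rbind, lapply(split(seq_along(gid), gid), function(ii) {
    data.frame(chrom = chrom[ii[1L]],
               read_start = min(read_pos[ii]),
               read_end = max(read_pos[ii]) + k,
               diag = stats::median(diag[ii]),
               n_seeds = length(ii))
  }))
  segs$ref_start <- segs$read_start + segs$diag
  segs$ref_end <- segs$read_end + segs$diag
  # multi-mapping flag: another segment (a different reference placement)
  # covers most of the same read span, as happens when a read part lies
  # in a repeat with several near-identical genomic copies
  n <- nrow(segs)
  segs$multi <- FALSE
  if (n > 1L) {
    for (i in seq_len(n)) {
      li <- segs$read_end[i] - segs$read_start[i]
      ov <- pmin(segs$read_end, segs$read_end[i]) -
        pmax(segs$read_start, segs$read_start[i])
      segs$multi[i] <- any(ov[-i] >= 0.8 * li)
    }
  }
  # drop segments nested in a stronger one (read coordinates)
  keep <- rep(TRUE, nrow(segs))
  o2 <- order(-segs$n_seeds)
  taken <- NULL
  for (i in o2) {
    if (!is.null(taken) &&
        any(segs$read_start[i] >= taken[, 1] - 5 &
              segs$read_end[i] <= taken[, 2] + 5)) {
      keep[i] <- FALSE
    } else taken <- rbind(taken, c(segs$read_start[i], segs$read_end[i]))
  }
  segs <- segs[keep, , drop = FALSE]
  segs[order(segs$read_start), , drop = FALSE]
}

# optimal chain of segments along the read: maximizes covered read
# length minus junction penalties. A colinear same-chromosome junction
# costs a small opening charge plus a near-zero per-base extension (the
# "minimum gap penalty"), so genuine split matches survive while
# alternative mappings of repeat-derived read parts (which always
# compete with a contiguous alignment) are discarded.
chain_segments <- function(segs) {
  n <- nrow(segs)
  if (n <= 1L) return(segs)
  len <- segs$read_end - segs$read_start
  best <- len
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ov <- segs$read_end[j] - segs$read_start[i]
      if (ov > 30) next
      read_gap <- max(0, -ov)
      colinear <- segs$chrom[j] == segs$chrom[i] &&
        segs$ref_start[i] >= segs$ref_end[j] - 30
      pen <- if (colinear)
        2 + 5e-4 * max(0, segs$ref_start[i] - segs$ref_end[j]) +
          0.1 * read_gap
      else 25 + 0.1 * read_gap
      # discourage routing the chain through repeat-ambiguous segments:
      # a contiguous interpretation should win where one exists
      if (segs$multi[i]) pen <- pen + 10
      sc <- best[j] + len[i] - max(0, ov) - pen
      if (sc > best[i]) { best[i] <- sc; prev[i] <- j }
    }
  }
  i <- which.max(best)
  path <- integer(0)
  while (i > 0L) { path <- c(i, path); i <- prev[i] }
  segs[path, , drop = FALSE]
}

# deterministic base-wise extension: extend a match rightwards while
# tolerating isolated mismatches; stops at two consecutive mismatches,
# then trims trailing mismatches. rv/fv are aligned character vectors.
extend_len <- function(rv, fv) {
  m <- length(rv)
  if (m == 0L) return(0L)
  mis <- rv != fv
  stop2 <- which(mis & c(mis[-1L], TRUE))
  len <- if (length(stop2)) stop2[1L] - 1L else m
  while (len > 0L && mis[len]) len <- len - 1L
  len
}

ref_window <- function(ref_str, from, m) {
  # char vector of ref_str[from+1 .. from+m] (0-based from), clipped
  if (m <= 0) return(character(0))
  strsplit(substr(ref_str, from + 1, from + m), "", fixed = TRUE)[[1L]]
}

refine_pair <- function(rvec, ref_str, s1, s2) {
  ref_len <- nchar(ref_str)
  # extend s1 right
  i <- s1$read_end; r <- s1$ref_end
  m <- min(length(rvec) - i, ref_len - r)
  if (m > 0) {
    e <- extend_len(rvec[(i + 1):(i + m)], ref_window(ref_str, r, m))
    s1$read_end <- i + e; s1$ref_end <- r + e
  }
  # extend s2 left
  i <- s2$read_start; r <- s2$ref_start
  m <- min(i, r)
  if (m > 0) {
    e <- extend_len(rev(rvec[(i - m + 1):i]),
                    rev(ref_window(ref_str, r - m, m)))
    s2$read_start <- i - e; s2$ref_start <- r - e
  }
  # trim any read-coordinate overlap created by the extensions
  ov <- s1$read_end - s2$read_start
  if (ov > 0) {
    s1$read_end <- s1$read_end - ov
    s1$ref_end <- s1$ref_end - ov
  }
  list(s1 = s1, s2 = s2)
}

#' Align one long read to a reference
#'
#' Seeds the read with exact k-mers on both strands, keeps the
#' orientation with more seed matches, clusters seed hits by diagonal
#' into local segments, refines the junction between consecutive
#' segments base-by-base (tolerating isolated substitutions), and scores
#' each segment with match +1 / mismatch -2 (equivalent to the optimal
#' gapless local score over the segment span).
#'
#' @param read a single read sequence.
#' @param reference named character vector of chromosome sequences (or a
#'   prebuilt [build_reference_index()] passed as `index`).
#' @param params an [align_params()].
#' @param index optional prebuilt reference index.
#' @return list of class `read_alignment`: `read_id`, `strand`, and
#'   `segments` (`data.frame` with `chrom`, `read_start`, `read_end`,
#'   `ref_start`, `ref_end`, `n_seeds`, `score`; read coordinates refer
#'   to the oriented read). Empty segments when nothing seeds.
#' @export
align_read <- function(read, reference, params = align_params(),
                       index = NULL) {
  if (!nchar(read)) stop("empty read")
  if (nchar(read) < params$min_seed)
    stop("read shorter than min_seed")
  if (is.null(index)) index <- build_reference_index(reference, params$k)
  res <- align_reads(stats::setNames(read, "read1"), reference,
                     params = params, index = index,
                     detailed_scores = TRUE)
  if (!length(res))
    return(structure(list(read_id = "read1", strand = "+",
                          segments = data.frame(
                            chrom = character(), read_start = numeric(),
                            read_end = numeric(), diag = numeric(),
                            n_seeds = integer(), ref_start = numeric(),
                            ref_end = numeric(), multi = logical(),
                            score = numeric())),
                     class = "read_alignment"))
  res[[1L]]
}

#' Align a batch of reads
#'
#' Batch version of [align_read()]: one index lookup over all seeds of
#' all reads, then per-read clustering. Junction refinement and exact
#' segment scores are computed for reads with more than one segment (the
#' only ones that can yield indel calls); single-segment reads carry a
#' seed-based approximate score unless `detailed_scores = TRUE`.
#'
#' @param reads named character vector of read sequences.
#' @param reference named character vector of chromosome sequences.
#' @param params an [align_params()].
#' @param index optional prebuilt [build_reference_index()].
#' @param detailed_scores force exact scoring of every segment.
#' @return list of `read_alignment` objects (one per read with >= 1
#'   seeded segment; reads with no seed hits are dropped).
#' @export
align_reads <- function(reads, reference, params = align_params(),
                        index = NULL, detailed_scores = FALSE) {
  if (is.null(index)) index <- build_reference_index(reference, params$k)
  k <- params$k
  offs <- function(L) unique(c(seq(1L, L - k + 1L, by = params$stride),
                               L - k + 1L))
  out <- vector("list", length(reads))
  # gather seed codes for both orientations of every read
  q_list <- list(); meta <- list()
  for (i in seq_along(reads)) {
    L <- nchar(reads[[i]])
    if (L < params$min_seed) next
    for (ori in c("+", "-")) {
      s <- if (ori == "+") reads[[i]] else revcomp(reads[[i]])
      cc <- kmer_codes(s, k)
      op <- offs(L)
      q_list[[length(q_list) + 1L]] <- cc[op]
      meta[[length(meta) + 1L]] <- data.frame(read = i, ori = ori,
                                              read_pos = op - 1L)
    }
  }
  if (!length(q_list)) return(list())
  q <- unlist(q_list)
  meta <- do.call(rbind, meta)
  hits <- index_lookup(index, q, params$max_seed_hits)
  hits$read <- meta$read[hits$query]
  hits$ori <- meta$ori[hits$query]
  hits$read_pos <- meta$read_pos[hits$query]
  sp <- split(hits, hits$read)
  for (key in names(sp)) {
    h <- sp[[key]]
    i <- h$read[1L]
    n_plus <- sum(h$ori == "+")
    ori <- if (n_plus >= nrow(h) - n_plus) "+" else "-"
    h <- h[h$ori == ori, , drop = FALSE]
    if (!nrow(h)) next
    segs <- cluster_hits(h$read_pos, h$chrom, h$pos, k, params$diag_tol)
    segs <- chain_segments(segs)
    segs$chrom <- index$chrom_names[segs$chrom]
    # repeat-ambiguous chain parts are kept aside: indel junctions must
    # be anchored in uniquely mapping segments on both sides
    repeat_segs <- segs[segs$multi, , drop = FALSE]
    segs <- segs[!segs$multi, , drop = FALSE]
    rvec <- strsplit(if (ori == "+") reads[[i]] else revcomp(reads[[i]]),
                     "", fixed = TRUE)[[1L]]
    if (nrow(segs) > 1L || (detailed_scores && nrow(segs))) {
      segs <- refine_alignment_named(segs, rvec, reference, params)
    } else if (nrow(segs)) {
      segs$score <- segs$n_seeds * k  # seed-based lower bound
    }
    out[[i]] <- structure(list(read_id = names(reads)[i], strand = ori,
                               segments = segs,
                               repeat_segments = repeat_segs),
                          class = "read_alignment")
  }
  out[!vapply(out, is.null, TRUE)]
}

refine_alignment_named <- function(segs, rvec, reference, params) {
  if (nrow(segs) > 1L) {
    for (j in seq_len(nrow(segs) - 1L)) {
      if (segs$chrom[j] != segs$chrom[j + 1L]) next
      rp <- refine_pair(rvec, reference[[segs$chrom[j]]],
                        segs[j, ], segs[j + 1L, ])
      segs[j, ] <- rp$s1; segs[j + 1L, ] <- rp$s2
    }
  }
  segs$score <- vapply(seq_len(nrow(segs)), function(j) {
    rs <- rvec[(segs$read_start[j] + 1):segs$read_end[j]]
    fs <- ref_window(reference[[segs$chrom[j]]], segs$ref_start[j],
                     segs$ref_end[j] - segs$ref_start[j])
    n_mis <- sum(rs != fs)
    params$match * (length(rs) - n_mis) + params$mismatch * n_mis
  }, 0)
  segs
}

#' @param x a `read_alignment`.
#' @param ... unused.
#' @rdname align_read
#' @export
print.read_alignment <- function(x, ...) {
  cat("read_alignment", x$read_id, "strand", x$strand, "\n")
  print(x$segments)
  invisible(x)
}

#' Call short indels (< `max_len`) from a gapped read alignment
#'
#' A reference-side gap of length `g < max_len` between two consecutive
#' same-chromosome segments is a carrier-A insertion (deletion in the
#' read's strain); a read-side gap is a carrier-B insertion whose
#' sequence is taken from the read. Gaps of `max_len` or more are left to
#' [call_long_insertions()]. Junctions anchored in a multi-mapping
#' (repeat-ambiguous) segment are never called.
#'
#' @param aln a `read_alignment`.
#' @param read the read sequence (oriented as aligned; needed to extract
#'   carrier-B inserted sequence). Optional for carrier-A-only calling.
#' @param max_len strict upper bound for a short call (default 300).
#' @param params an [align_params()].
#' @return `data.frame` of calls: `chrom`, `ref_start`, `ref_end`,
#'   `length`, `carrier`, `inserted_seq`, `read_id`.
#' @export
call_short_indels <- function(aln, read = NULL, max_len = 300,
                              params = align_params()) {
  empty <- indel_calls_empty()
  segs <- aln$segments
  if (nrow(segs) < 2L) return(empty)
  out <- list()
  for (j in seq_len(nrow(segs) - 1L)) {
    s1 <- segs[j, ]; s2 <- segs[j + 1L, ]
    if (s1$chrom != s2$chrom) next
    if (isTRUE(s1$multi) || isTRUE(s2$multi)) next
    ref_gap <- s2$ref_start - s1$ref_end
    read_gap <- s2$read_start - s1$read_end
    if (ref_gap > 0 && ref_gap < max_len &&
        read_gap <= params$read_adjacency_tol) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = s1$chrom, ref_start = s1$ref_end, ref_end = s2$ref_start,
        length = ref_gap, carrier = "A", inserted_seq = NA_character_,
        read_id = aln$read_id, stringsAsFactors = FALSE)
    } else if (read_gap > 0 && read_gap < max_len &&
               ref_gap <= params$ref_adjacency_tol) {
      iseq <- if (!is.null(read))
        substr(read, s1$read_end + 1, s2$read_start) else NA_character_
      out[[length(out) + 1L]] <- data.frame(
        chrom = s1$chrom, ref_start = s1$ref_end, ref_end = s1$ref_end,
        length = read_gap, carrier = "B", inserted_seq = iseq,
        read_id = aln$read_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Call long reference insertions from split read matches
#'
#' For each consecutive pair of segments on the same chromosome (and, by
#' construction of the aligner, same orientation) whose read-coordinate
#' gap is at most `read_adjacency_tol` and whose sandwiched reference
#' interval is at least `min_len`, emits a carrier-A insertion over that
#' interval. Split matches on different chromosomes or strands are never
#' called, mirroring the collection rule for split shotgun reads.
#'
#' @param aln a `read_alignment`.
#' @param min_len minimum sandwiched length (default 300).
#' @param read_adjacency_tol maximum read-coordinate gap (default 20).
#' @return `data.frame` of calls as in [call_short_indels()].
#' @export
call_long_insertions <- function(aln, min_len = 300,
                                 read_adjacency_tol = 20) {
  empty <- indel_calls_empty()
  segs <- aln$segments
  if (nrow(segs) < 2L) return(empty)
  out <- list()
  for (j in seq_len(nrow(segs) - 1L)) {
    s1 <- segs[j, ]; s2 <- segs[j + 1L, ]
    if (s1$chrom != s2$chrom) next
    if (isTRUE(s1$multi) || isTRUE(s2$multi)) next
    ref_gap <- s2$ref_start - s1$ref_end
    read_gap <- s2$read_start - s1$read_end
    if (ref_gap >= min_len && read_gap >= 0 &&
        read_gap <= read_adjacency_tol) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = s1$chrom, ref_start = s1$ref_end, ref_end = s2$ref_start,
        length = ref_gap, carrier = "A", inserted_seq = NA_character_,
        read_id = aln$read_id, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

indel_calls_empty <- function() {
  data.frame(chrom = character(), ref_start = numeric(),
             ref_end = numeric(), length = numeric(),
             carrier = character(), inserted_seq = character(),
             read_id = character(), stringsAsFactors = FALSE)
}

#' Merge per-read indel calls and annotate with repeat classes
#'
#' Calls of the same carrier on the same chromosome whose boundaries lie
#' within `merge_tolerance` are collapsed (median boundaries, summed
#' support). Carrier-A inserted sequences are filled from the reference.
#' `element_class` is the label of the repeat covering at least half of
#' the inserted interval; `has_3prime_end` is true when the inserted
#' sequence's best local alignment to the L1 consensus ends within 30 bp
#' of the consensus 3' terminus.
#'
#' @param calls `data.frame` of per-read calls.
#' @param repeats optional repeat annotation (`chrom`, `start`, `end`,
#'   `name` and/or `class`) in reference coordinates.
#' @param l1_consensus optional L1 consensus sequence.
#' @param reference optional named character vector (to extract carrier-A
#'   inserted sequences).
#' @param merge_tolerance boundary tolerance in bp (default 20).
#' @param min_support drop merged calls with fewer supporting reads.
#' @return `data.frame` of merged calls with `support`, `element_class`,
#'   `has_3prime_end`.
#' @export
merge_and_annotate <- function(calls, repeats = NULL, l1_consensus = NULL,
                               reference = NULL, merge_tolerance = 20,
                               min_support = 1L) {
  if (!nrow(calls)) {
    out <- indel_calls_empty()
    out$support <- integer(); out$element_class <- character()
    out$has_3prime_end <- logical(); out$read_id <- NULL
    return(out)
  }
  calls <- calls[order(calls$chrom, calls$carrier, calls$ref_start,
                       calls$ref_end), , drop = FALSE]
  key <- paste(calls$chrom, calls$carrier)
  merged <- list()
  for (kk in unique(key)) {
    cc <- calls[key == kk, , drop = FALSE]
    gid <- integer(nrow(cc)); g <- 0L
    ref_s <- -Inf; ref_e <- -Inf
    for (i in seq_len(nrow(cc))) {
      if (abs(cc$ref_start[i] - ref_s) > merge_tolerance ||
          abs(cc$ref_end[i] - ref_e) > merge_tolerance) {
        g <- g + 1L; ref_s <- cc$ref_start[i]; ref_e <- cc$ref_end[i]
      }
      gid[i] <- g
    }
    for (gg in unique(gid)) {
      m <- cc[gid == gg, , drop = FALSE]
      iseq <- m$inserted_seq[!is.na(m$inserted_seq)]
      merged[[length(merged) + 1L]] <- data.frame(
        chrom = m$chrom[1L],
        ref_start = round(stats::median(m$ref_start)),
        ref_end = round(stats::median(m$ref_end)),
        length = round(stats::median(m$length)),
        carrier = m$carrier[1L],
        inserted_seq = if (length(iseq)) iseq[1L] else NA_character_,
        support = nrow(m), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, merged)
  out <- out[out$support >= min_support, , drop = FALSE]
  if (!is.null(reference)) {
    fill <- out$carrier == "A" & is.na(out$inserted_seq)
    out$inserted_seq[fill] <- substring(
      unlist(reference[out$chrom[fill]]), out$ref_start[fill] + 1,
      out$ref_end[fill])
  }
  out$element_class <- "none"
  if (!is.null(repeats)) {
    lab <- if (!is.null(repeats$class)) repeats$class else repeats$name
    for (i in which(out$carrier == "A")) {
      sel <- repeats$chrom == out$chrom[i]
      if (!any(sel)) next
      ov <- pmin(repeats$end[sel], out$ref_end[i]) -
        pmax(repeats$start[sel], out$ref_start[i])
      cov <- ov / out$length[i]
      if (any(cov >= 0.5))
        out$element_class[i] <- lab[sel][which.max(cov)]
    }
  }
  out$has_3prime_end <- FALSE
  if (!is.null(l1_consensus)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -2)
    # the 3'-containment question only involves the consensus tail, so
    # align the ends of the inserted sequence (either orientation)
    # against a tail window of the consensus
    win <- 1500L
    tail_off <- max(0L, nchar(l1_consensus) - win)
    subj <- Biostrings::DNAString(substr(l1_consensus, tail_off + 1,
                                         nchar(l1_consensus)))
    for (i in seq_len(nrow(out))) {
      s <- out$inserted_seq[i]
      if (is.na(s) || !nzchar(s)) next
      L <- nchar(s)
      qwin <- unique(c(substr(s, max(1, L - win + 1), L),
                       substr(s, 1, min(L, win))))
      qwin <- c(qwin, revcomp(qwin))
      best_score <- -Inf; best_end <- NA
      for (qs in qwin) {
        pa <- tryCatch(Biostrings::pairwiseAlignment(
          Biostrings::DNAString(qs), subj, type = "local",
          substitutionMatrix = mat, gapOpening = 2, gapExtension = 0.5),
          error = function(e) NULL)
        if (is.null(pa)) next
        sc <- Biostrings::score(pa)
        if (sc > best_score) {
          best_score <- sc
          best_end <- tail_off + IRanges::end(Biostrings::subject(pa))
        }
      }
      # require a real match, not a spurious microalignment
      if (is.finite(best_score) && best_score >= 25 &&
          best_end >= nchar(l1_consensus) - 30)
        out$has_3prime_end[i] <- TRUE
      # class fallback must see the whole consensus, not just its tail:
      # middle fragments are L1 too
      if (out$element_class[i] == "none") {
        full <- Biostrings::DNAString(l1_consensus)
        fs <- -Inf
        for (qs in qwin) {
          pa <- tryCatch(Biostrings::pairwiseAlignment(
            Biostrings::DNAString(qs), full, type = "local",
            substitutionMatrix = mat, gapOpening = 2,
            gapExtension = 0.5), error = function(e) NULL)
          if (!is.null(pa)) fs <- max(fs, Biostrings::score(pa))
        }
        if (is.finite(fs) && fs >= 0.5 * min(L, win))
          out$element_class[i] <- "L1"
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Proximity of differentially acetylated regions to insertions
#'
#' A DAR is matched when its boundary lies within `proximity_bp`
#' (inclusive) of an insertion point; significance by the interval
#' permutation test with the `proximity_count` statistic.
#'
#' @param dars interval `data.frame` of DARs (e.g. B-specific peaks).
#' @param calls merged insertion calls (carrier A).
#' @param genome_sizes named chromosome lengths.
#' @param proximity_bp matching window (default 2000).
#' @param n_perm,seed permutation parameters.
#' @return list with `matched` (logical per DAR), `n_matched`,
#'   `fraction`, and `perm` (a `permutation_test`).
#' @export
dar_indel_proximity <- function(dars, calls, genome_sizes,
                                proximity_bp = 2000, n_perm = 999,
                                seed = NULL) {
  pts <- data.frame(chrom = calls$chrom, start = calls$ref_start,
                    end = calls$ref_start + 1)
  matched <- overlaps_any(expand_intervals(dars, proximity_bp), pts)
  perm <- permutation_association_test(
    dars, pts, genome_sizes, n_perm = n_perm,
    statistic = "proximity_count", proximity_bp = proximity_bp,
    seed = seed)
  list(matched = matched, n_matched = sum(matched),
       fraction = mean(matched), perm = perm)
}
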