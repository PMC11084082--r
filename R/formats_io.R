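# All internal coordinates are 0-based half-open. BED is native; 1-based
# inputs (SNP tables) are converted exactly once, on read.

#' Construct a validated table of genomic intervals
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param name,score optional per-interval annotation columns.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (and `name`/`score` when given).
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              name = NULL, score = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integer-valued")
  if (any(nchar(chrom) == 0L)) stop("chrom names must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  bad <- which(start >= end)
  if (length(bad))
    stop("empty or inverted interval at row ", bad[1L],
         " (start >= end)")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    strand = rep_len(strand, length(chrom)),
                    stringsAsFactors = FALSE)
  if (!is.null(name)) out$name <- name
  if (!is.null(score)) out$score <- score
  out
}

#' Read a BED3/BED6 file
#'
#' Coordinates are taken as 0-based half-open (BED convention) and are not
#' shifted. Lines starting with `#` (and `track`/`browser` lines) are
#' skipped. Intervals are returned in file order.
#'
#' @param path path to a tab-separated BED file with >= 3 columns.
#' @return A `data.frame` as from [genomic_intervals()]; columns 4-6 are
#'   kept as `name`, `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 3L))
    stop("BED parse error at line ", lineno[which(n < 3L)[1L]],
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1L]],
         ": invalid coordinates")
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (all(n >= 4L)) out$name <- vapply(fields, `[`, "", 4L)
  if (all(n >= 5L))
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  if (all(n >= 6L)) {
    strand <- vapply(fields, `[`, "", 6L)
    if (!all(strand %in% c("+", "-", ".")))
      stop("BED parse error: invalid strand field")
    out$strand <- strand
  } else out$strand <- "."
  out
}

#' Write intervals as BED
#'
#' Writes BED3 plus `name`, `score`, `strand` columns when present
#' (missing middle columns are filled so the file stays rectangular).
#'
#' @param x interval `data.frame` (see [genomic_intervals()]).
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has_strand <- !is.null(x$strand) && any(x$strand != ".")
  if (!is.null(x$name) || !is.null(x$score) || has_strand)
    cols <- c(cols, list(if (is.null(x$name)) rep(".", nrow(x)) else x$name))
  if (!is.null(x$score) || has_strand)
    cols <- c(cols, list(if (is.null(x$score)) rep(0, nrow(x))
                         else format_coord(x$score)))
  if (has_strand) cols <- c(cols, list(x$strand))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) {
  format(x, scientific = FALSE, trim = TRUE)
}

#' Read a SNP table
#'
#' Expects a 4-column TSV (`chrom`, `pos` 1-based, `allele_a`, `allele_b`);
#' positions are converted to 0-based on read and records are sorted by
#' `(chrom, pos)`. `#` lines are comments. The two alleles must differ and
#' be in `{A,C,G,T}`.
#'
#' @param path path to the TSV.
#' @return A `data.frame` with class `snp_table`: columns `chrom`, `pos`
#'   (0-based), `allele_a`, `allele_b`.
#' @export
read_snp_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         comment.char = "#", stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "allele_a",
                                       "allele_b"))
  snp_table(x$chrom, x$pos - 1, x$allele_a, x$allele_b)
}

#' @rdname read_snp_table
#' @param chrom,pos,allele_a,allele_b vectors of SNP fields (`pos` 0-based).
#' @export
snp_table <- function(chrom, pos, allele_a, allele_b) {
  allele_a <- toupper(allele_a); allele_b <- toupper(allele_b)
  if (!all(c(allele_a, allele_b) %in% c("A", "C", "G", "T")))
    stop("SNP alleles must be A/C/G/T")
  if (any(allele_a == allele_b))
    stop("SNP with identical alleles at row ",
         which(allele_a == allele_b)[1L])
  if (any(pos < 0)) stop("SNP positions must be >= 0 after 1->0 conversion")
  x <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  allele_a = allele_a, allele_b = allele_b,
                  stringsAsFactors = FALSE)
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("snp_table", "data.frame")
  x
}

#' @param snps a `snp_table`.
#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  writeLines(c("#chrom\tpos\tallele_a\tallele_b",
               paste(snps$chrom, format_coord(snps$pos + 1), snps$allele_a,
                     snps$allele_b, sep = "\t")), path)
  invisible(path)
}

#' @param object a `snp_table`.
#' @param genome_length total genome length in bp used for the density;
#'   if `NULL` the span from 0 to the last SNP per chromosome is used.
#' @param ... unused.
#' @rdname read_snp_table
#' @export
summary.snp_table <- function(object, genome_length = NULL, ...) {
  if (is.null(genome_length)) {
    genome_length <- sum(tapply(object$pos, object$chrom, max) + 1)
  }
  list(n_snps = nrow(object),
       genome_length = genome_length,
       density_per_kb = 1000 * nrow(object) / genome_length)
}

#' Per-feature read-count container
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param intervals interval `data.frame` aligned with `feature_id`.
#' @param counts numeric matrix, features x samples, with column names.
#' @param library_sizes named numeric vector of totals, one per sample.
#' @return An object of class `count_table`.
#' @export
count_table <- function(feature_id, intervals, counts, library_sizes) {
  counts <- as.matrix(counts)
  if (anyDuplicated(feature_id)) stop("duplicate feature ids")
  if (nrow(counts) != length(feature_id))
    stop("counts rows must match feature ids")
  if (is.null(colnames(counts))) stop("counts must have sample names")
  if (any(is.na(counts))) stop("missing count cells are not allowed")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (!setequal(names(library_sizes), colnames(counts)))
    stop("library_sizes must name every sample")
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  structure(list(feature_id = as.character(feature_id),
                 intervals = intervals,
                 counts = counts,
                 library_sizes = library_sizes[colnames(counts)]),
            class = "count_table")
}

#' @param x a `count_table`.
#' @param ... unused.
#' @rdname count_table
#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$feature_id), "features x",
      ncol(x$counts), "samples\n")
  cat("samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a count table TSV
#'
#' The file holds one header row (`feature_id`, `chrom`, `start`, `end`,
#' then one column per sample), one row per feature, and a
#' `#library_sizes` comment line carrying the per-sample totals.
#'
#' @param path file path.
#' @return [read_count_table()] returns a `count_table`.
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lib_line <- grep("^#library_sizes\t", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 5L || header[1L] != "feature_id")
    stop("count table header must start with feature_id, chrom, start, end")
  samples <- header[-(1:4)]
  rows <- strsplit(body[-1L], "\t", fixed = TRUE)
  if (any(lengths(rows) != length(header)))
    stop("count table row with missing cells at line ",
         which(lengths(rows) != length(header))[1L] + 1L)
  m <- do.call(rbind, rows)
  counts <- matrix(as.numeric(m[, -(1:4), drop = FALSE]),
                   nrow = nrow(m),
                   dimnames = list(NULL, samples))
  if (!length(lib_line)) stop("count table lacks a #library_sizes line")
  libf <- strsplit(lib_line[1L], "\t", fixed = TRUE)[[1L]][-1L]
  lib <- as.numeric(sub("^[^=]*=", "", libf))
  names(lib) <- sub("=.*$", "", libf)
  count_table(m[, 1L],
              genomic_intervals(m[, 2L], as.numeric(m[, 3L]),
                                as.numeric(m[, 4L])),
              counts, lib)
}

#' @param x a `count_table`.
#' @rdname read_count_table
#' @export
write_count_table <- function(x, path) {
  lib <- paste0(names(x$library_sizes), "=",
                format_coord(x$library_sizes))
  header <- paste(c("feature_id", "chrom", "start", "end",
                    colnames(x$counts)), collapse = "\t")
  body <- paste(x$feature_id, x$intervals$chrom,
                format_coord(x$intervals$start),
                format_coord(x$intervals$end),
                apply(x$counts, 1L, function(r)
                  paste(format_coord(r), collapse = "\t")),
                sep = "\t")
  writeLines(c(paste(c("#library_sizes", lib), collapse = "\t"),
               header, body), path)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings that return plain named uppercase
#' character vectors (the representation downstream string operations
#' use). Duplicate sequence names are rejected.
#'
#' @param path file path.
#' @return [read_fasta()] returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate sequence name in FASTA: ", nm[anyDuplicated(nm)])
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  seqs
}

#' @param seqs named character vector of sequences.
#' @param width line-wrap width.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

# ---- interval utilities (sorted binary-search counting) ----

#' Count points (e.g. SNPs) falling in each interval
#'
#' Binary-search counting against per-chromosome sorted position vectors;
#' an interval `[start, end)` counts positions `start <= pos < end`.
#'
#' @param intervals interval `data.frame`.
#' @param chrom,pos point coordinates (0-based).
#' @return integer vector, one count per interval.
#' @export
count_points_in_intervals <- function(intervals, chrom, pos) {
  out <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    p <- sort(pos[chrom == ch])
    idx <- which(intervals$chrom == ch)
    if (!length(p)) next
    lo <- findInterval(intervals$start[idx] - 0.5, p)
    hi <- findInterval(intervals$end[idx] - 0.5, p)
    out[idx] <- hi - lo
  }
  out
}

#' Test each query interval for overlap with any target interval
#'
#' Overlap means sharing at least one base. Implemented per chromosome
#' with an event-sweep over sorted target boundaries.
#'
#' @param query,target interval `data.frame`s.
#' @return logical vector over query rows.
#' @export
overlaps_any <- function(query, target) {
  out <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ti <- which(target$chrom == ch)
    if (!length(ti)) next
    ts <- target$start[ti]; te <- target$end[ti]
    o <- order(ts); ts <- ts[o]; te <- cummax(te[o])
    # query q overlaps some target iff among targets with start < q.end,
    # the max end exceeds q.start
    k <- findInterval(query$end[qi] - 0.5, ts)
    out[qi] <- k > 0 & te[pmax(k, 1L)] > query$start[qi]
  }
  out
}

#' Count, for each query interval, how many targets it overlaps
#'
#' @inheritParams overlaps_any
#' @return integer vector over query rows.
#' @export
count_overlaps <- function(query, target) {
  out <- integer(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    ti <- which(target$chrom == ch)
    if (!length(ti)) next
    ts <- sort(target$start[ti]); te <- sort(target$end[ti])
    # targets overlapping [s,e): #(start < e) - #(end <= s)
    out[qi] <- findInterval(query$end[qi] - 0.5, ts) -
      findInterval(query$start[qi] + 0.5, te)
  }
  out
}
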