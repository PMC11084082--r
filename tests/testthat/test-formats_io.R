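test_that("BED parsing maps fields directly and rejects bad intervals", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment", "chr1\t0\t100\tpk0\t0\t.",
               "chr2\t50\t60\tpk1\t7\t-"), f)
  x <- read_bed(f)
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(0, 50))
  expect_equal(x$end, c(100, 60))
  expect_equal(x$strand, c(".", "-"))
  expect_equal(x$name, c("pk0", "pk1"))

  writeLines(c("chr1\t0\t10", "chr1\t100\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\tx\t10", f)
  expect_error(read_bed(f), "line 1")
})

test_that("BED round-trip is byte-identical on random intervals", {
  set.seed(5)
  x <- random_intervals(50)
  x$name <- sprintf("iv%02d", seq_len(50))
  x$score <- sample(0:1000, 50)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f1)
  write_bed(read_bed(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SNP table converts to 0-based, sorts, validates alleles", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t11\tA\tG", "chr1\t3\tC\tT"), f)
  s <- read_snp_table(f)
  expect_equal(s$pos, c(2, 10))
  expect_equal(s$allele_a[2], "A")

  writeLines("chr1\t11\tA\tA", f)
  expect_error(read_snp_table(f), "identical alleles")
  writeLines("chr1\t11\tA\tN", f)
  expect_error(read_snp_table(f), "A/C/G/T")
})

test_that("SNP summary reports the planted genome-wide density", {
  set.seed(2)
  pos <- sample.int(1e6, 6300) - 1
  s <- snp_table("chr1", pos, rep("A", 6300), rep("G", 6300))
  sm <- summary(s, genome_length = 1e6)
  expect_equal(sm$density_per_kb, 6.3)
})

test_that("count tables round-trip losslessly and validate inputs", {
  ct <- count_table(c("p1", "p2"),
                    genomic_intervals("chr1", c(0, 500), c(100, 900)),
                    matrix(c(3, 7, 0, 12), 2, 2,
                           dimnames = list(NULL, c("s1", "s2"))),
                    c(s1 = 100, s2 = 200))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  ct2 <- read_count_table(f)
  expect_equal(ct2$counts, ct$counts)
  expect_equal(ct2$library_sizes, ct$library_sizes)
  expect_equal(ct2$feature_id, ct$feature_id)

  expect_error(count_table("p1", genomic_intervals("chr1", 0, 10),
                           matrix(-1, 1, 1, dimnames = list(NULL, "s1")),
                           c(s1 = 10)), "negative")
  # a row with a missing cell is rejected
  lines <- readLines(f)
  lines[3] <- sub("\t[0-9]+$", "", lines[3])
  writeLines(lines, f)
  expect_error(read_count_table(f), "missing cells")
})

test_that("a peak-scale count table parses quickly", {
  n <- 16353
  ct <- count_table(sprintf("p%05d", seq_len(n)),
                    genomic_intervals("chr1", (seq_len(n) - 1) * 1000,
                                      (seq_len(n) - 1) * 1000 + 500),
                    matrix(rpois(4 * n, 50), n, 4,
                           dimnames = list(NULL, paste0("s", 1:4))),
                    stats::setNames(rep(1e6, 4), paste0("s", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  t0 <- Sys.time()
  ct2 <- read_count_table(f)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
  expect_equal(nrow(ct2$counts), n)
})

test_that("FASTA round-trips, uppercases, and rejects duplicates", {
  set.seed(3)
  seqs <- c(a = random_dna(150), b = tolower(random_dna(80)))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back, c(a = seqs[["a"]], b = toupper(seqs[["b"]])))
  expect_error(write_fasta(c(a = "ACGT", a = "ACGT"), f), "duplicate")

  # larger genome round-trips content-identically
  g <- c(chr1 = random_dna(2e5))
  write_fasta(g, f)
  expect_identical(read_fasta(f)[["chr1"]], g[["chr1"]])
})

test_that("binary-search interval counting matches the naive oracle", {
  set.seed(7)
  peaks <- random_intervals(100)
  pts_chrom <- sample(c("chr1", "chr2"), 5000, replace = TRUE)
  pts_pos <- floor(runif(5000, 0, 1e5))
  expect_equal(count_points_in_intervals(peaks, pts_chrom, pts_pos),
               naive_count_points(peaks, pts_chrom, pts_pos))

  target <- random_intervals(200)
  expect_equal(overlaps_any(peaks, target),
               naive_overlaps_any(peaks, target))
})
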