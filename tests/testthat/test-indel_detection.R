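test_that("an exact substring aligns as one full-length gapless segment", {
  set.seed(41)
  ref <- c(chr1 = random_dna(5000))
  read <- substr(ref, 1201, 1900)
  a <- align_read(read, ref)
  expect_equal(nrow(a$segments), 1)
  expect_equal(a$segments$read_start, 0)
  expect_equal(a$segments$read_end, 700)
  expect_equal(a$segments$ref_start, 1200)
  expect_equal(a$segments$ref_end, 1900)
  expect_equal(nrow(call_short_indels(a)), 0)
  expect_error(align_read("", ref), "empty")
  expect_error(align_read("ACGT", ref), "min_seed")
})

test_that("segment scores equal the local-alignment DP oracle on short windows", {
  set.seed(42)
  for (i in 1:5) {
    ref <- c(chr1 = random_dna(2000))
    start <- sample(100:800, 1)
    read <- substr(ref, start + 1, start + 700)
    if (i > 2) {  # sprinkle isolated substitutions
      v <- strsplit(read, "")[[1L]]
      pos <- sample(30:670, 4)
      v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      read <- paste(v, collapse = "")
    }
    a <- align_read(read, ref)
    expect_equal(nrow(a$segments), 1)
    expect_equal(a$segments$score, dp_local_score(read, ref))
  }
})

test_that("a reference-side skip is recovered with exact gap structure", {
  set.seed(43)
  ref <- c(chr1 = random_dna(3000))
  # read skips ref[350:550): 200 reference-only bases
  read <- paste0(substr(ref, 1, 350), substr(ref, 551, 900))
  a <- align_read(read, ref)
  expect_equal(nrow(a$segments), 2)
  calls <- call_short_indels(a, read = read)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$carrier, "A")
  expect_equal(calls$length, 200)
  expect_equal(calls$ref_start, 350)
  expect_equal(calls$ref_end, 550)

  # 1% substitutions away from the junction leave boundaries unchanged
  v <- strsplit(read, "")[[1L]]
  pos <- c(sample(20:300, 4), sample(420:680, 3))
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  a2 <- align_read(paste(v, collapse = ""), ref)
  calls2 <- call_short_indels(a2)
  expect_equal(calls2$ref_start, 350)
  expect_equal(calls2$ref_end, 550)
})

test_that("read-side insertions are called as carrier B with the sequence", {
  set.seed(44)
  ref <- c(chr1 = random_dna(3000))
  ins <- random_dna(150)
  # force the insert ends to differ from the reference bases flanking
  # the junction, so microhomology cannot shift the call boundaries
  flip <- function(b) c(A = "C", C = "A", G = "T", T = "G")[[b]]
  substr(ins, 1, 1) <- flip(substr(ref, 951, 951))
  substr(ins, 2, 2) <- flip(substr(ref, 952, 952))
  substr(ins, 149, 149) <- flip(substr(ref, 949, 949))
  substr(ins, 150, 150) <- flip(substr(ref, 950, 950))
  read <- paste0(substr(ref, 601, 950), ins, substr(ref, 951, 1300))
  a <- align_read(read, ref)
  calls <- call_short_indels(a, read = read)
  expect_equal(calls$carrier, "B")
  expect_equal(calls$length, 150)
  expect_equal(calls$inserted_seq, ins)
  expect_equal(calls$ref_start, 950)
})

test_that("the 300-bp boundary splits short and long calls strictly", {
  set.seed(45)
  ref <- c(chr1 = random_dna(4000))
  # exactly 300 skipped reference bases: not a short call, is a long call
  read <- paste0(substr(ref, 1, 350), substr(ref, 651, 1000))
  a <- align_read(read, ref)
  expect_equal(nrow(call_short_indels(a)), 0)
  long <- call_long_insertions(a)
  expect_equal(long$length, 300)
})

test_that("long insertions require same chromosome, orientation, adjacency", {
  set.seed(46)
  segs <- data.frame(chrom = "chr1", read_start = c(0, 350),
                     read_end = c(350, 700), diag = 0, n_seeds = 10,
                     ref_start = c(1000, 7750), ref_end = c(1350, 8100),
                     multi = FALSE, score = 350)
  a <- structure(list(read_id = "r", strand = "+", segments = segs),
                 class = "read_alignment")
  calls <- call_long_insertions(a)
  expect_equal(calls$length, 6400)
  expect_equal(calls$ref_start, 1350)
  expect_equal(calls$ref_end, 7750)
  # different chromosomes: no call
  segs2 <- segs; segs2$chrom <- c("chr1", "chr2")
  a2 <- a; a2$segments <- segs2
  expect_equal(nrow(call_long_insertions(a2)), 0)
  # read-coordinate gap beyond tolerance: no call
  segs3 <- segs; segs3$read_start[2] <- 450
  a3 <- a; a3$segments <- segs3
  expect_equal(nrow(call_long_insertions(a3)), 0)
})

test_that("opposite-strand split matches are never chained into a call", {
  set.seed(47)
  ref <- c(chr1 = random_dna(6000))
  # read = prefix from + strand then a distant reverse-complement block
  read <- paste0(substr(ref, 1, 350), rc(substr(ref, 4001, 4350)))
  a <- align_read(read, ref)
  expect_equal(nrow(call_long_insertions(a)), 0)
  expect_equal(nrow(call_short_indels(a)), 0)
})

test_that("merging collapses nearby per-read calls and annotates repeats", {
  calls <- data.frame(
    chrom = "chr1", ref_start = c(1350, 1352, 9000),
    ref_end = c(7750, 7752, 9200), length = c(6400, 6400, 200),
    carrier = "A", inserted_seq = NA_character_,
    read_id = c("r1", "r2", "r3"), stringsAsFactors = FALSE)
  reps <- data.frame(chrom = "chr1", start = c(1300, 8990),
                     end = c(7800, 9210), name = c("L1_syn", "SINE_syn"),
                     class = c("L1", "SINE"))
  m <- merge_and_annotate(calls, repeats = reps)
  expect_equal(nrow(m), 2)
  expect_equal(m$support, c(2, 1))
  expect_equal(m$element_class, c("L1", "SINE"))
})

test_that("3'-end containment is decided by alignment to the consensus tail", {
  set.seed(48)
  cons <- random_dna(6000)
  tail162 <- substr(cons, 6000 - 161, 6000)
  mid300 <- substr(cons, 3000, 3299)
  calls <- data.frame(
    chrom = "chr1", ref_start = c(100, 5000), ref_end = c(262, 5300),
    length = c(162, 300), carrier = "A",
    inserted_seq = c(tail162, mid300),
    read_id = c("r1", "r2"), stringsAsFactors = FALSE)
  m <- merge_and_annotate(calls, l1_consensus = cons)
  expect_equal(m$has_3prime_end, c(TRUE, FALSE))
  expect_equal(m$element_class, c("L1", "L1"))
  # reverse-complemented insertions are recognized too
  calls$inserted_seq <- c(rc(tail162), rc(mid300))
  m2 <- merge_and_annotate(calls, l1_consensus = cons)
  expect_equal(m2$has_3prime_end, c(TRUE, FALSE))
})

test_that("carrier-B calls are structurally bounded by the read length", {
  # a read-side gap of length >= max_len is never called: whole long
  # insertions in the non-reference strain cannot be determined
  segs <- data.frame(chrom = "chr1", read_start = c(0, 650),
                     read_end = c(100, 700), diag = 0, n_seeds = 5,
                     ref_start = c(0, 100), ref_end = c(100, 150),
                     multi = FALSE, score = 100)
  a <- structure(list(read_id = "r", strand = "+", segments = segs),
                 class = "read_alignment")
  calls <- rbind(call_short_indels(a), call_long_insertions(a))
  bad <- calls$carrier == "B" & calls$length > 700 - 2 * 50
  expect_false(any(bad))
})

test_that("DAR-insertion proximity matching is inclusive at the window", {
  dars <- genomic_intervals("chr1", c(8000, 8000), c(10000, 10000))
  calls <- data.frame(chrom = "chr1", ref_start = c(11999, 12001),
                      carrier = "A")
  gs <- c(chr1 = 1e6)
  out1 <- dar_indel_proximity(dars[1, ], calls[1, , drop = FALSE], gs,
                              n_perm = 9, seed = 1)
  out2 <- dar_indel_proximity(dars[2, ], calls[2, , drop = FALSE], gs,
                              n_perm = 9, seed = 1)
  expect_true(out1$matched)
  expect_false(out2$matched)
})
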