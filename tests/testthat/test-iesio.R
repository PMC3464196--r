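test_that("FASTA reading parses, uppercases and validates records", {
  p <- write_tmp_fasta(list(s1 = "acgt"))
  g <- read_genome(p)
  expect_s4_class(g, "DNAStringSet")
  expect_equal(names(g), "s1")
  expect_equal(as.character(g[[1]]), "ACGT")

  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_length(read_genome(empty), 0)

  bad <- write_tmp_fasta(list(s1 = "ACXT"))
  expect_error(read_genome(bad), "malformed|illegal")
  rna <- write_tmp_fasta(list(s1 = "ACGU"))
  expect_error(read_genome(rna), "malformed|illegal")
  dup <- write_tmp_fasta(list(s1 = "ACGT", s1 = "ACGT"))
  expect_error(read_genome(dup), "duplicated")
})

test_that("coordinate conversion is a shared involution", {
  set.seed(11)
  for (i in 1:50) {
    s0 <- sample(0:1000, 1)
    e0 <- s0 + sample(1:500, 1)
    g <- to_gff_coords(s0, e0)
    expect_equal(g$start, s0 + 1)
    expect_equal(g$end, e0)
    back <- from_gff_coords(g$start, g$end)
    expect_equal(back$start, s0)
    expect_equal(back$end, e0)
    # and the other direction
    z <- from_gff_coords(g$start, g$end)
    g2 <- to_gff_coords(z$start, z$end)
    expect_equal(g2, g)
  }
  expect_error(from_gff_coords(0, 5), "coordinates")
})

test_that("GFF3 gene reading converts coordinates and derives introns", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tx\tgene\t1\t9\t.\t+\t.\tID=g1",
    "s1\tx\texon\t1\t3\t.\t+\t.\tParent=g1",
    "s1\tx\texon\t7\t9\t.\t+\t.\tParent=g1"
  ), gff)
  genes <- read_gff3_genes(gff)
  ex <- genes[genes$kind == "exon", ]
  expect_equal(ex$start, c(0L, 6L))
  expect_equal(ex$end, c(3L, 9L))
  intr <- genes[genes$kind == "intron", ]
  expect_equal(nrow(intr), 1)
  expect_equal(c(intr$start, intr$end), c(3L, 6L))

  single <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tx\tgene\t1\t9\t.\t+\t.\tID=g1",
    "s1\tx\texon\t1\t9\t.\t+\t.\tParent=g1"
  ), single)
  expect_equal(sum(read_gff3_genes(single)$kind == "intron"), 0)

  outside <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "s1\tx\tgene\t5\t9\t.\t+\t.\tID=g1",
    "s1\tx\texon\t1\t9\t.\t+\t.\tParent=g1"
  ), outside)
  expect_error(read_gff3_genes(outside), "outside gene bounds")
})

test_that("IES GFF3 writing follows the retained-TA convention and round-trips", {
  genome <- Biostrings::DNAStringSet(c(s1 = "CCCTAGGGTACCC"))
  ies <- tibble::tibble(scaffold = "s1", pos = 3L, seq = "TAGGGG",
                        support = 2L)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_ies_gff3(ies, genome, path)
  lines <- grep("^[^#]", readLines(path), value = TRUE)
  f <- strsplit(lines[1], "\t")[[1]]
  expect_equal(f[1], "s1")
  expect_equal(f[3], "internal_eliminated_sequence")
  expect_equal(as.integer(f[4:5]), c(4L, 5L))   # 1-based span of the TA

  back <- read_ies_gff3(path)
  expect_equal(back$scaffold, "s1")
  expect_equal(back$pos, 3L)
  expect_equal(back$seq, "TAGGGG")
  expect_equal(back$length, 6L)
  expect_equal(back$support, 2L)

  # empty set -> header-only file, read back as empty catalogue
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_ies_gff3(ies[0, ], genome, p2)
  expect_true(all(startsWith(readLines(p2), "#")))
  expect_equal(nrow(read_ies_gff3(p2)), 0)

  # records violating the reconstruction identity are refused
  bad <- tibble::tibble(scaffold = "s1", pos = 0L, seq = "TAGG")
  expect_error(write_ies_gff3(bad, genome, path), "TA")
  notleft <- tibble::tibble(scaffold = "s1", pos = 7L, seq = "TACC")
  # slides left to pos 7? pos 7 is G; invalid anyway
  expect_error(write_ies_gff3(notleft, genome, path), "TA|canonical")
})

test_that("round trip preserves a multi-record catalogue bit-identically", {
  set.seed(5)
  ref <- paste0(random_seq(40), "TA", random_seq(40), "TA", random_seq(40))
  genome <- Biostrings::DNAStringSet(setNames(ref, "sc"))
  p1 <- 40L
  p2 <- 82L
  mk <- function(p, core) {
    canon <- canonicalize_insertion(ref, p, paste0("TA", core))
    tibble::tibble(scaffold = "sc", pos = canon$pos, seq = canon$seq,
                   support = 3L, context = "exon", gene_id = "g1",
                   flags = "shorter_than_26")
  }
  ies <- iescan:::normalize_ies(dplyr::bind_rows(mk(p1, "GGCCG"), mk(p2, "CCGGC")))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_ies_gff3(ies, genome, path)
  back <- read_ies_gff3(path)
  expect_equal(as.data.frame(back), as.data.frame(ies))
})

test_that("plain-text SAM subset parsing extracts spans and clips", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:s1\tLN:10000",
    "r1\t0\ts1\t101\t60\t108M\t*\t0\t0\t*\t*",
    "r2\t16\ts1\t201\t60\t78M30S\t*\t0\t0\t*\t*",
    "r3\t0\ts1\t301\t60\t30S78M\t*\t0\t0\t*\t*",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"
  ), sam)
  a <- read_sam(sam)
  expect_equal(nrow(a), 3)            # unmapped dropped
  expect_equal(a$start, c(100L, 200L, 300L))
  expect_equal(a$end, c(208L, 278L, 378L))
  expect_equal(a$clip_left, c(0L, 0L, 30L))
  expect_equal(a$clip_right, c(0L, 30L, 0L))
  expect_equal(a$strand, c("+", "-", "+"))

  # header optional
  sam2 <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\t0\ts1\t11\t60\t50M\t*\t0\t0\t*\t*", sam2)
  expect_equal(read_sam(sam2)$start, 10L)

  bad <- withr::local_tempfile(fileext = ".sam")
  writeLines("r1\t0\ts1", bad)
  expect_error(read_sam(bad), "fewer than 6")
})

test_that("SAM write/read round-trips the simulator's alignments", {
  ds <- small_dataset()
  sub <- head(ds$reads, 500)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(sub, ds$genome, path)
  back <- read_sam(path)
  expect_equal(back$start, sub$start)
  expect_equal(back$cigar, sub$cigar)
  expect_equal(back$clip_left, sub$clip_left)
  expect_equal(back$clip_right, sub$clip_right)
})

test_that("boundary adjustment canonicalizes and rejects correctly", {
  # unique decomposition
  genome <- Biostrings::DNAStringSet(c(s1 = "ACGTACGT"))
  rec <- adjust_ies_boundaries(genome, "s1", 3L, "TAGGGG")
  expect_equal(rec$pos, 3L)
  expect_equal(rec$seq, "TAGGGG")
  # sliding: insertion of ATAT at 3 in CCTAGG == TATA at 2
  canon <- canonicalize_insertion("CCTAGG", 3L, "ATAT")
  expect_equal(canon$pos, 2L)
  expect_equal(canon$seq, "TATA")
  # no TA-bounded placement
  genome2 <- Biostrings::DNAStringSet(c(s1 = "CCGGAA"))
  rej <- adjust_ies_boundaries(genome2, "s1", 4L, "TTTT")
  expect_s3_class(rej, "ies_rejection")
  expect_match(rej$reason, "TA")
})

test_that("canonicalization is idempotent and agrees with brute force", {
  set.seed(77)
  n_checked <- 0
  for (i in 1:300) {
    ref <- random_seq(sample(20:60, 1), gc = 0.3)
    len <- sample(4:20, 1)
    pos <- sample(0:(nchar(ref)), 1)
    seq <- random_seq(len, gc = 0.2)
    got <- canonicalize_insertion(ref, pos, seq)
    want <- brute_canonicalize(ref, pos, seq)
    expect_equal(got, want, info = paste(ref, pos, seq))
    if (!is.null(got)) {
      n_checked <- n_checked + 1
      again <- canonicalize_insertion(ref, got$pos, got$seq)
      expect_equal(again, got)
    }
  }
  expect_gt(n_checked, 20)  # the sweep exercised real TA-bounded cases
})
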