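test_that("contig G+C filter is strict and ignores N", {
  ctg <- Biostrings::DNAStringSet(c(a = "ATATAT", b = "GCGCGC", c = "ATGC",
                                    d = "ATTNGC"))
  kept <- filter_contigs(ctg)
  # gc = 0 kept; 1.0 and exactly 0.5 dropped (strict <); N excluded from the
  # denominator: ATTNGC is 2 GC over 5 informative bases = 0.4, kept
  expect_equal(names(kept), c("a", "d"))
  expect_warning(filter_contigs(Biostrings::DNAStringSet(c(z = ""))),
                 "zero-length")
})

test_that("anchor chaining maps exact substrings and exposes insertions", {
  set.seed(21)
  ref <- random_seq(5000)
  genome <- Biostrings::DNAStringSet(c(s1 = ref))
  idx <- kmer_index(genome, 21)

  # contig equal to a reference substring: one anchor, no gaps
  ctg <- substr(ref, 1001, 2000)
  ch <- anchor_align_contig(ctg, idx)
  expect_true(ch$mapped)
  expect_equal(ch$scaffold, "s1")
  expect_equal(nrow(ch$gaps), 0)
  expect_equal(ch$anchors$rstart[1], 1000L)

  # contig = ref with a 100 bp insertion: one gap, contig side ~100 bp
  ins <- random_seq(100, gc = 0.2)
  ctg2 <- paste0(substr(ref, 1001, 1500), ins, substr(ref, 1501, 2000))
  ch2 <- anchor_align_contig(ctg2, idx)
  expect_true(ch2$mapped)
  expect_equal(nrow(ch2$gaps), 1)
  gap <- ch2$gaps[1, ]
  contig_gap <- gap$contig_end - gap$contig_start
  ref_gap <- gap$ref_end - gap$ref_start
  expect_equal(contig_gap - ref_gap, 100L)

  # short random sequence: no unique anchors expected
  ch3 <- anchor_align_contig(random_seq(30), idx)
  expect_false(ch3$mapped)

  # a repeated region yields equally scoring chains and is skipped
  rep_ref <- paste0(random_seq(300), substr(ref, 1, 400), random_seq(300),
                    substr(ref, 1, 400), random_seq(300))
  genome_rep <- Biostrings::DNAStringSet(c(r1 = rep_ref))
  ch4 <- anchor_align_contig(substr(ref, 50, 350), genome_rep)
  expect_false(ch4$mapped)
})

test_that("gap realignment recovers a clean insertion block", {
  same <- realign_gap("ACGTACGTACGT", "ACGTACGTACGT")
  expect_equal(same$ins_seq, "")

  set.seed(8)
  flank_l <- random_seq(50)
  flank_r <- random_seq(50)
  ins <- "TAGGCCGGTA"
  res <- realign_gap(paste0(flank_l, flank_r),
                     paste0(flank_l, ins, flank_r))
  expect_equal(res$ins_seq, ins)
  expect_equal(res$ins_ref_offset, 50L)

  expect_error(realign_gap(strrep("A", 30000), "ACGT"), "guard")
})

test_that("contigs identical to the somatic genome yield no IESs", {
  ds <- small_dataset()
  mac_tiles <- Biostrings::DNAStringSet(
    substring(as.character(ds$genome[[1]]), c(1, 2001, 4001),
              c(3000, 5000, 7000)))
  names(mac_tiles) <- paste0("t", 1:3)
  expect_equal(nrow(call_ies(mac_tiles, ds$genome)), 0)
})

test_that("end-to-end on simulated contigs: exact boundaries, full catalogue", {
  ds <- small_dataset()
  ies <- call_ies(ds$contigs, ds$genome)
  tr <- ds$truth
  key_t <- paste(tr$scaffold, tr$pos, tr$seq)
  key_c <- paste(ies$scaffold, ies$pos, ies$seq)
  expect_gte(mean(key_t %in% key_c), 0.95)   # recall, boundaries exact
  expect_gte(mean(key_c %in% key_t), 0.99)   # precision
  # reconstruction identity holds for every call
  expect_silent(validate_ies(ies, ds$genome))
  # records < 26 bp carry the flag
  short <- ies$length < 26
  expect_true(all(ies$flags[short] == "shorter_than_26"))
  # overlapping tiles produce the same call twice: support accumulates
  expect_gte(max(ies$support), 2)
})

test_that("duplicate calls merge with summed support", {
  set.seed(31)
  ref <- paste0(random_seq(200), "TA", random_seq(200))
  genome <- Biostrings::DNAStringSet(c(s1 = ref))
  canon <- canonicalize_insertion(ref, 200L, paste0("TA", random_seq(40, gc = 0.2)))
  germ <- paste0(substr(ref, 1, canon$pos), canon$seq,
                 substr(ref, canon$pos + 1, nchar(ref)))
  ctgs <- Biostrings::DNAStringSet(c(c1 = germ, c2 = germ))
  ies <- call_ies(ctgs, genome)
  expect_equal(nrow(ies), 1)
  expect_equal(ies$support, 2L)
  expect_equal(ies$pos, canon$pos)
  expect_equal(ies$seq, canon$seq)
})

test_that("TA-indels classify into exact, internal and external alternatives", {
  # somatic scaffold: L + TA + M + TA + R with the catalogued IES at |L|;
  # flanks chosen so no placement can slide.
  l_flank <- "CCGGCCGGCCGGCCGGCCGG"
  m_mid <- "GGCGGCGGC"
  r_flank <- "GGCCGGCCGGCCGGCCGGCC"
  ref <- paste0(l_flank, "TA", m_mid, "TA", r_flank)
  p <- nchar(l_flank)
  genome <- Biostrings::DNAStringSet(c(s1 = ref))
  # IES with an internal TA: TA-x-TA-y
  x <- "GGCCG"
  y <- "CCGGTTCCG"
  ies <- iescan:::normalize_ies(tibble::tibble(
    scaffold = "s1", pos = p, seq = paste0("TA", x, "TA", y)))

  indels <- tibble::tibble(
    scaffold = "s1",
    pos = c(p, p, p, p, 5L),
    seq = c(paste0("TA", x, "TA", y),       # identical to the IES
            paste0("TA", x),                # left sub-segment, internal TA
            paste0("TA", y),                # right sub-segment
            paste0("TA", m_mid),            # shares the IES boundary TA,
                                            # other end at the somatic TA
            "GGGG"),                        # unrelated, not TA-bounded
    kind = c("residual", "residual", "residual", "low_frequency",
             "low_frequency"))
  got <- classify_ta_indels(indels, ies, genome)
  expect_equal(got$boundary_class,
               c("exact_ies", "internal_alternative", "internal_alternative",
                 "external_alternative", "unrelated"))

  # residual indel that is not TA-bounded warns
  expect_warning(
    classify_ta_indels(tibble::tibble(scaffold = "s1", pos = 5L,
                                      seq = "GGGG", kind = "residual"),
                       ies, genome),
    "not TA-bounded")
})
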