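test_that("context classification follows the half-open convention", {
  genes <- tibble::tibble(
    gene_id = "g1", scaffold = "s1",
    start = c(100L, 200L, 230L), end = c(200L, 230L, 300L),
    kind = c("exon", "intron", "exon"), strand = "+",
    phase = NA_integer_)
  ies <- iescan:::normalize_ies(tibble::tibble(
    scaffold = "s1", pos = c(150L, 50L, 200L, 199L, 230L),
    seq = "TAGG"))
  got <- classify_context(ies, genes)
  got <- got[order(match(got$pos, c(150L, 50L, 200L, 199L, 230L))), ]
  expect_equal(got$context[got$pos == 150], "exon")
  expect_equal(got$context[got$pos == 50], "intergenic")
  # boundary: pos == exon end belongs to the following interval
  expect_equal(got$context[got$pos == 200], "intron")
  expect_equal(got$context[got$pos == 199], "exon")
  expect_equal(got$context[got$pos == 230], "exon")
  expect_equal(unique(got$gene_id[got$context != "intergenic"]), "g1")
})

test_that("composition pools G+C across the catalogue", {
  one <- iescan:::normalize_ies(tibble::tibble(scaffold = "s", pos = 0L,
                                               seq = "TATA"))
  expect_equal(ies_composition(one)$gc, 0, ignore_attr = TRUE)
  two <- iescan:::normalize_ies(tibble::tibble(scaffold = "s", pos = 0L,
                                               seq = "TAGC"))
  expect_equal(ies_composition(two)$gc, 0.5, ignore_attr = TRUE)
  expect_error(ies_composition(one[0, ]), "empty")
})

test_that("the generator's IES G+C parameter is recovered from the catalogue", {
  ds <- small_dataset()
  comp <- ies_composition(ds$truth)
  expect_lt(abs(comp$gc - 0.20), 0.02)
})

test_that("periodicity estimation recovers planted spacings", {
  draw <- function(spacing, n = 20000, seed = 5) {
    cfg <- sim_config(seed = seed, spacing = spacing)
    set.seed(seed)
    sample_ies_lengths(n, cfg)
  }
  fit <- size_periodicity(size_histogram(draw(10.2)))
  expect_lt(abs(fit$period - 10.2), 0.2)
  expect_gte(fit$n_peaks, 3)
  # the depleted second peak does not bias the slope
  expect_lt(fit$second_peak_ratio, 0.3)
  expect_gt(fit$first_peak_fraction, 0.2)

  fit12 <- size_periodicity(size_histogram(draw(12)))
  expect_lt(abs(fit12$period - 12), 0.2)

  # uniform lengths carry no periodic structure
  set.seed(6)
  expect_error(size_periodicity(size_histogram(sample(26:150, 5000,
                                                      replace = TRUE))),
               "insufficient periodic structure")
})

test_that("logo information content matches the closed form", {
  # all-T column against a 28% G+C background
  expect_equal(column_ic(c(A = 0, C = 0, G = 0, T = 1), gc = 0.28),
               log2(1 / 0.36), tolerance = 1e-12)
  # background frequencies carry zero information
  expect_equal(column_ic(c(A = 0.36, C = 0.14, G = 0.14, T = 0.36),
                         gc = 0.28), 0, tolerance = 1e-12)
  # A/T equal mix
  expect_equal(column_ic(c(A = 0.5, C = 0, G = 0, T = 0.5), gc = 0.28),
               log2(0.5 / 0.36), tolerance = 1e-12)
})

test_that("end logos are TA-led, order-invariant and exclude short records", {
  ds <- small_dataset()
  logo <- end_logo(ds$truth)
  expect_equal(unname(logo$freq["T", 1]), 1)
  expect_equal(unname(logo$freq["A", 2]), 1)
  expect_true(all(logo$ic >= 0))
  expect_gt(logo$ic[1], 1)    # constitutive T against a 0.36 background
  shuffled <- ds$truth[sample(nrow(ds$truth)), ]
  logo2 <- end_logo(shuffled)
  expect_equal(logo2$freq, logo$freq)

  shorty <- iescan:::normalize_ies(tibble::tibble(
    scaffold = "s", pos = c(0L, 4L), seq = c("TACG", "TAGGCCGGAA")))
  expect_warning(l2 <- end_logo(shorty), "excluded")
  expect_equal(l2$n_ends, 2)  # only the long record contributes both ends
})

test_that("in-frame stop classification honours the genetic code and phase", {
  # in-frame TGA, phase 0
  expect_equal(classify_stop_in_frame("TGACCC", 0), "stop_containing")
  # the same sequence read at phase 1 has no in-frame TGA
  expect_equal(classify_stop_in_frame("TGACCC", 1, flank_up = "C",
                                      flank_down = "GG"), "stopless")
  # TAA in frame: glutamine under the ciliate code, stop under the standard
  expect_equal(classify_stop_in_frame("TAAGGG", 0, code = "ciliate"),
               "stopless")
  expect_equal(classify_stop_in_frame("TAAGGG", 0, code = "standard"),
               "stop_containing")
  # 27 bp IES, phase 0, no in-frame TGA
  s27 <- strrep("TAT", 9)
  expect_equal(classify_stop_in_frame(s27, 0), "stopless")
  # phase 2 junction codon built from two upstream flank bases
  expect_equal(classify_stop_in_frame("ATGACCCCC", 2, flank_up = "GT",
                                      flank_down = "G"), "stop_containing")
  # junction codon completed from the downstream flank
  expect_equal(classify_stop_in_frame("TATTG", 0, flank_down = "AA"),
               "stop_containing")
  expect_equal(classify_stop_in_frame("TATTG", 0, flank_down = "CA"),
               "stopless")
  # missing upstream flank: the junction codon is skipped, not guessed
  expect_equal(classify_stop_in_frame("TGACCC", 1), "stopless")
})

test_that("3n bias chi-squared equals the two-cell closed form and is symmetric", {
  null <- c(3481, 6823)
  r <- chi2_3n_bias(c(7095, 16244), null)
  # independent closed form: 2-cell goodness of fit
  n <- 7095 + 16244
  e1 <- n * null[1] / sum(null)
  e2 <- n * null[2] / sum(null)
  expect_equal(r$chi2, (7095 - e1)^2 / e1 + (16244 - e2)^2 / e2,
               tolerance = 1e-12)
  expect_equal(r$df, 1L)
  expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))
  # swapping both cells' labels leaves the statistic unchanged
  r_swap <- chi2_3n_bias(c(16244, 7095), rev(null))
  expect_equal(r_swap$chi2, r$chi2, tolerance = 1e-12)
  # observed proportions equal to the null give exactly zero
  r0 <- chi2_3n_bias(c(3481 * 2, 6823 * 2), null)
  expect_equal(r0$chi2, 0, tolerance = 1e-12)
  expect_error(chi2_3n_bias(c(0, 0), null), "no observations")
})

test_that("density-vs-expression bins genes and fits the trend", {
  flat <- tibble::tibble(gene_id = paste0("g", 1:60), cds_kb = 1,
                         n_ies = 2, expression = seq_len(60))
  fit <- density_by_expression(flat, n_bins = 30)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(nrow(fit$bins), 30)

  two <- tibble::tibble(gene_id = paste0("g", 1:4), cds_kb = 1,
                        n_ies = c(1, 1, 0.5, 0.5), expression = c(1, 2, 3, 4))
  fit2 <- density_by_expression(two, n_bins = 2)
  expect_equal(fit2$slope, -0.5, tolerance = 1e-12)

  expect_error(density_by_expression(flat[1:10, ], n_bins = 30),
               "smaller n_bins")

  # density inversely proportional to expression gives a negative slope
  set.seed(2)
  inv <- tibble::tibble(gene_id = paste0("g", 1:300), cds_kb = 1,
                        expression = exp(runif(300, 0, 4)))
  inv$n_ies <- rpois(300, 2 / (1 + rank(inv$expression) / 100))
  fit3 <- density_by_expression(inv, n_bins = 30)
  expect_lt(fit3$slope, 0)
  expect_equal(glance(fit3)$slope, fit3$slope)
})

test_that("positional uniformity verdicts follow the KS test", {
  grid <- seq(500, 99500, by = 1000)
  u <- positional_uniformity(grid, 100000)
  expect_equal(u$verdict, "uniform")

  clustered <- seq(1, 10000, length.out = 100)
  nu <- positional_uniformity(clustered, 100000)
  expect_equal(nu$verdict, "non_uniform")
  expect_lt(nu$p, 0.002)

  few <- positional_uniformity(c(1, 2, 3), 1000)
  expect_equal(few$verdict, "inconclusive")
})
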