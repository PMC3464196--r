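#' Classify the genomic context of each IES
#'
#' The insertion point `pos` (the first base of the retained TA) is located
#' in the gene model: inside an exon interval, an intron interval, or in
#' neither (intergenic). Intervals are 0-based half-open, so a point equal
#' to an interval end belongs to the following interval.
#'
#' @param ies An IES catalogue tibble.
#' @param genes A gene-interval tibble from [read_gff3_genes()].
#' @return `ies` with `context` and `gene_id` filled in.
#' @export
classify_context <- function(ies, genes) {
  if (nrow(ies) == 0) return(ies)
  ies$context <- "intergenic"
  ies$gene_id <- NA_character_
  feats <- genes[genes$kind %in% c("exon", "intron"), ]
  if (nrow(feats) == 0) return(ies)
  fr <- GenomicRanges::GRanges(feats$scaffold,
                               IRanges::IRanges(feats$start + 1L, feats$end))
  pr <- GenomicRanges::GRanges(ies$scaffold,
                               IRanges::IRanges(ies$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pr, fr, select = "first")
  hit <- !is.na(hits)
  ies$context[hit] <- feats$kind[hits[hit]]
  ies$gene_id[hit] <- feats$gene_id[hits[hit]]
  ies
}

#' Composition and length summary of an IES catalogue
#'
#' @param ies An IES catalogue tibble (non-empty).
#' @return A one-row tibble: pooled `gc` over all IES sequences (Ns excluded
#'   from the denominator), `mean_length`, `median_length`,
#'   `frac_below_150`, `n`.
#' @export
ies_composition <- function(ies) {
  if (nrow(ies) == 0) abort("empty IES set")
  seqs <- Biostrings::DNAStringSet(ies$seq)
  freq <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T"))
  tot <- colSums(freq)
  tibble(
    gc = (tot["G"] + tot["C"]) / sum(tot),
    mean_length = mean(ies$length),
    median_length = stats::median(ies$length),
    frac_below_150 = mean(ies$length < 150),
    n = nrow(ies)
  )
}

#' Integer size histogram of an IES catalogue
#'
#' @param ies An IES catalogue tibble, or an integer vector of lengths.
#' @param min_len,max_len Histogram range (defaults 26-150, the range in
#'   which the periodic structure lives).
#' @return An `ies_size_histogram`: tibble `length`, `count`, with
#'   attributes `n` (in-range total) and `n_all`.
#' @export
size_histogram <- function(ies, min_len = 26, max_len = 150) {
  lens <- if (is.data.frame(ies)) ies$length else as.integer(ies)
  rng <- min_len:max_len
  counts <- tabulate(factor(lens[lens >= min_len & lens <= max_len],
                            levels = rng), nbins = length(rng))
  structure(tibble(length = rng, count = counts),
            n = sum(counts), n_all = length(lens),
            class = c("ies_size_histogram", "tbl_df", "tbl", "data.frame"))
}

#' Estimate the period of the IES size distribution
#'
#' Counts are smoothed with a discrete Gaussian kernel (`sigma` bp), local
#' maxima exceeding a prominence threshold are taken as peaks, peak indices
#' are inferred from the median inter-peak spacing (so a depleted peak does
#' not bias the fit), and the period is the least-squares slope of peak
#' position on peak index. Also reports the mass fraction in the first peak
#' and the depleted-second-peak ratio (mass at 36-40 bp relative to the mean
#' of the flanking windows 26-30 and 46-50 bp).
#'
#' @param hist An [size_histogram()] object.
#' @param sigma Gaussian smoothing bandwidth, bp. Default 1.5.
#' @param min_prominence Minimum peak prominence as a fraction of the highest
#'   smoothed count. Default 0.05.
#' @param rel_prominence Minimum prominence as a fraction of the peak's own
#'   height; scale-free, so sampling noise on a flat distribution never
#'   qualifies while genuinely periodic peaks of any amplitude do.
#'   Default 0.3.
#' @return An `ies_periodicity` object: `period`, `peaks`, `peak_index`,
#'   `residual` (RMS of the regression), `n_peaks`,
#'   `first_peak_fraction`, `second_peak_ratio`.
#' @export
size_periodicity <- function(hist, sigma = 1.5, min_prominence = 0.05,
                             rel_prominence = 0.3) {
  x <- hist$length
  y <- as.numeric(hist$count)
  half <- ceiling(4 * sigma)
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  ypad <- c(rep(0, half), y, rep(0, half))
  smooth <- vapply(seq_along(y), function(i) {
    sum(ypad[i:(i + 2 * half)] * kern)
  }, numeric(1))

  n <- length(smooth)
  is_max <- c(FALSE, smooth[2:(n - 1)] > smooth[1:(n - 2)] &
                smooth[2:(n - 1)] >= smooth[3:n], FALSE)
  # first bin can be a peak (abrupt minimum-size cutoff)
  if (n >= 2 && smooth[1] > smooth[2]) is_max[1] <- TRUE
  cand <- which(is_max)
  # prominence: height minus the higher of the two nearby flanking valleys
  prom <- vapply(cand, function(i) {
    valleys <- c(if (i > 1) min(smooth[max(1, i - 15):(i - 1)]) else 0,
                 if (i < n) min(smooth[(i + 1):min(n, i + 15)]) else 0)
    smooth[i] - max(valleys)
  }, numeric(1))
  keep <- prom >= min_prominence * max(smooth) &
    prom >= rel_prominence * smooth[cand]
  peaks <- x[cand[keep]]
  if (length(peaks) < 3) abort("insufficient periodic structure (< 3 peaks)")

  t0 <- stats::median(diff(peaks))
  idx <- round((peaks - peaks[1]) / t0)
  fit <- lm(peaks ~ idx)
  period <- unname(coef(fit)[2])

  mass <- function(a, b) sum(y[x >= a & x <= b])
  first_frac <- mass(min(x), peaks[1] + floor(period / 2)) / max(sum(y), 1)
  second_ratio <- mass(36, 40) /
    max(mean(c(mass(26, 30), mass(46, 50))), 1e-9)

  structure(list(period = period, peaks = peaks, peak_index = idx,
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 n_peaks = length(peaks), first_peak_fraction = first_frac,
                 second_peak_ratio = second_ratio),
            class = "ies_periodicity")
}

#' @export
print.ies_periodicity <- function(x, ...) {
  cat(sprintf("IES size periodicity: %.2f bp (%d peaks, residual %.2f bp)\n",
              x$period, x$n_peaks, x$residual))
  cat(sprintf("first-peak mass %.1f%%, depleted-second-peak ratio %.2f\n",
              100 * x$first_peak_fraction, x$second_peak_ratio))
  invisible(x)
}

#' Information content of one logo column
#'
#' Background-corrected (Kullback-Leibler) information,
#' `sum_b f(b) log2(f(b) / q(b))` bits, with `q(G)=q(C)=gc/2` and
#' `q(A)=q(T)=(1-gc)/2`.
#'
#' @param f Named frequency vector over `A,C,G,T` (sums to 1).
#' @param gc Background G+C content. Default 0.28.
#' @return Information content in bits (non-negative).
#' @export
column_ic <- function(f, gc = 0.28) {
  q <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  f <- f[names(q)]
  nz <- f > 0
  sum(f[nz] * log2(f[nz] / q[names(f)[nz]]))
}

#' End-consensus logo of an IES catalogue
#'
#' Works on the full germline element (the reported sequence plus the
#' retained right-boundary TA), pooling the left end with the
#' reverse-complemented right end, so positions 1-2 are constitutively T,A.
#' Information content is corrected for the genomic background G+C.
#'
#' @param ies An IES catalogue tibble.
#' @param n_positions Number of terminal positions. Default 8.
#' @param gc Background G+C content. Default 0.28 (somatic genome).
#' @return An `ies_logo` object: `freq` (4 x n matrix), `ic` (bits per
#'   position), `gc`, `n_ends`, `n_excluded`.
#' @export
end_logo <- function(ies, n_positions = 8, gc = 0.28) {
  elements <- paste0(ies$seq, "TA")
  keep <- nchar(elements) >= n_positions
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    warn(paste0(n_excl, " sequence(s) shorter than ", n_positions,
                " positions excluded from the logo"))
  }
  elements <- elements[keep]
  if (length(elements) == 0) abort("no sequences long enough for the logo")
  left <- substr(elements, 1, n_positions)
  right_full <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(elements)))
  right <- substr(right_full, 1, n_positions)
  ends <- c(left, right)
  mat <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(ends),
                                     baseOnly = TRUE)
  freq <- prop.table(mat[c("A", "C", "G", "T"), , drop = FALSE], margin = 2)
  ic <- apply(freq, 2, column_ic, gc = gc)
  structure(list(freq = freq, ic = ic, gc = gc, n_ends = length(ends),
                 n_excluded = n_excl),
            class = "ies_logo")
}

#' @export
print.ies_logo <- function(x, ...) {
  cat(sprintf("IES end consensus over %d positions (%d ends, gc=%.2f)\n",
              ncol(x$freq), x$n_ends, x$gc))
  cat("IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  cons <- rownames(x$freq)[apply(x$freq, 2, which.max)]
  cat("majority consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' Does a retained IES introduce an in-frame stop codon?
#'
#' `phase` is the offset of the insertion point within the current codon of
#' the surrounding ORF (0, 1 or 2). Junction codons straddling the IES
#' boundaries are completed from the supplied flanking bases and included in
#' the scan. Under the ciliate nuclear code (translation table 6) TAA/TAG
#' encode glutamine, so TGA is the only stop; the standard code counts
#' TAA/TAG/TGA.
#'
#' @param ies_seq IES sequence (character scalar).
#' @param phase Codon offset of the insertion point, 0-2.
#' @param flank_up,flank_down Up to 2 coding bases on each side of the
#'   insertion point (in transcript orientation) used to complete junction
#'   codons; missing flanks cause the junction codons to be skipped.
#' @param code `"ciliate"` (default) or `"standard"`.
#' @return `"stop_containing"` or `"stopless"`.
#' @export
classify_stop_in_frame <- function(ies_seq, phase, flank_up = "",
                                   flank_down = "",
                                   code = c("ciliate", "standard")) {
  code <- match.arg(code)
  stopifnot(phase %in% 0:2)
  stops <- if (code == "ciliate") "TGA" else c("TAA", "TAG", "TGA")
  up_needed <- phase
  up <- if (nchar(flank_up) >= up_needed && up_needed > 0) {
    substr(flank_up, nchar(flank_up) - up_needed + 1, nchar(flank_up))
  } else ""
  if (nchar(up) < up_needed) {
    # junction codon cannot be completed; start the scan at the first codon
    # fully determined by IES bases
    ies_seq <- substr(ies_seq, 3 - phase + 1, nchar(ies_seq))
    up <- ""
  }
  s <- paste0(up, ies_seq)
  down_needed <- (3 - nchar(s) %% 3) %% 3
  down <- if (down_needed > 0 && nchar(flank_down) >= down_needed) {
    substr(flank_down, 1, down_needed)
  } else ""
  if (down_needed > 0 && nchar(down) < down_needed) {
    s <- substr(s, 1, nchar(s) - nchar(s) %% 3)  # drop incomplete last codon
  } else {
    s <- paste0(s, down)
  }
  if (nchar(s) < 3) return("stopless")
  starts <- seq(1, nchar(s) - 2, by = 3)
  codons <- substring(s, starts, starts + 2)
  if (any(codons %in% stops)) "stop_containing" else "stopless"
}

#' Chi-squared test for the deficit of 3n-length IESs
#'
#' Two-cell goodness-of-fit test: the observed (3n, non-3n) counts for a
#' category of IESs in coding sequence are compared with the proportions
#' observed for IESs in non-coding sequence (the null), df = 1, no
#' continuity correction, upper-tail p.
#'
#' @param observed Length-2 vector `(n_3n, n_non3n)` for the category.
#' @param null Length-2 vector `(n_3n, n_non3n)` for the non-coding null.
#' @param category Optional label.
#' @return A one-row tibble: `category`, `n`, `n_3n`, `n_non3n`, `e_3n`,
#'   `e_non3n`, `chi2`, `df`, `p`.
#' @export
chi2_3n_bias <- function(observed, null, category = NA_character_) {
  stopifnot(length(observed) == 2, length(null) == 2,
            all(observed >= 0), all(null >= 0), sum(null) > 0)
  n <- sum(observed)
  if (n == 0) abort("no observations in category")
  e <- n * null / sum(null)
  chi2 <- sum((observed - e)^2 / e)
  tibble(category = category, n = n,
         n_3n = observed[1], n_non3n = observed[2],
         e_3n = e[1], e_non3n = e[2],
         chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' IES density as a function of gene expression
#'
#' Genes are placed in equal-count expression bins; the density of a bin is
#' total IES count over total coding length. An ordinary least-squares fit of
#' density on bin rank (0-based) summarizes the trend.
#'
#' @param gene_table A tibble: `gene_id`, `cds_kb`, `n_ies`, `expression`.
#' @param n_bins Number of expression bins. Default 30.
#' @return An `ies_density_fit`: `bins` (tibble `bin`, `rank`, `n_genes`,
#'   `density`), `slope`, `intercept`, `r_squared`, `fit` (the `lm`).
#' @export
density_by_expression <- function(gene_table, n_bins = 30) {
  if (length(unique(gene_table$expression)) < n_bins) {
    abort(paste0("fewer than ", n_bins, " distinct expression values; ",
                 "use a smaller n_bins"))
  }
  bins <- gene_table %>%
    mutate(bin = ntile(.data$expression, n_bins)) %>%
    group_by(.data$bin) %>%
    summarise(n_genes = n(),
              density = sum(.data$n_ies) / sum(.data$cds_kb),
              .groups = "drop") %>%
    mutate(rank = .data$bin - 1L)
  fit <- lm(density ~ rank, data = bins)
  structure(list(bins = bins, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "ies_density_fit")
}

#' @export
print.ies_density_fit <- function(x, ...) {
  cat(sprintf("IES density vs expression: slope %.4f per bin over %d bins\n",
              x$slope, nrow(x$bins)))
  invisible(x)
}

#' Kolmogorov-Smirnov test of positional uniformity along a scaffold
#'
#' One-sample KS test of IES insertion points against Uniform(0, L), with the
#' asymptotic p-value (integer positions produce ties; the asymptotic
#' approximation is used deliberately). Fewer than 10 positions yields an
#' inconclusive verdict.
#'
#' @param positions Numeric vector of 0-based insertion points.
#' @param scaffold_length Scaffold length L, bp.
#' @param alpha Rejection level. Default 0.002.
#' @return A one-row tibble: `verdict` (`uniform`, `non_uniform`,
#'   `inconclusive`), `statistic`, `p`, `n`, `alpha`.
#' @export
positional_uniformity <- function(positions, scaffold_length, alpha = 0.002) {
  n <- length(positions)
  if (n < 10) {
    return(tibble(verdict = "inconclusive", statistic = NA_real_,
                  p = NA_real_, n = n, alpha = alpha))
  }
  kt <- suppressWarnings(
    ks.test(positions, "punif", min = 0, max = scaffold_length,
            exact = FALSE))
  tibble(verdict = ifelse(kt$p.value < alpha, "non_uniform", "uniform"),
         statistic = unname(kt$statistic), p = kt$p.value, n = n,
         alpha = alpha)
}
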