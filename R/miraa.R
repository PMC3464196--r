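#' MIRAA parameters
#'
#' Thresholds for breakpoint-site detection from read alignments. The
#' defaults follow the published rule: a site needs more than 15 alignment
#' ends (10% of the average read coverage of the original data), must lie
#' more than 500 bp from both scaffold ends, and must have local read
#' coverage below 300x (to avoid highly repeated sequence).
#'
#' @param min_end_count Minimum number of clipped alignment ends (strictly
#'   greater than this value is required). Default 15.
#' @param end_margin Exclusion zone at each scaffold end, bp. Default 500.
#' @param max_coverage Maximum local read depth (strictly less). Default 300.
#' @param min_end_fraction Optional; when set, `min_end_count` is recomputed
#'   as this fraction of the observed mean coverage (default 0.10 when used).
#' @param merge_tol Adjacent candidate positions within this distance are
#'   merged to the position with the most ends (staggered cleavage blurs the
#'   breakpoint by a couple of bases). Default 2.
#' @param cov_window Width (bp) of the window whose median depth is the
#'   site's local coverage. Both germline flanks of an insertion map onto
#'   the junction base, doubling the depth exactly there; the repeat guard
#'   is about the neighbourhood, so a windowed median is used. Default 51.
#' @return A list of class `miraa_params`.
#' @export
miraa_params <- function(min_end_count = 15, end_margin = 500,
                         max_coverage = 300, min_end_fraction = NULL,
                         merge_tol = 2, cov_window = 51) {
  stopifnot(min_end_count > 0, end_margin > 0, max_coverage > 0,
            is.null(min_end_fraction) || min_end_fraction > 0, merge_tol >= 0,
            cov_window >= 1)
  structure(list(min_end_count = min_end_count, end_margin = end_margin,
                 max_coverage = max_coverage,
                 min_end_fraction = min_end_fraction, merge_tol = merge_tol,
                 cov_window = cov_window),
            class = "miraa_params")
}

# Per-position counts of clipped alignment terminations on one scaffold.
# A left-soft-clipped alignment contributes its first aligned base; a
# right-soft-clipped alignment contributes its last aligned base (the
# alignment "stops on the residual TA"). Returns integer vector length L.
clip_end_counts <- function(starts, ends, clip_left, clip_right, L) {
  at <- c(starts[clip_left > 0], ends[clip_right > 0] - 1L)
  at <- at[at >= 0 & at < L]
  tabulate(at + 1L, nbins = L)
}

# Per-position read depth (aligned spans) on one scaffold, via a difference
# array.
coverage_counts <- function(starts, ends, L) {
  d <- integer(L + 1L)
  s <- pmax(starts, 0L) + 1L
  e <- pmin(ends, L) + 1L
  keep <- s <= L & e > s - 1L
  ds <- tabulate(s[keep], nbins = L + 1L)
  de <- tabulate(e[keep], nbins = L + 1L)
  cumsum(ds - de)[seq_len(L)]
}

#' Detect candidate IES insertion sites from alignment-end pileups (MIRAA)
#'
#' Reads that span a germline IES junction align only partially against the
#' somatic reference, so their alignments terminate (with a soft-clip) at the
#' junction. A site is emitted where the number of clipped alignment
#' terminations exceeds `min_end_count`, the position is more than
#' `end_margin` from both scaffold ends, and local coverage is below
#' `max_coverage`. Neighbouring candidates within `merge_tol` bp are merged
#' to the position with the most ends (end counts summed).
#'
#' @param alignments Alignment tibble as returned by [read_sam()].
#' @param genome A [Biostrings::DNAStringSet] (the somatic reference).
#' @param params A [miraa_params()] object.
#' @return A tibble of sites: `scaffold`, `pos` (0-based), `end_count`,
#'   `coverage`, `has_ta`, sorted by scaffold and position.
#' @export
detect_breakpoint_sites <- function(alignments, genome, params = miraa_params()) {
  stopifnot(inherits(params, "miraa_params"))
  min_ends <- params$min_end_count
  if (!is.null(params$min_end_fraction)) {
    gl <- sum(as.numeric(Biostrings::width(genome)))
    mean_cov <- sum(as.numeric(alignments$end - alignments$start)) / gl
    min_ends <- params$min_end_fraction * mean_cov
  }
  out <- list()
  for (sc in names(genome)) {
    L <- Biostrings::width(genome)[match(sc, names(genome))]
    a <- alignments[alignments$scaffold == sc, ]
    if (nrow(a) == 0) next
    if (is.unsorted(a$start)) a <- a[order(a$start), ]
    ends_at <- clip_end_counts(a$start, a$end, a$clip_left, a$clip_right, L)
    cand <- which(ends_at > 0L) - 1L          # 0-based candidate positions
    if (length(cand) == 0) next
    cnt <- ends_at[cand + 1L]
    # merge candidates within merge_tol into the position of maximal count
    grp <- cumsum(c(1L, diff(cand) > params$merge_tol))
    merged <- tibble(pos = cand, end_count = cnt, grp = grp) %>%
      group_by(.data$grp) %>%
      summarise(pos = .data$pos[which.max(.data$end_count)],
                end_count = sum(.data$end_count), .groups = "drop")
    cov <- coverage_counts(a$start, a$end, L)
    half <- params$cov_window %/% 2L
    merged$coverage <- vapply(merged$pos, function(pp) {
      stats::median(cov[max(1L, pp + 1L - half):min(L, pp + 1L + half)])
    }, numeric(1))
    keep <- merged$end_count > min_ends &
      merged$pos >= params$end_margin &
      merged$pos < L - params$end_margin &
      merged$coverage < params$max_coverage
    m <- merged[keep, ]
    if (nrow(m)) {
      out[[sc]] <- tibble(scaffold = sc, pos = as.integer(m$pos),
                          end_count = as.integer(m$end_count),
                          coverage = as.integer(m$coverage))
    }
  }
  sites <- if (length(out)) bind_rows(out) else {
    tibble(scaffold = character(), pos = integer(), end_count = integer(),
           coverage = integer())
  }
  sites <- arrange(sites, .data$scaffold, .data$pos)
  annotate_sites_with_ta(sites, genome)
}

#' Annotate breakpoint sites with the TA dinucleotide flag
#'
#' `has_ta` is `TRUE` when the somatic genome carries `TA` starting at the
#' site position or one base upstream — the two registers at which an
#' alignment stopping on the retained TA can terminate. At scaffold edges
#' the flag is computed on the available bases.
#'
#' @param sites A tibble with `scaffold` and `pos` (0-based) columns.
#' @param genome A [Biostrings::DNAStringSet].
#' @return `sites` with a logical `has_ta` column.
#' @export
annotate_sites_with_ta <- function(sites, genome) {
  if (nrow(sites) == 0) {
    sites$has_ta <- logical(0)
    return(sites)
  }
  chrs <- setNames(as.character(genome), names(genome))
  has_ta <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ref <- chrs[[sites$scaffold[i]]]
    p <- sites$pos[i]
    at_p <- p + 2 <= nchar(ref) && substr(ref, p + 1, p + 2) == "TA"
    at_pm1 <- p >= 1 && substr(ref, p, p + 1) == "TA"
    has_ta[i] <- at_p || at_pm1
  }
  sites$has_ta <- has_ta
  sites
}
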