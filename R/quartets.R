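#' Group IESs across the four genes of WGD quartets and tally retention
#' patterns
#'
#' A quartet is a gene family retained in four copies through the
#' intermediate then the recent whole-genome duplication; the two recent-WGD
#' sibling pairs form the two "branches" of the intermediate WGD. IESs at
#' the same aligned position (within `tol` columns, transitively) form one
#' group assumed to descend from a single ancestral insertion; each group is
#' labelled by its presence pattern, oriented so that `1100` means both
#' genes of one intermediate branch.
#'
#' @param quartet_genes A tibble: `quartet_id`, `gene_id`, `branch` (`A` or
#'   `B`), `aligned` (row of a common quartet alignment; gaps `-`).
#' @param gene_ies A tibble: `gene_id`, `offset` (0-based IES position
#'   within the ungapped gene).
#' @param tol Alignment-column tolerance. Default 2.
#' @return A `quartet_patterns` object: `counts` (named vector `N1111`,
#'   `N1110`, `N1100`, `N1010`, `N1000`), `groups` (per-group tibble),
#'   `n_ambiguous`.
#' @export
classify_quartet_patterns <- function(quartet_genes, gene_ies, tol = 2) {
  counts <- c(N1111 = 0L, N1110 = 0L, N1100 = 0L, N1010 = 0L, N1000 = 0L)
  groups <- list()
  n_ambiguous <- 0L
  for (qid in unique(quartet_genes$quartet_id)) {
    qg <- quartet_genes[quartet_genes$quartet_id == qid, ]
    if (nrow(qg) != 4) abort(paste0("quartet ", qid, " does not have 4 genes"))
    rows <- list()
    for (i in seq_len(4)) {
      offs <- gene_ies$offset[gene_ies$gene_id == qg$gene_id[i]]
      for (o in offs) {
        rows[[length(rows) + 1]] <- tibble(
          gene_id = qg$gene_id[i], branch = qg$branch[i],
          col = aligned_column(qg$aligned[i], o))
      }
    }
    if (length(rows) == 0) next
    tab <- bind_rows(rows) %>% arrange(.data$col)
    # transitive single-linkage grouping of columns within tol
    grp <- cumsum(c(1L, diff(tab$col) > tol))
    for (g in unique(grp)) {
      members <- tab[grp == g, ]
      if (anyDuplicated(members$gene_id)) {
        n_ambiguous <- n_ambiguous + 1L
        next
      }
      n_a <- sum(members$branch == "A")
      n_b <- sum(members$branch == "B")
      pattern <- pattern_label(n_a, n_b)
      counts[paste0("N", pattern)] <- counts[paste0("N", pattern)] + 1L
      groups[[length(groups) + 1]] <- tibble(
        quartet_id = qid, column = round(mean(members$col)),
        pattern = pattern, n_genes = nrow(members))
    }
  }
  structure(list(counts = counts,
                 groups = if (length(groups)) bind_rows(groups) else NULL,
                 n_ambiguous = n_ambiguous),
            class = "quartet_patterns")
}

# Orient a (branch A count, branch B count) pair to the canonical pattern
# label; cross-branch single/single cases are lumped as 1010.
pattern_label <- function(n_a, n_b) {
  key <- paste(sort(c(n_a, n_b), decreasing = TRUE), collapse = "")
  switch(key, "22" = "1111", "21" = "1110", "20" = "1100",
         "11" = "1010", "10" = "1000",
         abort("impossible branch counts"))
}

# Per-cohort probabilities of the observable patterns (and the never-seen
# 0000 mass), as a function of the per-period-per-branch survival s.
#   cohort g3: extant at the intermediate WGD
#   cohort g2: acquired on one intermediate branch (uniform time in period)
#   cohort g1: acquired on one terminal branch
# Partial-period survival sigma = (1-s)/(-log s) for uniform acquisition and
# a constant loss rate.
cohort_probabilities <- function(s) {
  stopifnot(s > 0, s <= 1)
  q <- 1 - s + s * (1 - s)^2        # an intermediate branch leaves no copy
  sigma <- partial_survival(s)
  patterns <- c("1111", "1110", "1100", "1010", "1000", "0000")
  g3 <- c(s^6, 4 * s^5 * (1 - s), 2 * s^3 * q,
          4 * s^4 * (1 - s)^2, 4 * s^2 * (1 - s) * q, q^2)
  g2 <- c(0, 0, sigma * s^2, 0, 2 * sigma * s * (1 - s),
          1 - sigma + sigma * (1 - s)^2)
  g1 <- c(0, 0, 0, 0, sigma, 1 - sigma)
  p_obs <- c(g3 = 1 - q^2, g2 = sigma * (1 - (1 - s)^2), g1 = sigma)
  list(patterns = patterns, g3 = g3, g2 = g2, g1 = g1, p_obs = p_obs,
       sigma = sigma)
}

partial_survival <- function(s) if (s >= 1) 1 else (1 - s) / (-log(s))

#' Pattern probabilities of the quartet gain/loss model
#'
#' For each acquisition cohort (`g3`: extant at the intermediate WGD; `g2`:
#' acquired between the WGDs; `g1`: acquired since the recent WGD) the
#' probability of every retention pattern, including the unobservable
#' all-lost `0000`; probabilities within a cohort sum to 1. When cohort
#' fractions `rho` are supplied, the observation-conditioned mixture over
#' the five observable patterns is added.
#'
#' @param s Full-period survival probability per branch and period, in
#'   (0, 1].
#' @param rho Optional cohort fractions `(rho3, rho2, rho1)` summing to 1.
#' @return A tibble: `cohort`, `pattern`, `prob`; attribute `p_obs` gives
#'   per-cohort observation probabilities.
#' @export
pattern_probabilities <- function(s, rho = NULL) {
  cp <- cohort_probabilities(s)
  out <- bind_rows(
    tibble(cohort = "g3", pattern = cp$patterns, prob = cp$g3),
    tibble(cohort = "g2", pattern = cp$patterns, prob = cp$g2),
    tibble(cohort = "g1", pattern = cp$patterns, prob = cp$g1)
  )
  if (!is.null(rho)) {
    stopifnot(length(rho) == 3, abs(sum(rho) - 1) < 1e-8, all(rho >= 0))
    obs_mass <- sum(rho * cp$p_obs)
    mix <- (rho[1] * cp$g3 + rho[2] * cp$g2 + rho[3] * cp$g1)[1:5] / obs_mass
    out <- bind_rows(out, tibble(cohort = "mixture",
                                 pattern = cp$patterns[1:5], prob = mix))
  }
  structure(out, p_obs = cp$p_obs)
}

as_pattern_counts <- function(counts) {
  if (inherits(counts, "quartet_patterns")) counts <- counts$counts
  nm <- c("N1111", "N1110", "N1100", "N1010", "N1000")
  if (is.null(names(counts))) names(counts) <- nm
  stopifnot(all(nm %in% names(counts)), all(counts >= 0))
  as.numeric(counts[nm])
}

# Negative log-likelihood on the unconstrained scale
# par = (logit s, log w3/w1, log w2/w1); w are observed-cohort weights.
gain_loss_nll <- function(par, counts) {
  if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
  s <- stats::plogis(par[1])
  w <- exp(c(par[2], par[3], 0))
  w <- w / sum(w)
  cp <- cohort_probabilities(s)
  p <- w[1] * cp$g3[1:5] / cp$p_obs[1] +
    w[2] * cp$g2[1:5] / cp$p_obs[2] +
    w[3] * cp$g1[1:5] / cp$p_obs[3]
  if (any(!is.finite(p)) || any(p <= 0)) return(1e10)
  -sum(counts * log(p))
}

#' Fit the three-cohort gain/loss model to quartet pattern counts
#'
#' Maximizes the multinomial likelihood of the five observable patterns over
#' the survival `s` and the observed-cohort mixture weights, then converts
#' the weights to acquisition-cohort fractions `rho` by dividing out each
#' cohort's observation probability. Deterministic multi-start optimization
#' (fixed grid of Nelder-Mead starts). Model conventions: equal durations of
#' the two inter-WGD periods, constant loss rate (so one `s` ties all
#' survival factors together), uniform acquisition times within a period,
#' and `rho3` absorbing any pre-intermediate-WGD loss (those events are not
#' separately identifiable).
#'
#' @param counts Named counts (`N1111`, `N1110`, `N1100`, `N1010`, `N1000`)
#'   or a `quartet_patterns` object.
#' @return A `gain_loss_fit`: `rho` (named `rho3`, `rho2`, `rho1`), `s`,
#'   `sigma`, `weights`, `loglik`, `counts`, `fitted` (expected pattern
#'   probabilities).
#' @export
fit_gain_loss <- function(counts) {
  counts <- as_pattern_counts(counts)
  if (sum(counts) < 1) abort("no observed patterns to fit")
  if (sum(counts > 0) == 1) {
    warn("all counts in a single pattern; boundary estimate returned")
  }
  best <- NULL
  for (s0 in c(-1, 0.5, 2)) {
    for (a0 in c(-2, 0, 2)) {
      for (b0 in c(-2, 0, 2)) {
        f <- optim(c(s0, a0, b0), gain_loss_nll, counts = counts,
                   method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-12))
        if (is.null(best) || f$value < best$value - 1e-9) best <- f
      }
    }
  }
  s <- stats::plogis(best$par[1])
  w <- exp(c(best$par[2], best$par[3], 0))
  w <- w / sum(w)
  cp <- cohort_probabilities(s)
  rho <- w / cp$p_obs
  rho <- rho / sum(rho)
  fitted <- w[1] * cp$g3[1:5] / cp$p_obs[1] +
    w[2] * cp$g2[1:5] / cp$p_obs[2] + w[3] * cp$g1[1:5] / cp$p_obs[3]
  names(fitted) <- paste0("p", c("1111", "1110", "1100", "1010", "1000"))
  structure(list(rho = setNames(rho, c("rho3", "rho2", "rho1")),
                 s = s, sigma = cp$sigma,
                 weights = setNames(w, c("w3", "w2", "w1")),
                 loglik = -best$value, counts = setNames(
                   counts, c("N1111", "N1110", "N1100", "N1010", "N1000")),
                 fitted = fitted, convergence = best$convergence),
            class = "gain_loss_fit")
}

#' @export
print.gain_loss_fit <- function(x, ...) {
  cat("Quartet gain/loss model fit\n")
  cat(sprintf("  cohort fractions: rho3 = %.1f%%, rho2 = %.1f%%, rho1 = %.1f%%\n",
              100 * x$rho[1], 100 * x$rho[2], 100 * x$rho[3]))
  cat(sprintf("  per-period survival s = %.3f (sigma = %.3f)\n", x$s, x$sigma))
  cat(sprintf("  log-likelihood %.2f on n = %d groups\n", x$loglik,
              as.integer(sum(x$counts))))
  invisible(x)
}

#' @rdname fit_gain_loss
#' @param x A `gain_loss_fit`.
#' @param ... Unused.
#' @export
tidy.gain_loss_fit <- function(x, ...) {
  tibble(term = c(names(x$rho), "s", "sigma"),
         estimate = c(unname(x$rho), x$s, x$sigma))
}

#' @rdname fit_gain_loss
#' @export
glance.gain_loss_fit <- function(x, ...) {
  tibble(loglik = x$loglik, s = x$s, n = sum(x$counts),
         converged = x$convergence == 0)
}

#' Likelihood-ratio test that all IESs predate the intermediate WGD
#'
#' Null: only the `g3` cohort exists (survival `s` free); alternative: the
#' full three-cohort model. The statistic is twice the log-likelihood gain,
#' compared against a chi-squared distribution with 2 degrees of freedom.
#'
#' @param counts As for [fit_gain_loss()].
#' @return A one-row tibble: `statistic`, `df`, `p`, plus both fits'
#'   log-likelihoods.
#' @export
lrt_all_ancient <- function(counts) {
  counts <- as_pattern_counts(counts)
  full <- fit_gain_loss(counts)
  nll0 <- function(ls) {
    s <- stats::plogis(ls)
    cp <- cohort_probabilities(s)
    p <- cp$g3[1:5] / cp$p_obs[1]
    if (any(p <= 0)) return(1e10)
    -sum(counts * log(p))
  }
  o0 <- stats::optimize(nll0, interval = c(-12, 12), tol = 1e-10)
  loglik0 <- -o0$objective
  stat <- max(0, 2 * (full$loglik - loglik0))
  tibble(statistic = stat, df = 2L,
         p = pchisq(stat, df = 2, lower.tail = FALSE),
         loglik_full = full$loglik, loglik_null = loglik0)
}
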