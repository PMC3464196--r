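#' Configuration for the synthetic IES data generator
#'
#' Defaults reproduce the statistical structure the detection and inference
#' stages assume: a 28% G+C somatic (MAC-like) genome, IESs at 20% G+C with
#' the periodic size distribution (first peak at 28 bp, hard minimum 26 bp,
#' ~10.2 bp inter-peak spacing, geometric peak-weight decay, depleted second
#' peak), a degenerate TAYAGYNR end consensus, and 108 nt reads at 160x
#' coverage from ~500 bp fragments.
#'
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#' @param genome_length Total somatic genome length, bp. Default 500000.
#' @param n_scaffolds Number of scaffolds. Default 5.
#' @param gc Somatic genome G+C content. Default 0.28.
#' @param gene_mean_length,gene_gap_mean Mean gene length and mean intergenic
#'   gap, bp (genes are tiled with 1-3 exons and short introns).
#' @param n_ies Number of IESs to plant. Default 500.
#' @param ies_gc IES G+C content. Default 0.20.
#' @param first_peak,min_len,spacing,peak_sd,decay,second_peak_factor,n_peaks
#'   Size-model parameters: first-peak centre (28), minimum length (26),
#'   inter-peak spacing (10.2), per-peak s.d. (1.5), geometric weight decay
#'   (0.65), depleted-second-peak weight multiplier (0.05), number of peaks.
#' @param read_length,fragment,coverage Read simulation parameters
#'   (108 nt, 500 bp, 160x).
#' @param min_ies_spacing Minimum distance between planted insertion points,
#'   bp. Default 250 (keeps junction signals of neighbouring IESs separate).
#' @param edge_margin No IES is planted closer than this to a scaffold end.
#'   Default 600.
#' @param contig_length,contig_overlap Tiling used by [simulate_contigs()].
#' @param error_rate Per-base substitution rate for reads. Default 0
#'   (detection logic, not the mapper, is under test).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 500000, n_scaffolds = 5, gc = 0.28,
                       gene_mean_length = 1800, gene_gap_mean = 350,
                       n_ies = 500, ies_gc = 0.20,
                       first_peak = 28, min_len = 26, spacing = 10.2,
                       peak_sd = 1.5, decay = 0.65,
                       second_peak_factor = 0.05, n_peaks = 12,
                       read_length = 108, fragment = 500, coverage = 160,
                       min_ies_spacing = 250, edge_margin = 600,
                       contig_length = 1500, contig_overlap = 300,
                       error_rate = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            genome_length > 0, n_scaffolds >= 1, gc > 0, gc < 1,
            n_ies >= 0, ies_gc > 0, ies_gc < 1, min_len >= 2,
            spacing > 0, peak_sd > 0, decay > 0, decay < 1,
            second_peak_factor >= 0, read_length > 0, coverage > 0,
            read_length <= fragment, error_rate >= 0, error_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# iid bases at a target G+C
random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a somatic reference genome with gene annotations
#'
#' Scaffolds of i.i.d. bases at the configured G+C; non-overlapping genes
#' (1-3 exons, short introns) tiled along each scaffold with intergenic
#' gaps. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (interval tibble as from [read_gff3_genes()]).
#' @export
simulate_mac <- function(config) {
  set.seed(config$seed)
  per <- floor(config$genome_length / config$n_scaffolds)
  lens <- rep(per, config$n_scaffolds)
  lens[config$n_scaffolds] <- config$genome_length - per * (config$n_scaffolds - 1)
  if (any(lens < 2 * config$gene_gap_mean + config$gene_mean_length) &&
      config$gene_mean_length > 0) {
    if (any(lens < config$gene_mean_length)) {
      abort("gene demand exceeds genome length")
    }
  }
  seqs <- vapply(lens, random_dna, character(1), gc = config$gc)
  names(seqs) <- sprintf("scaffold_%d", seq_along(seqs))
  genome <- Biostrings::DNAStringSet(seqs)

  rows <- list()
  gi <- 0L
  for (sc in if (config$gene_mean_length > 0) names(seqs) else character()) {
    L <- nchar(seqs[[sc]])
    cursor <- round(runif(1, 0.5, 1.5) * config$gene_gap_mean)
    while (TRUE) {
      glen <- round(runif(1, 0.6, 1.4) * config$gene_mean_length)
      if (cursor + glen >= L) break
      gi <- gi + 1L
      gid <- sprintf("G%04d", gi)
      n_ex <- sample(1:3, 1)
      # short (20-30 bp) introns split the gene into exons
      intron_lens <- if (n_ex > 1) sample(20:30, n_ex - 1, replace = TRUE) else integer()
      coding <- glen - sum(intron_lens)
      cuts <- if (n_ex > 1) sort(sample(seq(30, coding - 30, by = 3), n_ex - 1)) else integer()
      ex_lens <- diff(c(0, cuts, coding))
      start <- cursor
      pos <- start
      phase <- 0L
      for (e in seq_len(n_ex)) {
        rows[[length(rows) + 1]] <- tibble(
          gene_id = gid, scaffold = sc, start = pos, end = pos + ex_lens[e],
          kind = "exon", strand = "+", phase = NA_integer_)
        rows[[length(rows) + 1]] <- tibble(
          gene_id = gid, scaffold = sc, start = pos, end = pos + ex_lens[e],
          kind = "CDS", strand = "+", phase = phase)
        if (e < n_ex) {
          rows[[length(rows) + 1]] <- tibble(
            gene_id = gid, scaffold = sc, start = pos + ex_lens[e],
            end = pos + ex_lens[e] + intron_lens[e],
            kind = "intron", strand = "+", phase = NA_integer_)
        }
        phase <- (3L - (sum(ex_lens[seq_len(e)]) %% 3L)) %% 3L
        pos <- pos + ex_lens[e] + if (e < n_ex) intron_lens[e] else 0L
      }
      cursor <- pos + round(runif(1, 0.5, 1.5) * config$gene_gap_mean)
    }
  }
  genes <- if (length(rows)) {
    bind_rows(rows) %>% arrange(.data$scaffold, .data$start)
  } else {
    tibble(gene_id = character(), scaffold = character(), start = integer(),
           end = integer(), kind = character(), strand = character(),
           phase = integer())
  }
  list(genome = genome, genes = genes)
}

#' Draw IES lengths from the periodic size model
#'
#' Mixture of Gaussian peaks at `first_peak + spacing * k` with geometric
#' weight decay (`decay^k`), the second peak damped by
#' `second_peak_factor`, truncated at `min_len` and rounded to integers.
#' Uses the current RNG state (seed control belongs to the caller).
#'
#' @param n Number of lengths.
#' @param config A [sim_config()] supplying the size-model parameters.
#' @return Integer vector of lengths.
#' @export
sample_ies_lengths <- function(n, config) {
  k <- 0:(config$n_peaks - 1)
  w <- config$decay^k
  w[2] <- w[2] * config$second_peak_factor
  w <- w / sum(w)
  peak <- sample.int(length(w), n, replace = TRUE, prob = w) - 1L
  len <- round(config$first_peak + config$spacing * peak +
                 stats::rnorm(n, 0, config$peak_sd))
  pmax(len, config$min_len)
}

# Position weight matrix approximating the degenerate 5'-TAYAGYNR-3'
# end consensus (rows A,C,G,T; columns = first 8 germline-element bases),
# skewed toward A/T to match an AT-rich element.
ies_end_pwm <- function(ies_gc) {
  at <- (1 - ies_gc) / 2
  gcb <- ies_gc / 2
  cbind(
    c(0, 0, 0, 1),                 # T
    c(1, 0, 0, 0),                 # A
    c(0.05, 0.25, 0.05, 0.65),     # Y
    c(0.75, 0.05, 0.10, 0.10),     # A-ish
    c(0.15, 0.05, 0.60, 0.20),     # G
    c(0.05, 0.25, 0.05, 0.65),     # Y
    c(at, gcb, gcb, at),           # N at IES background
    c(0.65, 0.05, 0.25, 0.05)      # R
  )
}

draw_pwm <- function(pwm) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(ncol(pwm)), function(j) {
    sample(bases, 1, prob = pwm[, j])
  }, character(1)), collapse = "")
}

# One IES sequence: starts TA, consensus over the first 8 germline-element
# positions and (reverse-complemented) over the last 8. The interior G+C is
# lowered to compensate the slightly GC-richer consensus positions so the
# pooled element composition hits the configured ies_gc.
sample_ies_seq <- function(len, config) {
  pwm <- ies_end_pwm(config$ies_gc)
  left <- draw_pwm(pwm)                       # element positions 1-8
  right_rc <- draw_pwm(pwm)                   # element last 8, rev-comp'd
  right <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(right_rc)))
  # element = seq + "TA"; its last 8 are (last 6 of seq) + "TA", so the
  # drawn right end must end in TA for consistency; force it.
  right <- paste0(substr(right, 1, 6), "TA")
  mid_len <- len + 2 - 8 - 8
  mid <- if (mid_len > 0) {
    # expected G+C carried by the 12 degenerate consensus positions
    # (both ends, minus the constitutive TAs); rows 2:3 are C and G
    e_gc <- 2 * sum(pwm[2:3, 3:8])
    gc_mid <- (config$ies_gc * len - e_gc) / mid_len
    random_dna(mid_len, min(max(gc_mid, 0.01), 0.99))
  } else ""
  element <- paste0(left, mid, right)
  element <- substr(element, 1, len + 2)
  substr(element, 1, len)                     # drop the right-boundary TA
}

#' Plant IESs into a somatic genome
#'
#' Insertion points are drawn uniformly from existing TA dinucleotides
#' (which guarantees every planted locus is TA-canonicalizable), subject to
#' a minimum mutual spacing and a scaffold-edge margin. Lengths follow the
#' periodic mixture; sequences carry the end consensus at both germline
#' boundaries. The truth table stores each IES in leftmost-canonical form
#' together with its germline (MIC) coordinates.
#'
#' @param mac Output of [simulate_mac()].
#' @param config The same [sim_config()].
#' @return A list: `mic` ([Biostrings::DNAStringSet] germline genome),
#'   `truth` (tibble `scaffold`, `pos`, `seq`, `length`, `mic_start`,
#'   `context`, `gene_id`), `config`.
#' @export
plant_ies <- function(mac, config) {
  set.seed(config$seed + 1L)
  genome <- mac$genome
  chrs <- setNames(as.character(genome), names(genome))
  ta_sites <- list()
  for (sc in names(chrs)) {
    L <- nchar(chrs[[sc]])
    m <- Biostrings::matchPattern("TA", Biostrings::DNAString(chrs[[sc]]))
    p <- Biostrings::start(m) - 1L
    p <- p[p >= config$edge_margin & p < L - config$edge_margin]
    if (length(p)) ta_sites[[sc]] <- tibble(scaffold = sc, pos = p)
  }
  sites <- bind_rows(ta_sites)
  if (nrow(sites) < config$n_ies) abort("too few TA sites to plant IESs")
  sites <- sites[sample.int(nrow(sites)), ]
  chosen <- list()
  taken <- list()
  for (i in seq_len(nrow(sites))) {
    if (length(chosen) >= config$n_ies) break
    sc <- sites$scaffold[i]; p <- sites$pos[i]
    prev <- taken[[sc]]
    if (is.null(prev) || all(abs(prev - p) >= config$min_ies_spacing)) {
      chosen[[length(chosen) + 1]] <- sites[i, ]
      taken[[sc]] <- c(prev, p)
    }
  }
  if (length(chosen) < config$n_ies) {
    abort("could not satisfy IES spacing; lower n_ies or spacing")
  }
  truth <- bind_rows(chosen) %>% arrange(.data$scaffold, .data$pos)
  truth$length <- sample_ies_lengths(nrow(truth), config)
  truth$seq <- vapply(truth$length, sample_ies_seq, character(1),
                      config = config)

  # canonicalize (insertion may slide left against the flank)
  for (i in seq_len(nrow(truth))) {
    canon <- canonicalize_insertion(chrs[[truth$scaffold[i]]],
                                    truth$pos[i], truth$seq[i])
    truth$pos[i] <- canon$pos
    truth$seq[i] <- canon$seq
  }
  truth <- truth %>%
    distinct(.data$scaffold, .data$pos, .keep_all = TRUE) %>%
    arrange(.data$scaffold, .data$pos)

  # build the germline genome and record MIC coordinates
  mic <- chrs
  truth$mic_start <- NA_integer_
  for (sc in unique(truth$scaffold)) {
    idx <- which(truth$scaffold == sc)
    ref <- chrs[[sc]]
    offs <- cumsum(c(0L, truth$length[idx]))[seq_along(idx)]
    truth$mic_start[idx] <- truth$pos[idx] + offs
    pieces <- character(2 * length(idx) + 1)
    last <- 0L
    for (j in seq_along(idx)) {
      pieces[2 * j - 1] <- substr(ref, last + 1L, truth$pos[idx[j]])
      pieces[2 * j] <- truth$seq[idx[j]]
      last <- truth$pos[idx[j]]
    }
    pieces[2 * length(idx) + 1] <- substr(ref, last + 1L, nchar(ref))
    mic[[sc]] <- paste(pieces, collapse = "")
  }
  truth <- classify_context(
    normalize_ies(truth[, c("scaffold", "pos", "seq", "length")]) %>%
      left_join(truth[, c("scaffold", "pos", "mic_start")],
                by = c("scaffold", "pos")),
    mac$genes)
  list(mic = Biostrings::DNAStringSet(mic), truth = truth, config = config)
}

#' Simulate reads from the germline genome, pre-aligned to the somatic
#' reference
#'
#' Error-free reads are drawn uniformly from the germline (MIC) sequence at
#' the configured coverage; each read's somatic (MAC) alignment is computed
#' analytically from the truth table. Reads crossing an IES junction are
#' soft-clipped at the point where exact matching against the somatic
#' sequence stops (alignments extend through the retained TA and any chance
#' homology beyond it); reads fully inside an IES are unmappable and
#' omitted. Deterministic given the seed.
#'
#' @param planted Output of [plant_ies()].
#' @param mac Output of [simulate_mac()].
#' @param config The same [sim_config()].
#' @return An alignment tibble (columns of [read_sam()]).
#' @export
simulate_reads_sam <- function(planted, mac, config) {
  set.seed(config$seed + 2L)
  rl <- config$read_length
  if (rl > config$fragment) abort("read length exceeds fragment size")
  chrs <- setNames(as.character(mac$genome), names(mac$genome))
  mics <- setNames(as.character(planted$mic), names(planted$mic))
  out <- list()
  for (sc in names(mics)) {
    micseq <- mics[[sc]]
    Lm <- nchar(micseq)
    tr <- planted$truth[planted$truth$scaffold == sc, ]
    n_reads <- round(Lm * config$coverage / rl)
    a <- sample.int(Lm - rl + 1L, n_reads, replace = TRUE) - 1L
    b <- a + rl

    m <- tr$mic_start
    len <- tr$length
    p <- tr$pos
    # The aligner model stops on the residual TA: a left-junction alignment
    # extends through the retained TA (the IES element begins with the same
    # TA the somatic genome keeps) and is clipped beyond it; a right-junction
    # alignment starts exactly on the retained TA. No extension through
    # chance homology: the clip equals the IES overhang beyond the TA.
    ext_left <- rep(2L, nrow(tr))
    ext_right <- rep(0L, nrow(tr))
    cum_before <- cumsum(c(0L, len))[seq_along(len)]  # inserted bp before IES j

    if (nrow(tr) == 0) {
      ov <- integer(n_reads)
    } else {
      j1 <- findInterval(a, m)           # last IES starting at or before a
      ov <- integer(n_reads)
      has1 <- j1 >= 1
      ov[has1 & a < (m[pmax(j1, 1)] + len[pmax(j1, 1)])] <-
        j1[has1 & a < (m[pmax(j1, 1)] + len[pmax(j1, 1)])]
      j2 <- pmin(j1 + 1L, nrow(tr))
      nxt <- ov == 0L & j1 < nrow(tr) & b > m[j2]
      ov[nxt] <- j2[nxt]
    }

    qname <- sprintf("%s_r%06d", sc, seq_len(n_reads))
    flag <- sample(c(0L, 16L), n_reads, replace = TRUE)
    start <- integer(n_reads)
    cigar <- character(n_reads)
    drop <- logical(n_reads)

    plain <- ov == 0L
    if (any(plain)) {
      # offset = total inserted length before the read start
      off <- if (nrow(tr)) {
        k <- findInterval(a[plain], m)
        ifelse(k == 0L, 0L, cum_before[k] + len[k])
      } else 0L
      start[plain] <- a[plain] - off
      cigar[plain] <- sprintf("%dM", rl)
    }
    for (j in which(tabulate(ov, nbins = max(nrow(tr), 1)) > 0)) {
      sel <- which(ov == j)
      aj <- a[sel]; bj <- b[sel]
      inside <- aj >= m[j] & bj <= m[j] + len[j]
      cross_l <- aj < m[j] & bj <= m[j] + len[j]
      cross_r <- aj >= m[j] & bj > m[j] + len[j]
      span <- aj < m[j] & bj > m[j] + len[j]
      drop[sel[inside]] <- TRUE
      if (any(cross_l)) {
        i2 <- sel[cross_l]
        la <- m[j] - a[i2]
        t <- b[i2] - m[j]
        ext <- pmin(t, ext_left[j])
        clip <- t - ext
        start[i2] <- a[i2] - cum_before[j]
        cigar[i2] <- ifelse(clip > 0,
                            sprintf("%dM%dS", la + ext, clip),
                            sprintf("%dM", rl))
      }
      if (any(cross_r)) {
        i2 <- sel[cross_r]
        lb <- b[i2] - (m[j] + len[j])
        t <- (m[j] + len[j]) - a[i2]
        ext <- pmin(t, ext_right[j])
        clip <- t - ext
        start[i2] <- p[j] - ext
        cigar[i2] <- ifelse(clip > 0,
                            sprintf("%dS%dM", clip, ext + lb),
                            sprintf("%dM", rl))
      }
      if (any(span)) {
        i2 <- sel[span]
        la <- m[j] - a[i2]
        lb <- b[i2] - (m[j] + len[j])
        use_left <- la >= lb
        el <- pmin(len[j], ext_left[j])
        er <- pmin(len[j], ext_right[j])
        start[i2] <- ifelse(use_left, a[i2] - cum_before[j], p[j] - er)
        cigar[i2] <- ifelse(use_left,
                            sprintf("%dM%dS", la + el, rl - la - el),
                            sprintf("%dS%dM", rl - er - lb, er + lb))
      }
    }
    keep <- !drop
    out[[sc]] <- tibble(qname = qname[keep], flag = flag[keep], scaffold = sc,
                        pos1 = start[keep] + 1L, cigar = cigar[keep])
  }
  tbl <- bind_rows(out)
  alignments_from_cigar(tbl) %>% arrange(.data$scaffold, .data$start)
}

#' Tile the germline genome into error-free contigs
#'
#' Overlapping fixed-length windows over each germline scaffold, emulating
#' an ideal assembly of germline-enriched reads.
#'
#' @param planted Output of [plant_ies()].
#' @param config The same [sim_config()].
#' @return A [Biostrings::DNAStringSet] of contigs.
#' @export
simulate_contigs <- function(planted, config) {
  mics <- setNames(as.character(planted$mic), names(planted$mic))
  segs <- character()
  for (sc in names(mics)) {
    L <- nchar(mics[[sc]])
    step <- config$contig_length - config$contig_overlap
    starts <- seq(1L, max(1L, L - config$contig_overlap), by = step)
    ends <- pmin(starts + config$contig_length - 1L, L)
    keep <- ends - starts + 1L >= 2 * config$contig_overlap
    pieces <- substring(mics[[sc]], starts[keep], ends[keep])
    names(pieces) <- sprintf("%s_c%04d", sc, seq_along(pieces))
    segs <- c(segs, pieces)
  }
  Biostrings::DNAStringSet(segs)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_mac()], [plant_ies()],
#' [simulate_reads_sam()] and [simulate_contigs()].
#'
#' @param config A [sim_config()].
#' @return A list: `genome`, `genes`, `mic`, `truth`, `reads`, `contigs`,
#'   `config`.
#' @export
simulate_ies_dataset <- function(config) {
  mac <- simulate_mac(config)
  planted <- plant_ies(mac, config)
  reads <- simulate_reads_sam(planted, mac, config)
  contigs <- simulate_contigs(planted, config)
  list(genome = mac$genome, genes = mac$genes, mic = planted$mic,
       truth = planted$truth, reads = reads, contigs = contigs,
       config = config)
}

#' Forward-simulate quartet retention-pattern counts
#'
#' Explicit branch-survival draws under the three-cohort gain/loss process:
#' `g3` loci are extant at the intermediate WGD; `g2` (`g1`) loci arise at a
#' uniform time within their period on one intermediate (terminal) branch
#' and survive the remainder with probability `s^(1-u)`. Loci lost from all
#' four terminal genes are discarded. Independent of the analytic
#' probabilities in [pattern_probabilities()] by construction.
#'
#' @param rho Cohort fractions `(rho3, rho2, rho1)`, summing to 1.
#' @param s Full-period survival probability.
#' @param n Number of ancestral loci to simulate.
#' @param seed Integer seed.
#' @return Named integer counts (`N1111` ... `N1000`).
#' @export
simulate_quartet_counts <- function(rho, s, n, seed) {
  stopifnot(length(rho) == 3, abs(sum(rho) - 1) < 1e-8, s > 0, s <= 1, n >= 0)
  set.seed(seed)
  counts <- c(N1111 = 0L, N1110 = 0L, N1100 = 0L, N1010 = 0L, N1000 = 0L)
  if (n == 0) return(counts)
  cohort <- sample(3:1, n, replace = TRUE, prob = rho)  # 3 = g3, 2 = g2, 1 = g1
  surv <- function(nn, pr) stats::rbinom(nn, 1, pr) == 1

  for (ci in 3:1) {
    nn <- sum(cohort == ci)
    if (nn == 0) next
    if (ci == 3) {
      brA <- surv(nn, s); brB <- surv(nn, s)
      a1 <- brA & surv(nn, s); a2 <- brA & surv(nn, s)
      b1 <- brB & surv(nn, s); b2 <- brB & surv(nn, s)
    } else if (ci == 2) {
      u <- runif(nn)
      alive <- surv(nn, s^(1 - u))      # to the end of the middle period
      onA <- runif(nn) < 0.5
      a1 <- alive & onA & surv(nn, s); a2 <- alive & onA & surv(nn, s)
      b1 <- alive & !onA & surv(nn, s); b2 <- alive & !onA & surv(nn, s)
    } else {
      u <- runif(nn)
      alive <- surv(nn, s^(1 - u))
      which_gene <- sample.int(4, nn, replace = TRUE)
      a1 <- alive & which_gene == 1; a2 <- alive & which_gene == 2
      b1 <- alive & which_gene == 3; b2 <- alive & which_gene == 4
    }
    nA <- a1 + a2; nB <- b1 + b2
    tot <- nA + nB
    lab <- character(nn)
    lab[tot == 4] <- "N1111"
    lab[tot == 3] <- "N1110"
    lab[tot == 2 & (nA == 2 | nB == 2)] <- "N1100"
    lab[tot == 2 & nA == 1 & nB == 1] <- "N1010"
    lab[tot == 1] <- "N1000"
    tab <- table(lab[lab != ""])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  counts
}
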