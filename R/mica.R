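#' MICA parameters
#'
#' @param k Anchor k-mer size for contig-to-reference seeding. Default 21.
#' @param flank Anchored flank (bp) added on each side of a gap before local
#'   realignment. Default 50.
#' @param max_gc Contigs with G+C content at or above this fraction are
#'   discarded (germline-enriched assemblies are AT-rich; GC-rich contigs are
#'   presumed bacterial contamination). Default 0.5.
#' @param match,mismatch,gap_open,gap_extend Affine alignment scores used in
#'   local realignment. Defaults +2/-3/-5/-2.
#' @param max_segment Refuse to realign segments longer than this (bp guard).
#' @return A list of class `mica_params`.
#' @export
mica_params <- function(k = 21, flank = 50, max_gc = 0.5, match = 2,
                        mismatch = -3, gap_open = -5, gap_extend = -2,
                        max_segment = 20000) {
  structure(list(k = k, flank = flank, max_gc = max_gc, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, max_segment = max_segment),
            class = "mica_params")
}

#' Filter contigs by G+C content
#'
#' Keeps contigs whose G+C fraction over `{A,C,G,T}` (Ns ignored in the
#' denominator) is strictly below `max_gc`. Zero-length contigs are dropped
#' with a warning.
#'
#' @param contigs A [Biostrings::DNAStringSet].
#' @param max_gc Threshold fraction, default 0.5 (strict `<`).
#' @return The retained subset of `contigs`.
#' @export
filter_contigs <- function(contigs, max_gc = 0.5) {
  w <- Biostrings::width(contigs)
  if (any(w == 0)) {
    warn(paste0(sum(w == 0), " zero-length contig(s) dropped"))
    contigs <- contigs[w > 0]
  }
  if (length(contigs) == 0) return(contigs)
  freq <- Biostrings::letterFrequency(contigs, letters = c("A", "C", "G", "T"))
  gc <- (freq[, "G"] + freq[, "C"]) / pmax(rowSums(freq), 1)
  contigs[gc < max_gc]
}

#' Build a unique k-mer index of a genome
#'
#' Positions of every k-mer occurring exactly once genome-wide (forward
#' strand); repeated k-mers are unusable as anchors and are removed.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param k K-mer size.
#' @return A keyed [data.table::data.table] with columns `kmer`, `scaffold`,
#'   `pos` (0-based), of class `kmer_index` (attribute `k`).
#' @export
kmer_index <- function(genome, k = 21) {
  tabs <- lapply(names(genome), function(sc) {
    s <- as.character(genome[[sc]])
    L <- nchar(s)
    if (L < k) return(NULL)
    starts <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                           scaffold = sc, pos = starts - 1L)
  })
  dt <- data.table::rbindlist(tabs)
  if (nrow(dt)) {
    dt <- dt[!kmer %in% dt[duplicated(kmer), kmer]]
    dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  }
  data.table::setkey(dt, kmer)
  data.table::setattr(dt, "k", k)
  dt
}

#' Anchor a contig on the reference by unique k-mer chaining
#'
#' Exact-match anchors (maximal runs of co-diagonal unique k-mer hits) are
#' chained by the highest-weight colinear increasing subsequence; the gaps
#' between adjacent chained anchors become insertion/deletion candidates.
#' Contigs with no anchors, or with two equally good chains (repeats), are
#' reported unmapped/ambiguous.
#'
#' @param contig Contig sequence (character scalar or `DNAString`).
#' @param index A [kmer_index()] of the reference (or a `DNAStringSet`, from
#'   which an index is built on the fly).
#' @param k K-mer size; taken from the index when one is supplied.
#' @return A list of class `anchor_chain`: `mapped`, `scaffold`, `anchors`
#'   (tibble `cstart`, `rstart`, `len`; 0-based), `gaps` (tibble
#'   `ref_start`, `ref_end`, `contig_start`, `contig_end`), `reason`.
#' @export
anchor_align_contig <- function(contig, index, k = 21) {
  if (methods::is(index, "DNAStringSet")) index <- kmer_index(index, k)
  k <- attr(index, "k")
  s <- as.character(contig)
  L <- nchar(s)
  unmapped <- function(reason) {
    structure(list(mapped = FALSE, scaffold = NA_character_,
                   anchors = NULL, gaps = NULL, reason = reason),
              class = "anchor_chain")
  }
  if (L < k) return(unmapped("contig shorter than k"))
  starts <- seq_len(L - k + 1L)
  q <- data.table::data.table(kmer = substring(s, starts, starts + k - 1L),
                              cpos = starts - 1L)
  hits <- index[q, on = "kmer", nomatch = NULL]
  if (nrow(hits) == 0) return(unmapped("no unique anchors"))

  # collapse co-diagonal runs of hits into maximal exact-match anchors
  hits[, diag_id := paste0(scaffold, ":", pos - cpos)]
  data.table::setorder(hits, diag_id, cpos)
  hits[, run := cumsum(c(1L, diff(cpos) != 1L)), by = diag_id]
  anchors <- hits[, .(scaffold = scaffold[1], cstart = cpos[1],
                      rstart = pos[1], len = cpos[.N] - cpos[1] + k),
                  by = .(diag_id, run)]

  # Best chain per scaffold (weighted LIS over anchor lengths). Adjacent
  # anchors may overlap by a few bases on either sequence (the retained TA
  # at an insertion matches on both sides of the junction); overlaps are
  # allowed during chaining and trimmed from the downstream anchor after.
  chain_one <- function(a) {
    a <- a[order(a$cstart), ]
    m <- nrow(a)
    best <- a$len
    prev <- rep(NA_integer_, m)
    for (i in seq_len(m)[-1]) {
      for (j in seq_len(i - 1)) {
        ok <- a$cstart[j] < a$cstart[i] && a$rstart[j] < a$rstart[i] &&
          a$cstart[j] + a$len[j] < a$cstart[i] + a$len[i] &&
          a$rstart[j] + a$len[j] < a$rstart[i] + a$len[i]
        if (ok && best[j] + a$len[i] > best[i]) {
          best[i] <- best[j] + a$len[i]
          prev[i] <- j
        }
      }
    }
    i <- which.max(best)
    path <- integer()
    while (!is.na(i)) { path <- c(i, path); i <- prev[i] }
    a <- a[path, , drop = FALSE]
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        o <- max(0L, a$cstart[i - 1] + a$len[i - 1] - a$cstart[i],
                 a$rstart[i - 1] + a$len[i - 1] - a$rstart[i])
        a$cstart[i] <- a$cstart[i] + o
        a$rstart[i] <- a$rstart[i] + o
        a$len[i] <- a$len[i] - o
      }
      a <- a[a$len > 0, , drop = FALSE]
    }
    list(score = max(best), anchors = a)
  }
  per_sc <- split(as_tibble(anchors)[, c("scaffold", "cstart", "rstart", "len")],
                  anchors$scaffold)
  chains <- lapply(per_sc, chain_one)
  scores <- vapply(chains, function(x) x$score, numeric(1))
  top <- which.max(scores)
  if (length(scores) > 1 && sum(scores == max(scores)) > 1) {
    return(unmapped("ambiguous placement (equally scoring chains)"))
  }
  ch <- chains[[top]]$anchors
  gaps <- NULL
  if (nrow(ch) > 1) {
    gaps <- tibble(
      ref_start = ch$rstart[-nrow(ch)] + ch$len[-nrow(ch)],
      ref_end = ch$rstart[-1],
      contig_start = ch$cstart[-nrow(ch)] + ch$len[-nrow(ch)],
      contig_end = ch$cstart[-1]
    )
  } else {
    gaps <- tibble(ref_start = integer(), ref_end = integer(),
                   contig_start = integer(), contig_end = integer())
  }
  structure(list(mapped = TRUE, scaffold = names(per_sc)[top],
                 anchors = as_tibble(ch[, c("cstart", "rstart", "len")]),
                 gaps = gaps, reason = NA_character_),
            class = "anchor_chain")
}

#' Globally realign a gap between two anchors
#'
#' Affine-gap global (Needleman-Wunsch) alignment of a reference segment and
#' the corresponding contig segment, each including a fixed anchored flank.
#' The insertion block is the maximal contig-only run of the alignment.
#'
#' @param ref_segment,contig_segment Character scalars.
#' @param params A [mica_params()] object (scoring constants, size guard).
#' @return A list: `score`, `ref_aligned`, `contig_aligned`, and for the
#'   maximal insertion `ins_seq` (`""` if none) with `ins_ref_offset`, the
#'   0-based offset within `ref_segment` at which the insertion sits.
#' @export
realign_gap <- function(ref_segment, contig_segment, params = mica_params()) {
  if (nchar(ref_segment) > params$max_segment ||
      nchar(contig_segment) > params$max_segment) {
    abort("segment exceeds realignment size guard")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = contig_segment, subject = ref_segment, type = "global",
    substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  subc <- strsplit(sub, "", fixed = TRUE)[[1]]
  patc <- strsplit(pat, "", fixed = TRUE)[[1]]
  is_gap <- subc == "-"
  ins_seq <- ""
  ins_ref_offset <- NA_integer_
  if (any(is_gap)) {
    r <- rle(is_gap)
    runs_end <- cumsum(r$lengths)
    runs_start <- runs_end - r$lengths + 1L
    gi <- which(r$values)
    best <- gi[which.max(r$lengths[gi])]
    cols <- runs_start[best]:runs_end[best]
    ins_seq <- paste(patc[cols], collapse = "")
    ins_ref_offset <- sum(!is_gap[seq_len(runs_start[best] - 1L)])
  }
  list(score = Biostrings::score(aln), ref_aligned = sub, contig_aligned = pat,
       ins_seq = ins_seq, ins_ref_offset = ins_ref_offset)
}

#' Accept or reject a rough insertion as a TA-bounded IES
#'
#' Slides the insertion against identical flanking bases to enumerate every
#' equivalent placement; the insertion is accepted as an IES if some
#' placement begins with `TA` while the somatic reference retains `TA` at the
#' insertion point (germline locus `L + TA..seq.. + TA + R`, somatic
#' `L + TA + R`). The leftmost such placement is returned.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param scaffold Scaffold name.
#' @param ref_pos 0-based insertion offset on the scaffold.
#' @param inserted_seq The inserted sequence (non-empty).
#' @return A one-row IES tibble, or an `ies_rejection` object whose
#'   `reason` element describes why the insertion was not accepted.
#' @export
adjust_ies_boundaries <- function(genome, scaffold, ref_pos, inserted_seq) {
  if (nchar(inserted_seq) == 0) abort("empty insertion")
  ref <- as.character(genome[[scaffold]])
  if (ref_pos < 0 || ref_pos > nchar(ref)) abort("insertion point outside scaffold")
  rejection <- function(reason) {
    structure(list(reason = reason), class = "ies_rejection")
  }
  canon <- canonicalize_insertion(ref, ref_pos, inserted_seq)
  if (is.null(canon)) return(rejection("no TA-bounded placement"))
  if (grepl("N", canon$seq, fixed = TRUE)) {
    return(rejection("insertion overlaps N"))
  }
  flags <- if (nchar(canon$seq) < 26) "shorter_than_26" else ""
  normalize_ies(tibble(scaffold = scaffold, pos = canon$pos, seq = canon$seq,
                       length = nchar(canon$seq), support = 1L, flags = flags))
}

#' Call IESs from germline contigs against a somatic reference (MICA)
#'
#' Composition of the pipeline: G+C contig filter, unique k-mer anchor
#' chaining, local affine-gap realignment of inter-anchor gaps, and
#' TA-boundary adjustment. Duplicate calls at one `(scaffold, pos, seq)` are
#' merged with summed support. Per-contig failures are collected, never
#' aborting the run.
#'
#' @param contigs A [Biostrings::DNAStringSet] of germline contigs.
#' @param genome A [Biostrings::DNAStringSet] (somatic reference).
#' @param params A [mica_params()] object.
#' @param index Optional precomputed [kmer_index()] of `genome`.
#' @return A tibble of IES records (see [read_ies_gff3()] for columns).
#' @export
call_ies <- function(contigs, genome, params = mica_params(), index = NULL) {
  contigs <- filter_contigs(contigs, params$max_gc)
  if (length(contigs) == 0) return(empty_ies())
  if (is.null(index)) index <- kmer_index(genome, params$k)
  chrs <- setNames(as.character(genome), names(genome))
  recs <- list()
  for (ci in seq_along(contigs)) {
    cseq <- as.character(contigs[[ci]])
    chain <- tryCatch(anchor_align_contig(cseq, index),
                      error = function(e) NULL)
    if (is.null(chain) || !chain$mapped || nrow(chain$gaps) == 0) next
    ref <- chrs[[chain$scaffold]]
    for (gi in seq_len(nrow(chain$gaps))) {
      g <- chain$gaps[gi, ]
      ins_len <- (g$contig_end - g$contig_start) - (g$ref_end - g$ref_start)
      if (ins_len <= 0) next
      fl <- params$flank
      r0 <- max(0L, g$ref_start - fl)
      r1 <- min(nchar(ref), g$ref_end + fl)
      c0 <- max(0L, g$contig_start - fl)
      c1 <- min(nchar(cseq), g$contig_end + fl)
      res <- tryCatch(
        realign_gap(substr(ref, r0 + 1L, r1), substr(cseq, c0 + 1L, c1), params),
        error = function(e) NULL)
      if (is.null(res) || !nzchar(res$ins_seq)) next
      rough_pos <- r0 + res$ins_ref_offset
      rec <- adjust_ies_boundaries(genome, chain$scaffold, rough_pos, res$ins_seq)
      if (is.data.frame(rec)) recs[[length(recs) + 1L]] <- rec
    }
  }
  if (length(recs) == 0) return(empty_ies())
  bind_rows(recs) %>%
    group_by(.data$scaffold, .data$pos, .data$seq) %>%
    summarise(length = first(.data$length), context = first(.data$context),
              gene_id = first(.data$gene_id), support = sum(.data$support),
              flags = first(.data$flags), .groups = "drop") %>%
    mutate(ies_id = sprintf("IES.%s.%d", .data$scaffold, .data$pos)) %>%
    normalize_ies()
}

#' Classify TA-indels against the IES catalogue
#'
#' TA-indels are low-level variants of the polyploid somatic genome produced
#' by IES excision errors. Each indel (after leftmost TA canonicalization) is
#' classified as: `exact_ies` (matches a catalogued IES), `internal_alternative`
#' (equals a TA-bounded sub-segment of an IES sharing one boundary TA —
#' excision used an internal alternative boundary), `external_alternative`
#' (one end coincides with an IES boundary TA, the other lies outside at a
#' somatic TA), or `unrelated`.
#'
#' @param indels A tibble: `scaffold`, `pos` (0-based), `seq`, `kind`
#'   (`residual` or `low_frequency`).
#' @param ies An IES catalogue tibble.
#' @param genome A [Biostrings::DNAStringSet].
#' @return `indels` with a `boundary_class` column (and canonicalized
#'   `pos`/`seq` where a TA-bounded placement exists).
#' @export
classify_ta_indels <- function(indels, ies, genome) {
  chrs <- setNames(as.character(genome), names(genome))
  out <- indels
  out$boundary_class <- rep("unrelated", nrow(indels))
  for (i in seq_len(nrow(indels))) {
    sc <- indels$scaffold[i]
    canon <- canonicalize_insertion(chrs[[sc]], indels$pos[i], indels$seq[i])
    if (is.null(canon)) {
      if (identical(indels$kind[i], "residual")) {
        warn(paste0("residual TA-indel at ", sc, ":", indels$pos[i],
                    " is not TA-bounded; classified unrelated"))
      }
      next
    }
    out$pos[i] <- canon$pos
    out$seq[i] <- canon$seq
    q <- canon$pos; t <- canon$seq; tl <- nchar(t)
    cand <- ies[ies$scaffold == sc, ]
    cls <- "unrelated"
    for (j in seq_len(nrow(cand))) {
      p <- cand$pos[j]; s <- cand$seq[j]; sl <- nchar(s)
      if (q == p && t == s) { cls <- "exact_ies"; break }
      # internal alternative: TA-bounded sub-segment of the IES sharing one
      # boundary TA; either case leaves an insertion at the IES site
      if (q == p && tl < sl) {
        share_left <- startsWith(s, t) && substr(s, tl + 1, tl + 2) == "TA"
        share_right <- t == substr(s, sl - tl + 1, sl)  # t starts with the
        if (share_left || share_right) {               # internal boundary TA
          cls <- "internal_alternative"; break
        }
      }
      # external alternative: one end on the IES boundary TA, the other
      # outside the IES at a somatic TA
      ref <- chrs[[sc]]
      if (q == p || q + tl == p) {
        other_end <- if (q == p) q + tl else q
        if (other_end + 2 <= nchar(ref) &&
            substr(ref, other_end + 1, other_end + 2) == "TA") {
          cls <- "external_alternative"; break
        }
      }
    }
    out$boundary_class[i] <- cls
  }
  out
}
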