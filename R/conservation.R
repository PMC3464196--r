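#' Map an ungapped sequence offset to its alignment column
#'
#' @param aligned A gapped aligned sequence (character scalar, `-` gaps).
#' @param pos 0-based offset within the ungapped sequence.
#' @return The 1-based alignment column holding that residue.
#' @export
aligned_column <- function(aligned, pos) {
  chars <- strsplit(aligned, "", fixed = TRUE)[[1]]
  residue_cols <- which(chars != "-")
  if (pos < 0 || pos >= length(residue_cols)) {
    abort("position beyond the ungapped sequence")
  }
  residue_cols[pos + 1L]
}

#' Is an IES position conserved between two aligned ohnologs?
#'
#' Each position (an offset within its ungapped gene sequence) is mapped to
#' its alignment column; the pair is conserved when the columns agree within
#' `tol` (2 nt by default, absorbing small alignment slop around the TA).
#'
#' @param pos_a,pos_b 0-based IES offsets within genes A and B.
#' @param aln_a,aln_b The two rows of the pairwise alignment.
#' @param tol Column tolerance, nt. Default 2.
#' @return Logical.
#' @export
conserved_pair <- function(pos_a, pos_b, aln_a, aln_b, tol = 2) {
  abs(aligned_column(aln_a, pos_a) - aligned_column(aln_b, pos_b)) <= tol
}

#' Add the conserved percentage to per-WGD conservation counts
#'
#' @param counts A tibble with columns `wgd`, `genes_with_ohnolog`, `n_ies`,
#'   `n_conserved`.
#' @return `counts` with `pct_conserved` (rounded to 0.1).
#' @export
summarize_conservation <- function(counts) {
  counts %>%
    mutate(pct_conserved = round(100 * .data$n_conserved / .data$n_ies, 1))
}

#' Per-WGD IES conservation table
#'
#' For every IES in a gene with at least one ohnolog of a given WGD age, the
#' IES counts as conserved when [conserved_pair()] holds against at least one
#' ohnolog of that age.
#'
#' @param pairs A tibble of aligned ohnolog pairs: `gene_a`, `gene_b`, `wgd`,
#'   `aln_a`, `aln_b` (gapped strings; degapping restores the gene sequences).
#' @param gene_ies A tibble of IES positions within genes: `gene_id`,
#'   `offset` (0-based, within the ungapped gene sequence).
#' @param tol Position tolerance in alignment columns. Default 2.
#' @return A tibble per WGD age: `wgd`, `genes_with_ohnolog`, `n_ies`,
#'   `n_conserved`, `pct_conserved`.
#' @export
conservation_table <- function(pairs, gene_ies, tol = 2) {
  if (nrow(pairs) == 0) {
    return(tibble(wgd = character(), genes_with_ohnolog = integer(),
                  n_ies = integer(), n_conserved = integer(),
                  pct_conserved = numeric()))
  }
  out <- list()
  for (w in unique(pairs$wgd)) {
    pw <- pairs[pairs$wgd == w, ]
    genes <- unique(c(pw$gene_a, pw$gene_b))
    ies_w <- gene_ies[gene_ies$gene_id %in% genes, ]
    conserved <- logical(nrow(ies_w))
    for (i in seq_len(nrow(ies_w))) {
      g <- ies_w$gene_id[i]
      off <- ies_w$offset[i]
      rel <- pw[pw$gene_a == g | pw$gene_b == g, ]
      for (r in seq_len(nrow(rel))) {
        a_side <- rel$gene_a[r] == g
        partner <- if (a_side) rel$gene_b[r] else rel$gene_a[r]
        my_aln <- if (a_side) rel$aln_a[r] else rel$aln_b[r]
        their_aln <- if (a_side) rel$aln_b[r] else rel$aln_a[r]
        their_offs <- gene_ies$offset[gene_ies$gene_id == partner]
        hit <- any(vapply(their_offs, function(o) {
          conserved_pair(off, o, my_aln, their_aln, tol)
        }, logical(1)))
        if (hit) { conserved[i] <- TRUE; break }
      }
    }
    out[[w]] <- tibble(wgd = w, genes_with_ohnolog = length(genes),
                       n_ies = nrow(ies_w),
                       n_conserved = sum(conserved))
  }
  summarize_conservation(bind_rows(out))
}

#' Dinucleotide entropy of a sequence
#'
#' Shannon entropy (bits) of the overlapping-dinucleotide composition; used
#' to flag low-complexity sequences (a perfect `TATATA...` repeat scores 1
#' bit, random DNA close to 4).
#'
#' @param seq Character scalar.
#' @return Entropy in bits.
#' @export
dinucleotide_entropy <- function(seq) {
  f <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(seq))
  p <- f / sum(f)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Cluster homologous IESs inserted at non-homologous sites
#'
#' All-against-all local alignment of IES sequences; a pair is similar when
#' the best local alignment covers at least `coverage` of the longer IES and
#' scores at least `min_score`. Pairs whose somatic flanking sequences
#' (`flank` bp each side of the insertion point) themselves align with score
#' `>= flank_score` are excluded (homologous site, not an independent
#' insertion). Low-complexity members (dinucleotide entropy below
#' `min_entropy`) are dropped. Clusters are the connected components of the
#' similarity graph (transitive closure), size 2 or more.
#'
#' @param ies An IES catalogue tibble.
#' @param genome A [Biostrings::DNAStringSet] supplying the flanks.
#' @param coverage Minimum coverage fraction of the longer IES. Default 0.85.
#' @param flank Flank length, bp. Default 500.
#' @param min_score Minimum local-alignment score for IES similarity.
#'   Default 50.
#' @param flank_score Flank-homology exclusion score. Default 40.
#' @param min_entropy Minimum dinucleotide entropy (bits). Default 2.
#' @param params A [mica_params()] supplying the scoring constants.
#' @return A tibble `cluster`, `ies_id`; attribute `pairs` holds the scored
#'   pair table.
#' @export
cluster_homologous_ies <- function(ies, genome, coverage = 0.85, flank = 500,
                                   min_score = 50, flank_score = 40,
                                   min_entropy = 2, params = mica_params()) {
  empty <- structure(tibble(cluster = integer(), ies_id = character()),
                     pairs = NULL)
  if (nrow(ies) < 2) return(empty)
  keep <- vapply(ies$seq, dinucleotide_entropy, numeric(1)) >= min_entropy
  ies <- ies[keep, ]
  if (nrow(ies) < 2) return(empty)

  chrs <- setNames(as.character(genome), names(genome))
  flank_up <- character(nrow(ies))
  flank_dn <- character(nrow(ies))
  for (i in seq_len(nrow(ies))) {
    ref <- chrs[[ies$scaffold[i]]]
    p <- ies$pos[i]
    flank_up[i] <- substr(ref, max(1, p - flank + 1), p)
    flank_dn[i] <- substr(ref, p + 1, min(nchar(ref), p + flank))
  }

  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  local_score <- function(a, b) {
    if (!nzchar(a) || !nzchar(b)) return(-Inf)
    Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = -params$gap_open, gapExtension = -params$gap_extend))
  }

  combs <- utils::combn(nrow(ies), 2)
  pair_rows <- list()
  for (c_i in seq_len(ncol(combs))) {
    i <- combs[1, c_i]; j <- combs[2, c_i]
    aln <- Biostrings::pairwiseAlignment(
      ies$seq[i], ies$seq[j], type = "local", substitutionMatrix = mat,
      gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
    longer <- max(nchar(ies$seq[i]), nchar(ies$seq[j]))
    on_longer <- if (nchar(ies$seq[i]) >= nchar(ies$seq[j])) {
      Biostrings::nchar(Biostrings::pattern(aln))
    } else {
      Biostrings::nchar(Biostrings::subject(aln))
    }
    cov <- on_longer / longer
    flank_hom <- local_score(flank_up[i], flank_up[j]) >= flank_score ||
      local_score(flank_dn[i], flank_dn[j]) >= flank_score
    pair_rows[[c_i]] <- tibble(
      ies_a = ies$ies_id[i], ies_b = ies$ies_id[j],
      score = Biostrings::score(aln), coverage = cov,
      flank_homologous = flank_hom,
      similar = Biostrings::score(aln) >= min_score && cov >= coverage &&
        !flank_hom)
  }
  pair_tbl <- bind_rows(pair_rows)
  edges <- pair_tbl[pair_tbl$similar, c("ies_a", "ies_b")]
  if (nrow(edges) == 0) return(structure(empty[0, ], pairs = pair_tbl))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = ies$ies_id)
  comp <- igraph::components(g)
  member <- tibble(ies_id = names(comp$membership),
                   cluster = unname(comp$membership)) %>%
    group_by(.data$cluster) %>% filter(n() >= 2) %>% ungroup()
  member$cluster <- match(member$cluster, unique(member$cluster))
  structure(member[, c("cluster", "ies_id")], pairs = pair_tbl)
}
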