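#' Read a genome (or contig set) from FASTA
#'
#' Sequences are uppercased and restricted to the alphabet `{A,C,G,T,N}`.
#' `U` (RNA) and any IUPAC ambiguity code other than `N` are rejected, as are
#' duplicated sequence identifiers.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) return(Biostrings::DNAStringSet())
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                       conditionMessage(e)))
    ),
    # the low-level reader silently drops letters outside the DNA alphabet;
    # treat that as a format error, not a cleanup
    warning = function(w) {
      if (grepl("invalid one-letter sequence code", conditionMessage(w))) {
        abort(paste0("malformed FASTA in ", path,
                     ": illegal sequence character"))
      }
      invokeRestart("muffleWarning")
    }
  )
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  ok <- Biostrings::letterFrequency(seqs, letters = "ACGTN", OR = "") |>
    rowSums() == Biostrings::width(seqs)
  if (any(!ok)) {
    abort(paste0("illegal character (outside A/C/G/T/N) in record '",
                 names(seqs)[which(!ok)[1]], "' of ", path))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated sequence id '", ids[duplicated(ids)][1],
                 "' in ", path))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Single home for the coordinate convention: internal coordinates are 0-based
# half-open [start, end); GFF3 text is 1-based inclusive.
#' Convert 0-based half-open coordinates to 1-based inclusive (GFF3)
#' @param start,end Numeric vectors, 0-based half-open.
#' @return A list with `start` and `end`, 1-based inclusive.
#' @export
to_gff_coords <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 0))
  list(start = start + 1L, end = end)
}

#' Convert 1-based inclusive (GFF3) coordinates to 0-based half-open
#' @param start,end Numeric vectors, 1-based inclusive.
#' @return A list with `start` and `end`, 0-based half-open.
#' @export
from_gff_coords <- function(start, end) {
  if (any(start < 1) || any(end < start)) {
    abort("GFF3 coordinates must satisfy 1 <= start <= end")
  }
  list(start = start - 1L, end = end)
}

#' Read gene models from GFF3
#'
#' Imports `gene`, `exon` and `CDS` features, converts them to 0-based
#' half-open coordinates, and derives introns as the gaps between consecutive
#' exons of a gene. Exons are associated to genes through their `Parent`
#' attribute (resolved through mRNA features when present), falling back to
#' containment within gene bounds.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with one row per interval: `gene_id`, `scaffold`,
#'   `start`, `end` (0-based half-open), `kind` (`exon`, `intron`, `CDS`),
#'   `strand`, `phase` (CDS only, else `NA`).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  if (nrow(df) == 0) {
    return(tibble(gene_id = character(), scaffold = character(),
                  start = integer(), end = integer(), kind = character(),
                  strand = character(), phase = integer()))
  }
  df$type <- as.character(df$type)
  get_attr <- function(col) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (is(v, "CharacterList") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
                    character(1))
      }
      as.character(v)
    } else rep(NA_character_, nrow(df))
  }
  df$ID <- get_attr("ID")
  df$Parent <- get_attr("Parent")

  genes <- df[df$type == "gene", ]
  if (any(genes$start < 1)) abort("negative or zero GFF3 coordinate")
  # resolve Parent chains (exon -> mRNA -> gene)
  parent_of <- setNames(df$Parent, df$ID)
  resolve_gene <- function(id) {
    seen <- character()
    while (!is.na(id) && !(id %in% genes$ID) && !(id %in% seen)) {
      seen <- c(seen, id)
      id <- if (id %in% names(parent_of)) parent_of[[id]] else NA_character_
    }
    id
  }
  parts <- df[df$type %in% c("exon", "CDS"), ]
  if (nrow(parts)) {
    parts$gene_id <- vapply(parts$Parent, resolve_gene, character(1))
    # containment fallback for orphan features
    orphan <- is.na(parts$gene_id)
    if (any(orphan)) {
      for (i in which(orphan)) {
        hit <- which(genes$seqnames == parts$seqnames[i] &
                       genes$start <= parts$start[i] & genes$end >= parts$end[i])
        if (length(hit)) parts$gene_id[i] <- genes$ID[hit[1]]
      }
    }
    if (any(is.na(parts$gene_id))) abort("exon/CDS feature with no resolvable gene")
  }

  out <- list()
  for (g in seq_len(nrow(genes))) {
    gid <- genes$ID[g]
    if (is.na(gid)) gid <- paste0("gene", g)
    gb <- from_gff_coords(genes$start[g], genes$end[g])
    p <- parts[!is.na(parts$gene_id) & parts$gene_id == gid, ]
    mk <- function(feature_kind) {
      q <- p[p$type == feature_kind, ]
      if (nrow(q) == 0) return(NULL)
      cc <- from_gff_coords(q$start, q$end)
      if (any(cc$start < gb$start) || any(cc$end > gb$end)) {
        abort(paste0(feature_kind, " outside gene bounds for gene '", gid, "'"))
      }
      o <- order(cc$start)
      if (any(diff(cc$start[o]) < 0) || any(cc$end[o][-length(o)] > cc$start[o][-1])) {
        abort(paste0("overlapping or out-of-order ", feature_kind,
                     "s in gene '", gid, "'"))
      }
      ph <- if (feature_kind == "CDS") as.integer(q$phase[o]) else NA_integer_
      tibble(gene_id = gid, scaffold = as.character(q$seqnames[1]),
             start = as.integer(cc$start[o]), end = as.integer(cc$end[o]),
             kind = feature_kind, strand = as.character(q$strand[1]),
             phase = ph)
    }
    ex <- mk("exon")
    cds <- mk("CDS")
    introns <- NULL
    if (!is.null(ex) && nrow(ex) > 1) {
      introns <- tibble(gene_id = gid, scaffold = ex$scaffold[1],
                        start = ex$end[-nrow(ex)], end = ex$start[-1],
                        kind = "intron", strand = ex$strand[1],
                        phase = NA_integer_)
    }
    out[[g]] <- bind_rows(ex, introns, cds)
  }
  bind_rows(out) %>% arrange(.data$scaffold, .data$gene_id, .data$start)
}

#' Validate an IES catalogue against a genome
#'
#' Checks, for every record, that the sequence begins with `TA`, that the
#' somatic genome carries `TA` at the insertion point (so the reconstruction
#' `MAC[0:p] + seq + MAC[p:]` restores the germline locus with its two
#' boundary TAs), that the sequence is free of `N`, and that the placement is
#' leftmost-canonical.
#'
#' @param ies A tibble of IES records (`scaffold`, `pos`, `seq`, ...).
#' @param genome A [Biostrings::DNAStringSet].
#' @return `ies` invisibly; aborts describing the first offending record.
#' @export
validate_ies <- function(ies, genome) {
  if (nrow(ies) == 0) return(invisible(ies))
  chrs <- setNames(as.character(genome), names(genome))
  for (i in seq_len(nrow(ies))) {
    sc <- ies$scaffold[i]; p <- ies$pos[i]; s <- ies$seq[i]
    lab <- paste0("IES record ", i, " (", sc, ":", p, ")")
    if (!sc %in% names(chrs)) abort(paste0(lab, ": unknown scaffold"))
    if (substr(s, 1, 2) != "TA") abort(paste0(lab, ": sequence does not start with TA"))
    if (grepl("N", s, fixed = TRUE)) abort(paste0(lab, ": sequence contains N"))
    ref <- chrs[[sc]]
    if (p < 0 || p + 2 > nchar(ref)) abort(paste0(lab, ": insertion point outside scaffold"))
    if (substr(ref, p + 1, p + 2) != "TA") {
      abort(paste0(lab, ": somatic genome lacks TA at the insertion point"))
    }
    canon <- canonicalize_insertion(ref, p, s)
    if (is.null(canon) || canon$pos != p || canon$seq != s) {
      abort(paste0(lab, ": placement is not leftmost-canonical"))
    }
  }
  invisible(ies)
}

#' Canonicalize an insertion placement (leftmost TA-led form)
#'
#' An insertion of `seq` at 0-based reference offset `pos` (germline locus
#' `ref[0:pos] + seq + ref[pos:]`) can slide against identical flanking bases.
#' All equivalent placements are enumerated by sliding; among those whose
#' sequence begins with `TA` *and* whose reference retains a `TA` at the
#' insertion point, the leftmost is returned.
#'
#' @param ref Reference scaffold sequence (character scalar).
#' @param pos 0-based insertion offset on `ref`.
#' @param seq Inserted sequence (character scalar).
#' @return A list with `pos` and `seq` for the canonical placement, or `NULL`
#'   if no TA-bounded placement exists.
#' @export
canonicalize_insertion <- function(ref, pos, seq) {
  len <- nchar(seq)
  L <- nchar(ref)
  if (len == 0 || pos < 0 || pos > L) abort("invalid insertion")
  refc <- strsplit(ref, "", fixed = TRUE)[[1]]
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  placements <- list(list(pos = pos, s = sc))
  # slide left: allowed when the last inserted base equals ref[pos-1]
  p <- pos; s <- sc
  while (p >= 1 && s[len] == refc[p]) {
    s <- c(refc[p], s[-len]); p <- p - 1
    placements[[length(placements) + 1]] <- list(pos = p, s = s)
  }
  # slide right: allowed when the first inserted base equals ref[pos]
  p <- pos; s <- sc
  while (p < L && s[1] == refc[p + 1]) {
    s <- c(s[-1], refc[p + 1]); p <- p + 1
    placements[[length(placements) + 1]] <- list(pos = p, s = s)
  }
  ok <- Filter(function(pl) {
    pl$s[1] == "T" && len >= 2 && pl$s[2] == "A" &&
      pl$pos + 2 <= L && refc[pl$pos + 1] == "T" && refc[pl$pos + 2] == "A"
  }, placements)
  if (length(ok) == 0) return(NULL)
  best <- ok[[which.min(vapply(ok, function(pl) pl$pos, numeric(1)))]]
  list(pos = as.integer(best$pos), seq = paste(best$s, collapse = ""))
}

#' Write an IES catalogue to GFF3
#'
#' One feature per IES of type `internal_eliminated_sequence`, spanning the
#' retained TA on the somatic genome (1-based `p+1 .. p+2`), with attributes
#' `ID`, `ies_seq`, `ies_length`, `support`, and optional `context`,
#' `gene_id`, `flags`. Records failing [validate_ies()] are refused.
#'
#' @param ies A tibble of IES records.
#' @param genome The somatic genome the records refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ies_gff3 <- function(ies, genome, path) {
  validate_ies(ies, genome)
  ies <- normalize_ies(ies)
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(ies)) ies$scaffold else character(),
    ranges = IRanges::IRanges(
      start = if (nrow(ies)) to_gff_coords(ies$pos, ies$pos + 2)$start else integer(),
      end = if (nrow(ies)) to_gff_coords(ies$pos, ies$pos + 2)$end else integer()),
    strand = rep("+", nrow(ies)))
  if (nrow(ies)) {
    S4Vectors::mcols(gr)$source <- "iescan"
    S4Vectors::mcols(gr)$type <- "internal_eliminated_sequence"
    S4Vectors::mcols(gr)$ID <- ies$ies_id
    S4Vectors::mcols(gr)$ies_seq <- ies$seq
    S4Vectors::mcols(gr)$ies_length <- as.character(ies$length)
    S4Vectors::mcols(gr)$support <- as.character(ies$support)
    S4Vectors::mcols(gr)$context <- ies$context
    S4Vectors::mcols(gr)$gene_id <- ies$gene_id
    S4Vectors::mcols(gr)$flags <- ifelse(ies$flags == "", NA_character_, ies$flags)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an IES catalogue from GFF3
#'
#' Inverse of [write_ies_gff3()]; round-tripping restores records exactly.
#'
#' @param path Path to a GFF3 file written by [write_ies_gff3()].
#' @return A tibble of IES records.
#' @export
read_ies_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(empty_ies())
  df <- as.data.frame(gr)
  grab <- function(col, default = NA_character_) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(default, nrow(df))
  }
  tibble(
    ies_id = grab("ID"),
    scaffold = as.character(df$seqnames),
    pos = as.integer(from_gff_coords(df$start, df$end)$start),
    seq = grab("ies_seq"),
    length = as.integer(grab("ies_length")),
    context = grab("context"),
    gene_id = grab("gene_id"),
    support = as.integer(grab("support", "1")),
    flags = dplyr::coalesce(grab("flags"), "")
  ) %>% arrange(.data$scaffold, .data$pos)
}

# Canonical column set for an IES catalogue tibble.
empty_ies <- function() {
  tibble(ies_id = character(), scaffold = character(), pos = integer(),
         seq = character(), length = integer(), context = character(),
         gene_id = character(), support = integer(), flags = character())
}

# Fill optional columns with defaults and order columns/rows.
normalize_ies <- function(ies) {
  ies <- as_tibble(ies)
  n <- nrow(ies)
  if (!"length" %in% names(ies)) ies$length <- nchar(ies$seq)
  if (!"ies_id" %in% names(ies)) {
    ies$ies_id <- sprintf("IES.%s.%d", ies$scaffold, ies$pos)
  }
  if (!"context" %in% names(ies)) ies$context <- NA_character_
  if (!"gene_id" %in% names(ies)) ies$gene_id <- NA_character_
  if (!"support" %in% names(ies)) ies$support <- 1L
  if (!"flags" %in% names(ies)) ies$flags <- ""
  ies$pos <- as.integer(ies$pos)
  ies$length <- as.integer(ies$length)
  ies$support <- as.integer(ies$support)
  ies[, names(empty_ies())] %>% arrange(.data$scaffold, .data$pos)
}

#' Read a plain-text SAM file (header optional, columns 1-6 required)
#'
#' Only the fields the toolkit needs are kept. Unmapped records (flag bit
#' 0x4, `*` reference or `*` CIGAR) are dropped. CIGAR strings are parsed
#' with the usual `M/I/D/S/H/=/X` operations; `clip_left`/`clip_right` are
#' the terminal soft-clip lengths.
#'
#' @param path Path to a SAM file.
#' @return A tibble: `qname`, `flag`, `scaffold`, `start` (0-based),
#'   `end` (0-based exclusive), `cigar`, `strand`, `clip_left`, `clip_right`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(qname = character(), flag = integer(), scaffold = character(),
                  start = integer(), end = integer(), cigar = character(),
                  strand = character(), clip_left = integer(),
                  clip_right = integer()))
  }
  fields <- stringr::str_split_fixed(lines, "\t", 7)
  if (any(fields[, 6] == "")) abort("SAM record with fewer than 6 columns")
  tbl <- tibble(
    qname = fields[, 1],
    flag = as.integer(fields[, 2]),
    scaffold = fields[, 3],
    pos1 = as.integer(fields[, 4]),
    cigar = fields[, 6]
  )
  mapped <- bitwAnd(tbl$flag, 4L) == 0L & tbl$scaffold != "*" & tbl$cigar != "*"
  tbl <- tbl[mapped, ]
  if (nrow(tbl) == 0) return(read_sam_empty())
  alignments_from_cigar(tbl)
}

read_sam_empty <- function() {
  tibble(qname = character(), flag = integer(), scaffold = character(),
         start = integer(), end = integer(), cigar = character(),
         strand = character(), clip_left = integer(), clip_right = integer())
}

# Derive start/end/clips from 1-based pos + CIGAR; shared by read_sam and the
# simulator (which builds the tibble directly).
alignments_from_cigar <- function(tbl) {
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(tbl$cigar)
  ops <- GenomicAlignments::explodeCigarOps(tbl$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(tbl$cigar)
  clip_l <- mapply(function(o, l) {
    i <- if (length(o) && o[1] == "H") 2L else 1L
    if (length(o) >= i && o[i] == "S") l[i] else 0L
  }, ops, lens)
  clip_r <- mapply(function(o, l) {
    n <- length(o)
    i <- if (n && o[n] == "H") n - 1L else n
    if (i >= 1 && o[i] == "S") l[i] else 0L
  }, ops, lens)
  tibble(
    qname = tbl$qname,
    flag = tbl$flag,
    scaffold = tbl$scaffold,
    start = tbl$pos1 - 1L,
    end = tbl$pos1 - 1L + as.integer(refw),
    cigar = tbl$cigar,
    strand = ifelse(bitwAnd(tbl$flag, 16L) > 0L, "-", "+"),
    clip_left = as.integer(clip_l),
    clip_right = as.integer(clip_r)
  )
}

#' Write alignments to a plain-text SAM file
#'
#' @param alignments A tibble with `qname`, `flag`, `scaffold`, `start`
#'   (0-based) and `cigar` columns (as produced by [simulate_reads_sam()]).
#' @param genome The reference the alignments refer to (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), Biostrings::width(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                  alignments$qname, alignments$flag, alignments$scaffold,
                  alignments$start + 1L, alignments$cigar)
  writeLines(c(hdr, body), path)
  invisible(path)
}
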