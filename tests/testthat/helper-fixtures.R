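# Shared fixtures, built in code at test time.

write_tmp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(records), function(n) {
    c(paste0(">", n), records[[n]])
  })), path)
  path
}

# Independent brute-force oracle for leftmost TA canonicalization: rebuild
# the germline locus, then try every placement exhaustively.
brute_canonicalize <- function(ref, pos, seq) {
  germ <- paste0(substr(ref, 1, pos), seq,
                 substr(ref, pos + 1, nchar(ref)))
  len <- nchar(seq)
  L <- nchar(ref)
  for (p in 0:L) {
    cand <- substr(germ, p + 1, p + len)
    rebuilt <- paste0(substr(ref, 1, p), cand,
                      substr(ref, p + 1, nchar(ref)))
    if (rebuilt == germ &&
        substr(cand, 1, 2) == "TA" &&
        p + 2 <= L && substr(ref, p + 1, p + 2) == "TA") {
      return(list(pos = p, seq = cand))
    }
  }
  NULL
}

random_seq <- function(n, gc = 0.3) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A small simulated dataset shared by several test files (cached per run).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 421, genome_length = 60000, n_scaffolds = 2,
                        n_ies = 40)
      cache <<- simulate_ies_dataset(cfg)
    }
    cache
  }
})
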