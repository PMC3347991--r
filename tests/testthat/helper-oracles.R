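# Independent oracles and shared fixtures for the test suite.

# naive homology oracle: Hamming distance of every full-length placement on
# both strands, written without any of the package's scanning machinery
naive_hits <- function(transcript_seq, transcript_id, reference,
                       max_mismatch = 2) {
  n <- nchar(transcript_seq)
  rows <- list()
  for (r in seq_len(nrow(reference))) {
    pat <- strsplit(reference$mature[r], "")[[1]]
    k <- length(pat)
    if (k > n) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") transcript_seq else revcomp_rna(transcript_seq)
      sc <- strsplit(s, "")[[1]]
      for (off in 0:(n - k)) {
        mm <- sum(sc[(off + 1):(off + k)] != pat)
        if (mm <= max_mismatch) {
          start <- if (strand == "+") off else n - off - k
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = reference$id[r], transcript_id = transcript_id,
            start = start, end = start + k, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$transcript_id, out$start, out$strand, out$mirna_id), ,
      drop = FALSE]
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

as_transcripts <- function(ids, seqs) {
  out <- data.frame(id = ids, sequence = seqs, length = nchar(seqs),
                    has_n = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

# independent dot-bracket parser for hand-built structures
.pairs_from_db_test <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pr <- rep(-1L, length(ch))
  st <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") st <- c(st, i)
    else if (ch[i] == ")") {
      j <- st[length(st)]; st <- st[-length(st)]
      pr[i] <- j - 1L; pr[j] <- i - 1L
    }
  }
  pr
}

# memoized end-to-end discovery on the default synthetic world (shared by
# the pipeline tests and the acceptance suite; folding dominates runtime)
.e2e_cache <- new.env(parent = emptyenv())
default_e2e <- function() {
  if (is.null(.e2e_cache$res)) {
    sim <- make_transcriptome(default_sim_spec())
    res <- suppressMessages(run_discovery(sim$transcripts, sim$reference))
    .e2e_cache$res <- list(sim = sim, res = res)
  }
  .e2e_cache$res
}
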