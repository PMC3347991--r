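# Homology search: full-length ungapped placement of known mature miRNAs on
# both strands of a transcript, Hamming distance <= max_mismatch.
#
# The decisive filter is the mismatch bound, implemented exactly.  Score and
# E-value follow a megablast-like model: score = 2*matches - 3*mismatches,
# E = K*m*n*exp(-lambda*S) (Karlin-Altschul) with packaged constants; both
# are configurable because the original BLASTN parameters are unrecorded.

#' Homology search scoring constants
#'
#' @param match reward per matching base.
#' @param mismatch penalty per mismatching base (positive number).
#' @param K,lambda Karlin-Altschul constants for the E-value.
#' @return list of constants used by \code{\link{find_hits}}.
#' @export
homology_params <- function(match = 2, mismatch = 3, K = 0.71,
                            lambda = 1.33) {
  list(match = match, mismatch = mismatch, K = K, lambda = lambda)
}

# mismatch count of `pat` at every offset of `txt` (both split char vectors);
# vectorized over offsets: O(|pat|) vector ops.
.hamming_profile <- function(txt, pat) {
  n <- length(txt); k <- length(pat)
  n_off <- n - k + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (i in seq_len(k)) {
    mm <- mm + (txt[i:(i + n_off - 1L)] != pat[i])
  }
  mm
}

#' Find homology hits of known matures in one transcript
#'
#' Scans every full-length ungapped placement of each reference mature on the
#' + strand and on the reverse complement of the transcript, keeping
#' placements with at most \code{max_mismatch} mismatching bases.  Minus
#' strand hits are reported in + strand coordinates.  Placements overlapping
#' an \code{N} never match (N pairs nothing).
#'
#' @param transcript one-row \code{transcript_set} slice, or a list/row with
#'   \code{id} and \code{sequence}.
#' @param reference data.frame of known matures
#'   (\code{\link{read_reference_mirnas}} layout).
#' @param max_mismatch maximum Hamming distance (default 2).
#' @param params scoring constants from \code{\link{homology_params}}.
#' @return data.frame of hits: \code{mirna_id}, \code{transcript_id},
#'   \code{start}, \code{end} (0-based half-open, + strand), \code{strand},
#'   \code{mismatches}, \code{score}, \code{e_value}; sorted by
#'   (transcript_id, start, strand, mirna_id).
#' @export
find_hits <- function(transcript, reference, max_mismatch = 2,
                      params = homology_params()) {
  if (is.null(reference) || nrow(reference) == 0L)
    stop("empty reference set", call. = FALSE)
  seq_fwd <- transcript$sequence
  id <- transcript$id
  n <- nchar(seq_fwd)
  fwd <- strsplit(seq_fwd, "")[[1]]
  rev <- strsplit(revcomp_rna(seq_fwd), "")[[1]]
  out <- list()
  for (r in seq_len(nrow(reference))) {
    pat <- strsplit(reference$mature[r], "")[[1]]
    k <- length(pat)
    for (str in c("+", "-")) {
      txt <- if (str == "+") fwd else rev
      mm <- .hamming_profile(txt, pat)
      keep <- which(mm <= max_mismatch)
      if (!length(keep)) next
      start_local <- keep - 1L           # 0-based on scanned strand
      start_plus <- if (str == "+") start_local else n - (start_local + k)
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = reference$id[r], transcript_id = id,
        start = start_plus, end = start_plus + k, strand = str,
        mismatches = mm[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    hits <- data.frame(mirna_id = character(0), transcript_id = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0), mismatches = integer(0),
                       score = numeric(0), e_value = numeric(0))
    return(hits)
  }
  hits <- do.call(rbind, out)
  k_len <- hits$end - hits$start
  hits$score <- params$match * (k_len - hits$mismatches) -
    params$mismatch * hits$mismatches
  hits$e_value <- params$K * k_len * n * exp(-params$lambda * hits$score)
  hits <- hits[order(hits$transcript_id, hits$start, hits$strand,
                     hits$mirna_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter homology hits by E-value or score
#'
#' A hit is kept when \code{e_value < e_cut} OR \code{score > score_cut}
#' (strict on both sides); the mismatch bound is already enforced by
#' \code{\link{find_hits}}.
#'
#' @param hits data.frame from \code{\link{find_hits}}.
#' @param e_cut E-value cut (default 1e-2).
#' @param score_cut score cut (default 32).
#' @return filtered hits.
#' @export
filter_hits <- function(hits, e_cut = 1e-2, score_cut = 32) {
  if (nrow(hits) == 0L) return(hits)
  hits[hits$e_value < e_cut | hits$score > score_cut, , drop = FALSE]
}

#' Find hits across a whole transcript set
#'
#' @inheritParams find_hits
#' @param transcripts \code{transcript_set}; records flagged \code{has_n} are
#'   skipped when \code{exclude_n} (mirrors removal of low-quality reads).
#' @param exclude_n drop N-containing transcripts (default TRUE).
#' @return combined hit data.frame.
#' @export
find_hits_all <- function(transcripts, reference, max_mismatch = 2,
                          params = homology_params(), exclude_n = TRUE) {
  if (exclude_n && "has_n" %in% names(transcripts))
    transcripts <- transcripts[!transcripts$has_n, , drop = FALSE]
  min_len <- min(nchar(reference$mature))
  res <- lapply(seq_len(nrow(transcripts)), function(i) {
    if (transcripts$length[i] < min_len) return(NULL)
    find_hits(transcripts[i, ], reference, max_mismatch, params)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(find_hits(list(id = "x", sequence = paste(rep("A", 40),
                                                     collapse = "")),
                     reference, -1, params))  # empty frame w/ right columns
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
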