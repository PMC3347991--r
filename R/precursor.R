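# Candidate precursor windows around homology hits, and overlap-merging of
# transcript fragments guided by a shared known precursor.

#' Extract candidate precursor windows around a homology hit
#'
#' For every (left, right) flank pair on the grid
#' \code{seq(flank_min, flank_max, step)} the window is clipped to the
#' transcript and strand-resolved so the mature reads 5'->3' inside the
#' returned sequence; duplicate clipped windows are removed.  Flanks are in
#' mature orientation: for a minus-strand hit the 5' flank extends toward
#' higher + strand coordinates.
#'
#' @param transcript row with \code{id}, \code{sequence}.
#' @param hit one-row hit data.frame from \code{\link{find_hits}}.
#' @param flank_min,flank_max,step flank grid in nt (defaults 20, 280, 20).
#' @return data.frame of windows: \code{transcript_id}, \code{strand},
#'   \code{win_start}, \code{win_end} (0-based half-open on + strand),
#'   \code{sequence} (strand-resolved), \code{mature_offset} (0-based offset
#'   of the mature within \code{sequence}).
#' @export
extract_windows <- function(transcript, hit, flank_min = 20, flank_max = 280,
                            step = 20) {
  n <- nchar(transcript$sequence)
  if (hit$start < 0 || hit$end > n)
    stop("hit outside transcript ", transcript$id, call. = FALSE)
  grid <- seq(flank_min, flank_max, by = step)
  combos <- expand.grid(left = grid, right = grid)
  if (hit$strand == "+") {
    ws <- pmax(0L, hit$start - combos$left)
    we <- pmin(n, hit$end + combos$right)
  } else {
    ws <- pmax(0L, hit$start - combos$right)
    we <- pmin(n, hit$end + combos$left)
  }
  keep <- !duplicated(paste(ws, we))
  ws <- as.integer(ws[keep]); we <- as.integer(we[keep])
  seqs <- substring(transcript$sequence, ws + 1L, we)
  if (hit$strand == "-") {
    seqs <- revcomp_rna(seqs)
    mat_off <- we - hit$end
  } else {
    mat_off <- hit$start - ws
  }
  data.frame(transcript_id = transcript$id, strand = hit$strand,
             win_start = ws, win_end = we, sequence = seqs,
             mature_offset = as.integer(mat_off), stringsAsFactors = FALSE)
}

#' Merge overlapping transcript fragments along a guide precursor
#'
#' Fragments are projected onto a common (known-precursor) coordinate system
#' via their guide offsets; fragments whose projected intervals overlap by at
#' least \code{min_overlap} nt and agree exactly over the whole overlap are
#' spliced into one longer sequence.  Any disagreement in an overlap aborts
#' the merge for that pair (conservative no-merge).
#'
#' @param fragments data.frame with \code{id}, \code{sequence}.
#' @param guide_offsets integer vector (one per fragment): 0-based start of
#'   each fragment on the guide precursor.
#' @param min_overlap minimum projected overlap in nt (default 20).
#' @return list with \code{merged} (data.frame of resulting sequences) and
#'   \code{status} (\code{"merged"}, \code{"partial"} or \code{"unmerged"}).
#' @export
merge_overlapping <- function(fragments, guide_offsets, min_overlap = 20) {
  stopifnot(nrow(fragments) == length(guide_offsets))
  if (nrow(fragments) < 2L)
    stop("need >= 2 fragments to merge", call. = FALSE)
  ord <- order(guide_offsets, -nchar(fragments$sequence))
  frag <- fragments[ord, , drop = FALSE]
  off <- guide_offsets[ord]
  pieces <- list(list(seq = frag$sequence[1], start = off[1],
                      ids = frag$id[1]))
  merged_any <- FALSE
  for (i in seq_len(nrow(frag))[-1]) {
    cur <- pieces[[length(pieces)]]
    s <- frag$sequence[i]; st <- off[i]
    cur_end <- cur$start + nchar(cur$seq)
    ov <- cur_end - st
    if (ov >= min_overlap && ov <= nchar(s) && ov <= nchar(cur$seq)) {
      a <- substring(cur$seq, nchar(cur$seq) - ov + 1L, nchar(cur$seq))
      b <- substring(s, 1L, ov)
      if (identical(a, b)) {
        cur$seq <- paste0(cur$seq, substring(s, ov + 1L))
        cur$ids <- c(cur$ids, frag$id[i])
        pieces[[length(pieces)]] <- cur
        merged_any <- TRUE
        next
      }
    } else if (ov > nchar(s) && st >= cur$start) {
      # fragment fully contained: must agree in place
      a <- substring(cur$seq, st - cur$start + 1L, st - cur$start + nchar(s))
      if (identical(a, s)) {
        cur$ids <- c(cur$ids, frag$id[i])
        pieces[[length(pieces)]] <- cur
        merged_any <- TRUE
        next
      }
    }
    pieces[[length(pieces) + 1L]] <- list(seq = s, start = st,
                                          ids = frag$id[i])
  }
  merged <- data.frame(
    id = vapply(pieces, function(p) paste(p$ids, collapse = "+"),
                character(1)),
    sequence = vapply(pieces, `[[`, character(1), "seq"),
    guide_start = vapply(pieces, function(p) as.integer(p$start),
                         integer(1)),
    stringsAsFactors = FALSE)
  status <- if (!merged_any) "unmerged"
            else if (length(pieces) == 1L) "merged" else "partial"
  if (status == "unmerged")
    warning("no fragments could be merged (no consistent overlap >= ",
            min_overlap, " nt)", call. = FALSE)
  list(merged = merged, status = status)
}
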