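# Precursor hairpin criteria: MFE, AMFE/MFEI, A+U content, single-arm
# mature placement and mature:miRNA* duplex mismatches.
#
# Threshold strictness follows the criteria sentence literally: MFE <= -15
# inclusive, MFEI > 0.5 strict, 30 <= A+U% <= 70 inclusive, duplex
# mismatches < 6 strict.  G:U counts as paired in the duplex (it is a
# structural pair), unlike in target scoring.

#' Criteria configuration for precursor classification
#'
#' @param mfe_max maximum folding energy in kcal/mol (pass when
#'   \code{mfe <= mfe_max}); default -15.
#' @param mfei_min minimum MFEI, strict (\code{mfei > mfei_min}); default 0.5.
#' @param au_min_pct,au_max_pct inclusive A+U content band; default 30-70.
#' @param max_duplex_mismatch exclusive bound on mature:star mismatches
#'   (pass when \code{mismatches < max_duplex_mismatch}); default 6.
#' @param require_single_arm mature must sit wholly in one arm; default TRUE.
#' @return list of thresholds.
#' @export
criteria_config <- function(mfe_max = -15, mfei_min = 0.5, au_min_pct = 30,
                            au_max_pct = 70, max_duplex_mismatch = 6,
                            require_single_arm = TRUE) {
  stopifnot(au_min_pct < au_max_pct)
  list(mfe_max = mfe_max, mfei_min = mfei_min, au_min_pct = au_min_pct,
       au_max_pct = au_max_pct, max_duplex_mismatch = max_duplex_mismatch,
       require_single_arm = require_single_arm)
}

#' Adjusted MFE and minimal folding free energy index
#'
#' \code{AMFE = |MFE| * 100 / length} (kcal/mol per 100 nt) and
#' \code{MFEI = AMFE / (100 - AU\%)}, i.e. AMFE over the G+C percentage.
#'
#' @param mfe folding energy, kcal/mol (<= 0).
#' @param length precursor length, nt.
#' @param au_pct A+U content of the precursor, percent.
#' @return list with \code{amfe} and \code{mfei}.
#' @export
compute_mfei <- function(mfe, length, au_pct) {
  stopifnot(mfe <= 0, length > 0, au_pct >= 0)
  if (any(au_pct >= 100))
    stop("undefined MFEI: A+U content is 100% (no G+C)", call. = FALSE)
  amfe <- abs(mfe) * 100 / length
  list(amfe = amfe, mfei = amfe / (100 - au_pct))
}

#' A+U content of a sequence, in percent
#' @param sequence RNA string.
#' @return percent of A and U bases.
#' @export
au_content <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  100 * sum(ch %in% c("A", "U")) / length(ch)
}

#' Locate the mature:miRNA* duplex in a folded window
#'
#' The mature must sit wholly within one arm: any mature position inside a
#' terminal (hairpin) loop, or mature partners on both sides of the mature
#' (pairing across the loop in both directions), is a rejection.  The star
#' is the contiguous stretch pairing with the mature, extended by a 2-nt 3'
#' overhang.  Duplex mismatches count every mature position not paired into
#' the star span plus every star-span position not paired to the mature
#' (bulged nucleotides on either strand count 1 each).
#'
#' @param window one-row window data.frame (\code{\link{extract_windows}}),
#'   or a list with \code{sequence} and \code{mature_offset}; mature length
#'   taken from \code{mature_len} if present else from \code{attr}.
#' @param struct \code{rna_structure} for \code{window$sequence}.
#' @param mature_len mature length in nt.
#' @return list with \code{ok}, and on success \code{arm} ("5p"/"3p"),
#'   \code{star}, \code{star_start}, \code{star_end},
#'   \code{duplex_mismatches}; on rejection \code{reason}.
#' @export
locate_duplex <- function(window, struct, mature_len) {
  pr <- struct$pairs
  n <- length(pr)
  m0 <- window$mature_offset          # 0-based
  m1 <- m0 + mature_len               # half-open
  if (m1 > n) stop("mature extends beyond window", call. = FALSE)
  mi <- (m0 + 1L):m1                  # 1-based indices of mature
  partners <- pr[mi]                  # 0-based partners, -1 unpaired
  paired <- partners >= 0L
  if (!any(paired))
    return(list(ok = FALSE, reason = "no-stem"))
  # hairpin (terminal) loops: maximal unpaired runs flanked by a pair (i,j)
  # with the run exactly spanning (i, j)
  in_loop <- rep(FALSE, n)
  ip <- which(pr >= 0L)
  for (i in ip) {
    j <- pr[i] + 1L
    if (j > i && all(pr[(i + 1L):(j - 1L)] < 0L))
      in_loop[(i + 1L):(j - 1L)] <- TRUE
  }
  if (any(in_loop[mi]))
    return(list(ok = FALSE, reason = "mature-in-loop"))
  up <- partners[paired] + 1L          # 1-based partner positions
  if (any(up > max(mi)) && any(up < min(mi)))
    return(list(ok = FALSE, reason = "straddles-loop"))
  if (any(up >= min(mi) & up <= max(mi)))
    return(list(ok = FALSE, reason = "self-pairing"))
  arm <- if (all(up > max(mi))) "5p" else "3p"
  star_lo <- min(up)                   # 1-based
  star_hi <- min(n, max(up) + 2L)      # 2-nt 3' overhang
  star_span <- star_lo:star_hi
  star <- substring(struct$sequence, star_lo, star_hi)
  m_unpaired <- sum(!paired) +
    sum(paired & (partners + 1L < star_lo | partners + 1L > star_hi))
  core <- star_lo:max(up)              # star core (without the overhang)
  star_bulged <- sum(!(pr[core] + 1L) %in% mi)
  list(ok = TRUE, arm = arm, star = star,
       star_start = star_lo - 1L, star_end = star_hi,
       duplex_mismatches = as.integer(m_unpaired + star_bulged))
}

#' Evaluate a folded candidate window against the precursor criteria
#'
#' Failures are recorded as data (pass flags plus reasons), not errors.
#'
#' @param window one-row window data.frame with \code{sequence},
#'   \code{mature_offset}.
#' @param struct \code{rna_structure} of the window sequence.
#' @param mature_len mature length, nt.
#' @param cfg thresholds from \code{\link{criteria_config}}.
#' @return list (class \code{precursor_candidate}) with the window, the
#'   structure, \code{mfe}, \code{amfe}, \code{mfei}, \code{au_pct},
#'   \code{arm}, \code{star}, \code{duplex_mismatches}, \code{pass_flags},
#'   \code{pass}, \code{reasons}.
#' @export
evaluate_candidate <- function(window, struct, mature_len,
                               cfg = criteria_config()) {
  au <- au_content(window$sequence)
  ix <- compute_mfei(struct$mfe, nchar(window$sequence), au)
  dup <- locate_duplex(window, struct, mature_len)
  flags <- c(
    mfe = struct$mfe <= cfg$mfe_max,
    mfei = ix$mfei > cfg$mfei_min,
    au = au >= cfg$au_min_pct && au <= cfg$au_max_pct,
    duplex = isTRUE(dup$ok) &&
      dup$duplex_mismatches < cfg$max_duplex_mismatch,
    arm = if (cfg$require_single_arm) isTRUE(dup$ok) else TRUE)
  reasons <- names(flags)[!flags]
  if (!isTRUE(dup$ok) && !is.null(dup$reason))
    reasons <- unique(c(reasons, dup$reason))
  structure(list(
    window = window, structure = struct, mfe = struct$mfe, amfe = ix$amfe,
    mfei = ix$mfei, au_pct = au,
    arm = if (isTRUE(dup$ok)) dup$arm else NA_character_,
    star = if (isTRUE(dup$ok)) dup$star else NA_character_,
    duplex_mismatches = if (isTRUE(dup$ok)) dup$duplex_mismatches
                        else NA_integer_,
    pass_flags = flags, pass = all(flags), reasons = reasons),
    class = "precursor_candidate")
}

#' Select the best passing candidate for one hit
#'
#' Among passing candidates: highest MFEI, ties broken by shorter window,
#' then smaller window start.
#'
#' @param candidates list of \code{precursor_candidate} objects sharing one
#'   homology hit.
#' @return the selected candidate, or \code{NULL} if none passes.
#' @export
select_best <- function(candidates) {
  if (!length(candidates)) return(NULL)
  passing <- Filter(function(x) isTRUE(x$pass), candidates)
  if (!length(passing)) return(NULL)
  key <- vapply(passing, function(x) {
    c(-x$mfei, nchar(x$window$sequence), x$window$win_start)
  }, numeric(3))
  ord <- order(key[1, ], key[2, ], key[3, ])
  passing[[ord[1]]]
}
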