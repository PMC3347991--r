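# miRNA target prediction with the penalizing-score scheme:
# per miRNA position, Watson-Crick pair = 0, G:U wobble = 0.5, mismatch = 1,
# gap = 2; penalties doubled in the seed (miRNA positions 2-7, 1-based from
# the 5' end).  Sites scoring <= 3 are putative targets.  At most one bulge
# (max_gaps = 1) keeps the cut-off meaningful.

.base_idx <- c(A = 1L, C = 2L, G = 3L, U = 4L)

# penalty of miRNA base (row) opposite target base (col)
.pen_matrix <- local({
  m <- matrix(1, 4, 4, dimnames = list(names(.base_idx), names(.base_idx)))
  m["A", "U"] <- 0; m["U", "A"] <- 0; m["G", "C"] <- 0; m["C", "G"] <- 0
  m["G", "U"] <- 0.5; m["U", "G"] <- 0.5
  m
})

.seed_weight <- function(k, seed = c(2, 7)) {
  w <- rep(1, k)
  w[seq(seed[1], min(seed[2], k))] <- 2
  w
}

# alignment map: for gap_type/gap_pos, target offset (from site 3' end,
# 1-based) paired with each miRNA position p; NA = miRNA bulge
.align_map <- function(k, gap_type, gap_pos) {
  if (gap_type == "none") return(seq_len(k))
  if (gap_type == "target_bulge") {
    # one extra target nt between miRNA positions gap_pos and gap_pos + 1
    off <- seq_len(k)
    off[off > gap_pos] <- off[off > gap_pos] + 1L
    return(off)
  }
  # mirna_bulge: miRNA position gap_pos unaligned
  off <- integer(k)
  off[seq_len(k) < gap_pos] <- seq_len(k)[seq_len(k) < gap_pos]
  off[gap_pos] <- NA_integer_
  idx <- seq_len(k) > gap_pos
  off[idx] <- seq_len(k)[idx] - 1L
  off
}

#' Penalizing score of a miRNA:site duplex
#'
#' The miRNA (5'->3') is aligned antiparallel to the site (5'->3' on the
#' transcript); with \code{|site| != |mirna|} the single best bulge
#' placement is used.  Gap penalties are doubled when the bulge falls in
#' the seed block.
#'
#' @param mirna mature RNA string (5'->3').
#' @param site target site RNA string (5'->3').
#' @param max_gaps maximum length difference / bulges (default 1).
#' @param gap_penalty per-gap penalty (default 2).
#' @return list with \code{score}, \code{gap_type}
#'   (\code{none/target_bulge/mirna_bulge}), \code{gap_pos}.
#' @export
score_duplex <- function(mirna, site, max_gaps = 1, gap_penalty = 2) {
  k <- nchar(mirna)
  L <- nchar(site)
  if (abs(L - k) > max_gaps)
    stop("site length differs from miRNA by more than max_gaps",
         call. = FALSE)
  m <- .base_idx[strsplit(mirna, "")[[1]]]
  s <- rev(.base_idx[strsplit(site, "")[[1]]])  # s[q] = q-th nt from 3' end
  w <- .seed_weight(k)
  pen_at <- function(p, q) .pen_matrix[m[p], s[q]] * w[p]
  best <- list(score = Inf, gap_type = "none", gap_pos = NA_integer_)
  cand <- if (L == k) {
    list(list(type = "none", pos = NA_integer_))
  } else if (L == k + 1) {
    lapply(seq_len(k - 1), function(g) list(type = "target_bulge", pos = g))
  } else {
    lapply(seq_len(k), function(g) list(type = "mirna_bulge", pos = g))
  }
  for (cd in cand) {
    off <- .align_map(k, cd$type, cd$pos)
    sc <- 0
    for (p in seq_len(k)) {
      if (is.na(off[p])) next
      sc <- sc + pen_at(p, off[p])
    }
    if (cd$type != "none") {
      gpos <- cd$pos
      in_seed <- if (cd$type == "mirna_bulge") gpos >= 2 && gpos <= 7
                 else gpos >= 2 && gpos < 7
      sc <- sc + gap_penalty * (if (in_seed) 2 else 1)
    }
    if (sc < best$score)
      best <- list(score = sc, gap_type = cd$type, gap_pos = cd$pos)
  }
  best
}

#' Scan transcripts for miRNA target sites
#'
#' Every window within one bulge of the miRNA length is scored; windows at
#' or below \code{score_cut} are kept, overlapping windows for the same
#' miRNA collapsed to the minimum-score placement; output sorted by score
#' then coordinate.
#'
#' @param mirna named list/row with \code{id} and \code{mature}, or a bare
#'   RNA string.
#' @param transcripts \code{transcript_set}.
#' @param score_cut maximum penalizing score (default 3.0).
#' @param max_gaps maximum bulges per site (default 1).
#' @return data.frame of target sites: \code{mirna_id},
#'   \code{transcript_id}, \code{site_start}, \code{site_end} (0-based
#'   half-open), \code{score}, \code{gap_type}, \code{gap_pos},
#'   \code{cleavage_pos}, \code{cleavage_ok}, \code{site}.
#' @export
scan_targets <- function(mirna, transcripts, score_cut = 3.0, max_gaps = 1) {
  if (is.character(mirna) && length(mirna) == 1L)
    mirna <- list(id = "miRNA", mature = mirna)
  k <- nchar(mirna$mature)
  m <- .base_idx[strsplit(mirna$mature, "")[[1]]]
  w <- .seed_weight(k)
  out <- list()
  for (ti in seq_len(nrow(transcripts))) {
    txt <- .base_idx[strsplit(transcripts$sequence[ti], "")[[1]]]
    txt[is.na(txt)] <- 0L                        # N: pairs nothing
    n <- length(txt)
    pen_prof <- function(L, off) {
      # score for every site end e in [L, n]; off[p] = offset from e
      ends <- L:n
      if (!length(ends) || n < L) return(numeric(0))
      sc <- numeric(length(ends))
      for (p in seq_len(k)) {
        if (is.na(off[p])) next
        tb <- txt[ends - off[p] + 1L]
        pp <- ifelse(tb == 0L, 1, .pen_matrix[cbind(m[p], pmax(tb, 1L))])
        sc <- sc + pp * w[p]
      }
      sc
    }
    cands <- list(list(L = k, type = "none", pos = NA_integer_, extra = 0))
    if (max_gaps >= 1 && n >= k + 1) {
      for (g in seq_len(k - 1))
        cands[[length(cands) + 1L]] <- list(
          L = k + 1L, type = "target_bulge", pos = g,
          extra = 2 * (if (g >= 2 && g < 7) 2 else 1))
      for (g in seq_len(k))
        cands[[length(cands) + 1L]] <- list(
          L = k - 1L, type = "mirna_bulge", pos = g,
          extra = 2 * (if (g >= 2 && g <= 7) 2 else 1))
    }
    hits <- list()
    for (cd in cands) {
      if (n < cd$L) next
      off <- .align_map(k, cd$type, cd$pos)
      sc <- pen_prof(cd$L, off) + cd$extra
      keep <- which(sc <= score_cut)
      if (!length(keep)) next
      ends <- (cd$L:n)[keep]
      hits[[length(hits) + 1L]] <- data.frame(
        site_start = ends - cd$L, site_end = ends, score = sc[keep],
        gap_type = cd$type, gap_pos = cd$pos, stringsAsFactors = FALSE)
    }
    if (!length(hits)) next
    h <- do.call(rbind, hits)
    h <- h[order(h$score, h$site_start, h$site_end - h$site_start), ,
           drop = FALSE]
    chosen <- h[0, ]
    for (r in seq_len(nrow(h))) {
      if (!nrow(chosen) ||
          all(h$site_start[r] >= chosen$site_end |
              h$site_end[r] <= chosen$site_start)) {
        chosen <- rbind(chosen, h[r, ])
      }
    }
    chosen$mirna_id <- mirna$id
    chosen$transcript_id <- transcripts$id[ti]
    chosen$site <- substring(transcripts$sequence[ti],
                             chosen$site_start + 1L, chosen$site_end)
    out[[length(out) + 1L]] <- chosen
  }
  if (!length(out))
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      score = numeric(0), gap_type = character(0),
                      gap_pos = integer(0), cleavage_pos = integer(0),
                      cleavage_ok = logical(0), site = character(0)))
  res <- do.call(rbind, out)
  cl <- lapply(seq_len(nrow(res)), function(i)
    predict_cleavage(res[i, ], mirna$mature))
  res$cleavage_pos <- vapply(cl, `[[`, integer(1), "pos")
  res$cleavage_ok <- vapply(cl, `[[`, logical(1), "ok")
  res <- res[order(res$score, res$transcript_id, res$site_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  cols <- c("mirna_id", "transcript_id", "site_start", "site_end", "score",
            "gap_type", "gap_pos", "cleavage_pos", "cleavage_ok", "site")
  res[, cols]
}

#' Predicted cleavage position for a target site
#'
#' The transcript coordinate of the bond between the target nucleotides
#' pairing miRNA positions 10 and 11 (the canonical slicing register);
#' returned as the 0-based coordinate of the nucleotide 5' of the cleaved
#' bond.  A bulge between positions 10 and 11 flags the site instead.
#'
#' @param site one-row site data.frame from \code{\link{scan_targets}}.
#' @param mirna mature RNA string.
#' @return list with \code{pos} (0-based transcript coordinate, NA when
#'   flagged) and \code{ok}.
#' @export
predict_cleavage <- function(site, mirna) {
  k <- nchar(mirna)
  if (k < 11) return(list(pos = NA_integer_, ok = FALSE))
  off <- .align_map(k, site$gap_type, site$gap_pos)
  o10 <- off[10]; o11 <- off[11]
  if (is.na(o10) || is.na(o11) || (o11 - o10) != 1L)
    return(list(pos = NA_integer_, ok = FALSE))
  list(pos = as.integer(site$site_end - o11), ok = TRUE)
}

#' Render a miRNA:target alignment as a 3-line text block
#'
#' Top line: target site 5'->3'; middle: match symbols (\code{|}
#' Watson-Crick, \code{o} G:U wobble, space mismatch); bottom: miRNA
#' 3'->5'.  Bulged nucleotides get a \code{-} on the opposite strand.
#'
#' @param site one-row site data.frame from \code{\link{scan_targets}}.
#' @param mirna mature RNA string (5'->3').
#' @return character scalar (three lines joined by newlines).
#' @export
render_alignment <- function(site, mirna) {
  k <- nchar(mirna)
  mc <- strsplit(mirna, "")[[1]]
  sc <- strsplit(site$site, "")[[1]]
  L <- length(sc)
  off <- .align_map(k, site$gap_type, site$gap_pos)
  # build columns in miRNA 5'->3' order (target 3'->5'), then reverse
  top <- character(0); mid <- character(0); bot <- character(0)
  sym <- function(mb, tb) {
    p <- .pen_matrix[mb, tb]
    if (p == 0) "|" else if (p == 0.5) "o" else " "
  }
  srev <- rev(sc)
  for (p in seq_len(k)) {
    if (site$gap_type == "target_bulge" && p == site$gap_pos + 1L) {
      q <- off[p] - 1L  # the bulged target nt from the 3' end
      top <- c(top, srev[q]); mid <- c(mid, " "); bot <- c(bot, "-")
    }
    if (is.na(off[p])) {  # miRNA bulge
      top <- c(top, "-"); mid <- c(mid, " "); bot <- c(bot, mc[p])
    } else {
      top <- c(top, srev[off[p]])
      mid <- c(mid, sym(mc[p], srev[off[p]]))
      bot <- c(bot, mc[p])
    }
  }
  paste(
    paste0("5' ", paste(rev(top), collapse = ""), " 3'  (target)"),
    paste0("   ", paste(rev(mid), collapse = "")),
    paste0("3' ", paste(rev(bot), collapse = ""), " 5'  (",
           if (!is.null(site$mirna_id)) site$mirna_id else "miRNA", ")"),
    sep = "\n")
}

#' Re-derive the penalizing score from a rendered match line
#'
#' Counts symbols of the middle alignment line with the penalty table and
#' seed doubling; used as a round-trip check against
#' \code{\link{score_duplex}}.
#'
#' @param alignment text from \code{\link{render_alignment}}.
#' @param k miRNA length.
#' @param gap_in_seed logical: does the bulge (if any) fall in the seed?
#' @return numeric score.
#' @export
score_from_alignment <- function(alignment, k, gap_in_seed = FALSE) {
  lines <- strsplit(alignment, "\n")[[1]]
  mid <- sub("^   ", "", lines[2])
  bot <- sub("^3' ", "", sub(" 5'.*$", "", lines[3]))
  top <- sub("^5' ", "", sub(" 3'.*$", "", lines[1]))
  cols <- rev(seq_len(nchar(mid)))  # miRNA 5'->3'
  midc <- rev(strsplit(mid, "")[[1]])
  topc <- rev(strsplit(top, "")[[1]])
  botc <- rev(strsplit(bot, "")[[1]])
  sc <- 0; p <- 0
  for (i in seq_along(midc)) {
    if (botc[i] == "-") {            # target bulge column
      sc <- sc + 2 * (if (gap_in_seed) 2 else 1)
      next
    }
    p <- p + 1
    if (topc[i] == "-") {            # miRNA bulge column
      sc <- sc + 2 * (if (gap_in_seed) 2 else 1)
      next
    }
    w <- if (p >= 2 && p <= 7) 2 else 1
    sc <- sc + w * switch(midc[i], "|" = 0, "o" = 0.5, 1)
  }
  sc
}
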