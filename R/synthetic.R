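# Synthetic-data generators: transcriptomes with planted precursor
# hairpins, homologous-but-unfoldable decoys, engineered target sites and
# qPCR Ct tables -- every generator deterministic under a fixed seed.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.random_rna <- function(len, au_bias = 0.5) {
  p <- c(A = au_bias / 2, U = au_bias / 2,
         C = (1 - au_bias) / 2, G = (1 - au_bias) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

#' Build a precursor hairpin with a requested duplex-mismatch count
#'
#' Returns \code{mature + loop + star} where the star is the reverse
#' complement of the mature with \code{duplex_mismatches} evenly spread
#' single-nucleotide deletions; each deletion leaves one mature position
#' without a pairing partner, so the folded hairpin carries exactly that
#' many duplex mismatches (bulges count 1 per nucleotide).
#'
#' @param mature RNA string, 18-24 nt.
#' @param duplex_mismatches requested mismatch count (< mature length - 8).
#' @param loop_len terminal loop length, >= 3 nt (default 8).
#' @return list with \code{sequence}, \code{mature_offset} (0),
#'   \code{mature_len}.
#' @export
make_hairpin <- function(mature, duplex_mismatches = 0, loop_len = 8) {
  mature <- normalize_rna(mature)
  k <- nchar(mature)
  if (k < 18 || k > 24) stop("mature must be 18-24 nt", call. = FALSE)
  if (loop_len < 3) stop("loop_len must be >= 3", call. = FALSE)
  if (duplex_mismatches >= k - 8)
    stop("requested mismatches too large for a stable stem", call. = FALSE)
  mch <- strsplit(mature, "")[[1]]
  star <- strsplit(revcomp_rna(mature), "")[[1]]
  if (duplex_mismatches > 0) {
    # Mismatch units: a star substitution opposite a mid-stem mature
    # position makes a 1x1 internal loop (counts 2: one bulged nt on each
    # strand); for odd counts the star nucleotide opposite the mature 5'
    # terminus is dropped, leaving that terminus dangling (counts exactly
    # 1 and cannot be absorbed into a neighboring loop).
    n_sub <- duplex_mismatches %/% 2
    end_del <- duplex_mismatches %% 2 == 1
    nonpair <- c(A = "C", C = "A", G = "A", U = "C")
    if (n_sub > 0) {
      lo <- 6; hi <- k - 5
      pos <- if (n_sub == 1) round((lo + hi) / 2) else
        unique(round(seq(lo, hi, length.out = n_sub)))
      while (length(pos) < n_sub)
        pos <- sort(c(pos, setdiff(lo:hi, pos)[1]))
      for (p in pos) star[k - p + 1] <- nonpair[[mch[p]]]
    }
    if (end_del) star <- star[-k]
  }
  # loop: alternating C/A, unlikely to extend the stem
  loop <- paste(rep(c("C", "A"), length.out = loop_len), collapse = "")
  list(sequence = paste0(mature, loop, paste(star, collapse = "")),
       mature_offset = 0L, mature_len = k)
}

# Altschul-Erikson dinucleotide shuffle (preserves dinucleotide counts)
.dinuc_shuffle <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  if (n < 3) return(seq)
  verts <- unique(s)
  edges <- split(s[-1], s[-n])          # outgoing edge targets per vertex
  last <- s[n]
  repeat {
    # pick a random final edge for each vertex except the terminal one
    fin <- list()
    ok <- TRUE
    for (v in names(edges)) {
      if (v == last) next
      fin[[v]] <- sample(edges[[v]], 1)
    }
    # connectivity: following final edges from every vertex must reach last
    for (v in names(fin)) {
      cur <- v; seen <- character(0)
      while (cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- if (!is.null(fin[[cur]])) fin[[cur]] else last
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  out_edges <- list()
  for (v in names(edges)) {
    e <- edges[[v]]
    if (!is.null(fin[[v]]) && v != last) {
      i <- match(fin[[v]], e)
      e <- e[-i]
      out_edges[[v]] <- c(sample(e), fin[[v]])
    } else {
      out_edges[[v]] <- sample(e)
    }
  }
  res <- character(n)
  res[1] <- s[1]
  ptr <- setNames(rep(1L, length(out_edges)), names(out_edges))
  for (i in 2:n) {
    v <- res[i - 1]
    res[i] <- out_edges[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
  }
  paste(res, collapse = "")
}

#' Default simulation specification
#'
#' The stated world for end-to-end tests: 20 planted precursors (duplex
#' mismatches cycling 0-3, every fourth on the minus strand), 20
#' shuffled-context decoys carrying an intact mature, and 20 background
#' transcripts; transcript lengths 220-320 nt; uniform base composition.
#'
#' @param seed integer seed.
#' @return list (class \code{sim_spec}).
#' @export
default_sim_spec <- function(seed = 20120406) {
  ref <- fixture_reference()
  ref <- ref[!duplicated(ref$mature), ]
  idx <- rep(seq_len(nrow(ref)), length.out = 20)
  planted <- data.frame(
    mirna_id = paste0(ref$id[idx], "_p", seq_len(20)),
    source_id = ref$id[idx],
    mature = ref$mature[idx],
    duplex_mismatches = rep(0:3, length.out = 20),
    loop_len = 8L,
    strand = ifelse(seq_len(20) %% 4 == 0, "-", "+"),
    stringsAsFactors = FALSE)
  decoy_idx <- rep(seq_len(nrow(ref)), length.out = 20)
  structure(list(
    seed = seed,
    n_background = 20L,
    transcript_len = c(220L, 320L),
    au_bias = 0.5,
    planted = planted,
    decoys = data.frame(
      mirna_id = paste0(ref$id[decoy_idx], "_d", seq_len(20)),
      source_id = ref$id[decoy_idx],
      mature = ref$mature[decoy_idx],
      stringsAsFactors = FALSE)),
    class = "sim_spec")
}

#' Generate a synthetic transcriptome with planted ground truth
#'
#' Planted precursor hairpins are embedded at random positions (minus
#' strand plantings as the reverse complement), decoys embed the intact
#' mature in a dinucleotide-shuffled hairpin context (homology preserved,
#' structure destroyed), and background transcripts carry nothing.
#'
#' @param spec \code{sim_spec} from \code{\link{default_sim_spec}}.
#' @return list with \code{transcripts} (\code{transcript_set}),
#'   \code{truth} (data.frame: transcript_id, mirna_id, kind, strand,
#'   mat_start, mat_end), \code{reference} (matures used for planting).
#' @export
make_transcriptome <- function(spec = default_sim_spec()) {
  .with_seed(spec$seed, {
    ids <- character(0); seqs <- character(0)
    truth <- list()
    rlen <- function() sample(spec$transcript_len[1]:spec$transcript_len[2], 1)
    embed <- function(insert, len) {
      if (nchar(insert) > len - 20)
        stop("planted element longer than its transcript", call. = FALSE)
      pos <- sample(10:(len - nchar(insert) - 10), 1)   # 0-based offset
      left <- .random_rna(pos, spec$au_bias)
      right <- .random_rna(len - pos - nchar(insert), spec$au_bias)
      list(seq = paste0(left, insert, right), pos = pos)
    }
    for (i in seq_len(nrow(spec$planted))) {
      p <- spec$planted[i, ]
      hp <- make_hairpin(p$mature, p$duplex_mismatches, p$loop_len)
      ins <- hp$sequence
      if (p$strand == "-") ins <- revcomp_rna(ins)
      e <- embed(ins, rlen())
      id <- sprintf("synth_planted_%02d", i)
      ids <- c(ids, id); seqs <- c(seqs, e$seq)
      k <- nchar(p$mature)
      mat_start <- if (p$strand == "+") e$pos else
        e$pos + nchar(ins) - k            # mature at the far end on '-'
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, mirna_id = p$mirna_id, kind = "planted",
        strand = p$strand, mat_start = mat_start, mat_end = mat_start + k,
        duplex_mismatches = p$duplex_mismatches, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(spec$decoys))) {
      d <- spec$decoys[i, ]
      hp <- make_hairpin(d$mature, 0)
      ctx <- substring(hp$sequence, nchar(d$mature) + 1L)
      ins <- paste0(d$mature, .dinuc_shuffle(ctx))
      e <- embed(ins, rlen())
      id <- sprintf("synth_decoy_%02d", i)
      ids <- c(ids, id); seqs <- c(seqs, e$seq)
      k <- nchar(d$mature)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, mirna_id = d$mirna_id, kind = "decoy",
        strand = "+", mat_start = e$pos, mat_end = e$pos + k,
        duplex_mismatches = NA_integer_, stringsAsFactors = FALSE)
    }
    for (i in seq_len(spec$n_background)) {
      ids <- c(ids, sprintf("synth_bg_%02d", i))
      seqs <- c(seqs, .random_rna(rlen(), spec$au_bias))
    }
    transcripts <- data.frame(id = ids, sequence = seqs,
                              length = nchar(seqs),
                              has_n = FALSE, stringsAsFactors = FALSE)
    class(transcripts) <- c("transcript_set", "data.frame")
    ref <- unique(rbind(
      data.frame(id = spec$planted$source_id, mature = spec$planted$mature,
                 stringsAsFactors = FALSE)))
    ref$family <- vapply(ref$id, family_from_id, character(1))
    ref$species_tag <- "pde"
    list(transcripts = transcripts, truth = do.call(rbind, truth),
         reference = ref[, c("id", "family", "mature", "species_tag")])
  })
}

# deterministic site engineering: modify the perfect complement so the
# duplex scores exactly `target_score` (multiples of 0.5 via one wobble)
.engineer_site <- function(mature, target_score) {
  k <- nchar(mature)
  if (target_score < 0 || (target_score * 2) %% 1 != 0)
    stop("unreachable penalty: ", target_score, call. = FALSE)
  m <- strsplit(mature, "")[[1]]
  site <- strsplit(revcomp_rna(mature), "")[[1]]   # site 5'->3'
  # non-seed, weight-1 positions, keeping 10/11 intact for cleavage
  avail <- setdiff(c(seq(12, k), 8, 9, 1), c(10, 11))
  need_wobble <- (target_score * 2) %% 2 == 1
  rem <- target_score
  if (need_wobble) {
    wp <- avail[m[avail] %in% c("G", "U")]
    if (!length(wp)) stop("no wobble-capable position available",
                          call. = FALSE)
    p <- wp[1]
    site[k - p + 1] <- if (m[p] == "G") "U" else "G"
    avail <- setdiff(avail, p)
    rem <- rem - 0.5
  }
  n_mm <- rem  # integer number of 1.0 mismatches
  if (n_mm > length(avail))
    stop("unreachable penalty: ", target_score, call. = FALSE)
  mm_target <- c(A = "A", C = "C", G = "A", U = "C")
  for (p in head(avail, n_mm)) site[k - p + 1] <- mm_target[[m[p]]]
  paste(site, collapse = "")
}

#' Generate target transcripts with sites of specified penalty
#'
#' Each transcript carries one site engineered (by controlled
#' wobble/mismatch placement outside the seed) to score exactly the
#' intended penalty under \code{\link{score_duplex}}.
#'
#' @param specs data.frame with \code{mirna_id}, \code{mature},
#'   \code{score} (intended penalty; multiples of 0.5).
#' @param seed integer seed.
#' @param transcript_len length of each synthetic mRNA (default 500).
#' @return list with \code{transcripts} (\code{transcript_set}) and
#'   \code{truth} (transcript_id, mirna_id, score, site_start, site_end).
#' @export
make_target_transcripts <- function(specs, seed = 1, transcript_len = 500) {
  .with_seed(seed, {
    ids <- character(0); seqs <- character(0); truth <- list()
    for (i in seq_len(nrow(specs))) {
      sp <- specs[i, ]
      site <- .engineer_site(sp$mature, sp$score)
      pos <- sample(30:(transcript_len - nchar(site) - 30), 1)
      seq <- paste0(.random_rna(pos), site,
                    .random_rna(transcript_len - pos - nchar(site)))
      id <- sprintf("synth_target_%02d", i)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      truth[[i]] <- data.frame(
        transcript_id = id, mirna_id = sp$mirna_id, score = sp$score,
        site_start = pos, site_end = pos + nchar(site),
        stringsAsFactors = FALSE)
    }
    transcripts <- data.frame(id = ids, sequence = seqs,
                              length = nchar(seqs), has_n = FALSE,
                              stringsAsFactors = FALSE)
    class(transcripts) <- c("transcript_set", "data.frame")
    list(transcripts = transcripts, truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic qPCR Ct table with known fold structure
#'
#' Reference-gene Ct is constant (up to noise) across samples; each gene's
#' Ct in the treatment sample is shifted by \code{-log2(fold)} relative to
#' the calibrator, so \code{\link{relative_quant}} recovers the planted
#' folds.
#'
#' @param ct_specs data.frame with \code{gene}, \code{fold}, \code{sd},
#'   \code{replicates}.
#' @param seed integer seed.
#' @param samples two sample names, \code{c(treatment, calibrator)}.
#' @param reference_gene normalizer gene name.
#' @return Ct data.frame (\code{gene}, \code{sample}, \code{replicate},
#'   \code{ct}).
#' @export
make_ct_table <- function(ct_specs, seed = 1,
                          samples = c("needle", "stem"),
                          reference_gene = "5S_rRNA") {
  stopifnot(all(ct_specs$fold > 0), all(ct_specs$sd >= 0))
  .with_seed(seed, {
    rows <- list()
    add <- function(gene, sample, n, mu, sdv) {
      rows[[length(rows) + 1L]] <<- data.frame(
        gene = gene, sample = sample, replicate = seq_len(n),
        ct = mu + (if (sdv > 0) rnorm(n, 0, sdv) else 0),
        stringsAsFactors = FALSE)
    }
    for (s in samples)
      add(reference_gene, s, max(ct_specs$replicates), 15, max(ct_specs$sd))
    for (i in seq_len(nrow(ct_specs))) {
      g <- ct_specs[i, ]
      base <- 25 + (i %% 5)
      add(g$gene, samples[2], g$replicates, base, g$sd)
      add(g$gene, samples[1], g$replicates, base - log2(g$fold), g$sd)
    }
    do.call(rbind, rows)
  })
}
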