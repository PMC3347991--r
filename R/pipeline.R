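# Pipeline orchestration: configuration, discovery end-to-end, and the
# full run (discovery + targets + expression) with structured logging.

#' Default pipeline configuration
#'
#' Aggregates every stage threshold at its standard value: homology
#' mismatch/E-value/score cuts, the precursor window grid, hairpin
#' criteria, family mismatch bound, target score cut and the qPCR
#' reference/calibrator.  Loadable/dumpable losslessly as JSON.
#'
#' @param ... overrides for any default field.
#' @return list (class \code{pipeline_config}).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # homology
    max_mismatch = 2, e_cut = 1e-2, score_cut = 32,
    # precursor windows
    flank_min = 20, flank_max = 280, flank_step = 20,
    win_min = 50, win_max = 600,
    # hairpin criteria
    mfe_max = -15, mfei_min = 0.5, au_min_pct = 30, au_max_pct = 70,
    max_duplex_mismatch = 6, require_single_arm = TRUE,
    # catalog
    max_family_mismatch = 4, name_prefix = "can",
    # targets
    target_score_cut = 3.0, max_gaps = 1,
    # expression
    reference_gene = "5S_rRNA", calibrator_sample = "stem",
    # io
    transcripts = NULL, reference = NULL, ct_table = NULL, out_dir = NULL,
    seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration (JSON)
#' @param cfg \code{pipeline_config}.
#' @param path JSON file path.
#' @return \code{path} / \code{pipeline_config}.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

.log_line <- function(stage, ...) {
  message(sprintf("[pinemir] %-10s %s", stage, paste0(...)))
}

#' Run the discovery stage end-to-end
#'
#' homology hits -> filter -> candidate windows -> MFE folding -> hairpin
#' criteria -> best candidate per hit -> per-locus deduplication -> family
#' assignment and member naming -> catalog + summary.  Deterministic given
#' config and inputs; every rejection is tallied by reason.
#'
#' @param transcripts \code{transcript_set} (or FASTA path in
#'   \code{cfg$transcripts}).
#' @param reference reference mature data.frame (or FASTA path in
#'   \code{cfg$reference}).
#' @param cfg \code{pipeline_config}.
#' @param out_dir if non-NULL, writes catalog TSV, precursor FASTA,
#'   dot-bracket file, GFF3, summary TSV and the resolved config.
#' @return list with \code{catalog}, \code{summary}, \code{accepted}
#'   (candidate detail), \code{rejections} (reason tally), \code{hits}.
#' @export
run_discovery <- function(transcripts = NULL, reference = NULL,
                          cfg = pipeline_config(), out_dir = cfg$out_dir) {
  if (is.null(transcripts)) {
    if (is.null(cfg$transcripts) || !file.exists(cfg$transcripts))
      stop("configuration error: transcript FASTA not found: ",
           cfg$transcripts, call. = FALSE)
    transcripts <- read_fasta(cfg$transcripts, allow_n = TRUE)
  }
  if (is.null(reference)) {
    if (is.null(cfg$reference) || !file.exists(cfg$reference))
      stop("configuration error: reference FASTA not found: ",
           cfg$reference, call. = FALSE)
    reference <- read_reference_mirnas(cfg$reference)
  }
  crit <- criteria_config(cfg$mfe_max, cfg$mfei_min, cfg$au_min_pct,
                          cfg$au_max_pct, cfg$max_duplex_mismatch,
                          cfg$require_single_arm)
  hits <- find_hits_all(transcripts, reference, cfg$max_mismatch)
  .log_line("homology", nrow(hits), " raw hits on ", nrow(transcripts),
            " transcripts")
  hits <- filter_hits(hits, cfg$e_cut, cfg$score_cut)
  .log_line("filter", nrow(hits), " hits pass E/score filter")
  # fold each locus once: hits from different reference matures at the same
  # placement share windows, keep the closest homolog
  hits <- hits[order(hits$transcript_id, hits$strand, hits$start,
                     hits$mismatches), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$transcript_id, hits$strand,
                                 hits$start, hits$end)), , drop = FALSE]
  .log_line("loci", nrow(hits), " distinct placements to evaluate")

  fold_cache <- new.env(parent = emptyenv())
  rejections <- c()
  accepted <- list()
  for (hi in seq_len(nrow(hits))) {
    hit <- hits[hi, ]
    tr <- transcripts[transcripts$id == hit$transcript_id, ]
    wins <- extract_windows(tr, hit, cfg$flank_min, cfg$flank_max,
                            cfg$flank_step)
    wins <- wins[nchar(wins$sequence) >= cfg$win_min &
                 nchar(wins$sequence) <= cfg$win_max, , drop = FALSE]
    k <- hit$end - hit$start
    cands <- lapply(seq_len(nrow(wins)), function(wi) {
      w <- wins[wi, ]
      key <- w$sequence
      st <- fold_cache[[key]]
      if (is.null(st)) {
        st <- fold_mfe(w$sequence)
        fold_cache[[key]] <- st
      }
      evaluate_candidate(w, st, k, crit)
    })
    best <- select_best(cands)
    if (is.null(best)) {
      rs <- unlist(lapply(cands, `[[`, "reasons"))
      top <- if (length(rs)) names(sort(table(rs), decreasing = TRUE))[1]
             else "no-window"
      rejections[top] <- (if (top %in% names(rejections))
                            rejections[[top]] else 0) + 1
      next
    }
    accepted[[length(accepted) + 1L]] <- data.frame(
      mirna_id = hit$mirna_id, transcript_id = hit$transcript_id,
      strand = hit$strand, mat_start = hit$start, mat_end = hit$end,
      mismatches = hit$mismatches,
      mature = substring(best$window$sequence, best$window$mature_offset + 1,
                         best$window$mature_offset + k),
      win_start = best$window$win_start, win_end = best$window$win_end,
      win_seq = best$window$sequence, dotbracket = best$structure$dotbracket,
      mfe = best$mfe, amfe = best$amfe, mfei = best$mfei,
      au_pct = best$au_pct, arm = best$arm,
      duplex_mismatches = best$duplex_mismatches,
      stringsAsFactors = FALSE)
  }
  .log_line("hairpin", length(accepted), " hits with a passing precursor; ",
            "rejections: ",
            if (length(rejections))
              paste(names(rejections), rejections, sep = "=",
                    collapse = ", ") else "none")
  if (!length(accepted)) {
    empty <- data.frame()
    .log_line("catalog", "0 records")
    return(list(catalog = empty, summary = NULL, accepted = empty,
                rejections = rejections, hits = hits))
  }
  acc <- do.call(rbind, accepted)
  # one record per locus: best (fewest mismatches, then highest MFEI) among
  # reference matures hitting the same place
  locus <- paste(acc$transcript_id, acc$strand, acc$mat_start, acc$mat_end)
  acc <- acc[order(locus, acc$mismatches, -acc$mfei), , drop = FALSE]
  acc <- acc[!duplicated(paste(acc$transcript_id, acc$strand,
                               acc$mat_start, acc$mat_end)), , drop = FALSE]
  # and one record per distinct mature locus center (family members can
  # co-locate; keep distinct mature subsequences)
  .log_line("dedupe", nrow(acc), " loci after deduplication")
  fam <- vapply(acc$mature, function(m)
    assign_family(m, reference, cfg$max_family_mismatch), character(1))
  records <- data.frame(
    family = unname(fam), mature = acc$mature, arm = acc$arm,
    length = nchar(acc$mature), au_pct = round(acc$au_pct, 1),
    mfe = acc$mfe, mfei = round(acc$mfei, 2),
    precursor_id = paste0(acc$transcript_id, ":", acc$win_start, "-",
                          acc$win_end, acc$strand),
    start = acc$mat_start, idx = seq_len(nrow(acc)),
    stringsAsFactors = FALSE)
  records <- name_members(records, cfg$name_prefix)
  acc <- acc[records$idx, , drop = FALSE]   # keep detail aligned to names
  records$idx <- NULL
  summary <- summarize_catalog(records)
  .log_line("catalog", nrow(records), " records in ",
            summary$n_families, " families")
  catalog <- records[, c(.catalog_cols, "start")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_catalog(catalog[, .catalog_cols],
                  file.path(out_dir, "catalog.tsv"))
    write_fasta(setNames(acc$win_seq, catalog$name),
                file.path(out_dir, "precursors.fa"))
    writeLines(unlist(lapply(seq_len(nrow(acc)), function(i)
      c(paste0(">", catalog$name[i]), acc$win_seq[i], acc$dotbracket[i]))),
      file.path(out_dir, "precursors.dotbracket"))
    gff <- data.frame(transcript_id = acc$transcript_id,
                      strand = acc$strand, win_start = acc$win_start,
                      win_end = acc$win_end, mat_start = acc$mat_start,
                      mat_end = acc$mat_end, name = catalog$name,
                      transcript_len = NA_integer_,
                      stringsAsFactors = FALSE)
    write_gff3(gff, file.path(out_dir, "precursors.gff3"))
    write_summary(summary, file.path(out_dir, "summary.tsv"))
    write_config(pipeline_config(), file.path(out_dir,
                                              "resolved_config.json"))
  }
  list(catalog = catalog, summary = summary, accepted = acc,
       rejections = rejections, hits = hits)
}

#' Run the full pipeline: discovery, target scan, expression
#'
#' @param cfg \code{pipeline_config} with input paths set
#'   (\code{transcripts}, \code{reference}, optionally \code{ct_table}),
#'   or pass objects directly.
#' @param transcripts,reference,ct optional in-memory inputs overriding the
#'   config paths.
#' @param target_transcripts optional separate mRNA set for the target
#'   scan; defaults to \code{transcripts}.
#' @param out_dir output directory (or NULL for in-memory only).
#' @return list with \code{discovery}, \code{targets}, \code{expression}.
#' @export
run_full <- function(cfg = pipeline_config(), transcripts = NULL,
                     reference = NULL, ct = NULL,
                     target_transcripts = NULL, out_dir = cfg$out_dir) {
  disc <- run_discovery(transcripts, reference, cfg, out_dir)
  .log_line("discover", "stage complete")
  tt <- if (!is.null(target_transcripts)) target_transcripts
        else if (!is.null(transcripts)) transcripts
        else read_fasta(cfg$transcripts, allow_n = TRUE)
  targets <- NULL
  if (nrow(disc$catalog)) {
    targets <- do.call(rbind, lapply(seq_len(nrow(disc$catalog)),
      function(i) scan_targets(
        list(id = disc$catalog$name[i], mature = disc$catalog$mature[i]),
        tt, cfg$target_score_cut, cfg$max_gaps)))
    rownames(targets) <- NULL
  }
  .log_line("targets", if (is.null(targets)) 0 else nrow(targets),
            " target sites at score <= ", cfg$target_score_cut)
  expr <- NULL
  if (!is.null(ct) || (!is.null(cfg$ct_table) && file.exists(cfg$ct_table))) {
    if (is.null(ct)) ct <- read_ct_table(cfg$ct_table)
    expr <- relative_quant(ct, cfg$reference_gene, cfg$calibrator_sample)
    .log_line("expression", nrow(expr), " gene/sample folds (calibrator ",
              cfg$calibrator_sample, ")")
  } else {
    .log_line("expression", "no Ct table supplied; stage skipped")
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(targets) && nrow(targets))
      write.table(targets[, setdiff(names(targets), "site")],
                  file.path(out_dir, "targets.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(expr))
      write.table(expr, file.path(out_dir, "expression.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  list(discovery = disc, targets = targets, expression = expr)
}
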