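# Family assignment, member naming, and catalog summary statistics.

# round half up to match percentage presentation (38%/41%/58% style)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# best ungapped sliding alignment: shorter sequence slid along the longer,
# overhanging positions of the longer count as mismatches
.slide_mismatches <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  ka <- length(sa); kb <- length(sb)
  best <- Inf; best_run <- -1L
  for (off in 0:(kb - ka)) {
    seg <- sb[(off + 1L):(off + ka)]
    eq <- sa == seg
    mm <- sum(!eq) + (kb - ka)
    run <- if (any(eq)) max(rle(eq)$lengths[rle(eq)$values]) else 0L
    if (mm < best || (mm == best && run > best_run)) {
      best <- mm; best_run <- run
    }
  }
  list(mismatches = best, run = best_run)
}

#' Assign a mature miRNA to a known family
#'
#' The family of the reference mature with the fewest mismatches under the
#' best ungapped offset alignment (shorter sequence slid along the longer,
#' overhangs counting as mismatches), provided that minimum is at most
#' \code{max_family_mismatch}; ties broken by the reference with the longer
#' exact-match run, then lexicographic family name.
#'
#' @param mature RNA string.
#' @param reference reference data.frame (\code{id}, \code{family},
#'   \code{mature}).
#' @param max_family_mismatch maximum mismatches within a family (default 4).
#' @return family label, or \code{"unassigned"}.
#' @export
assign_family <- function(mature, reference, max_family_mismatch = 4) {
  stopifnot(nrow(reference) > 0)
  res <- lapply(reference$mature, .slide_mismatches, b = mature)
  mm <- vapply(res, `[[`, numeric(1), "mismatches")
  run <- vapply(res, `[[`, numeric(1), "run")
  ord <- order(mm, -run, reference$family)
  best <- ord[1]
  if (mm[best] > max_family_mismatch) return("unassigned")
  reference$family[best]
}

#' Assign member letter suffixes within each family
#'
#' Within a family, suffixes a, b, c, ... are assigned in order of precursor
#' transcript id then coordinate; deterministic across input orderings.
#' Every member gets a suffix (single-member families get "a").
#'
#' @param records catalog data.frame with \code{family},
#'   \code{precursor_id}; ordering uses \code{precursor_id} and, when
#'   present, \code{start}.
#' @param prefix species prefix for names (default \code{"can"},
#'   candidate).
#' @return records with a \code{name} column like \code{can-miR482a}.
#' @export
name_members <- function(records, prefix = "can") {
  if (nrow(records) == 0L) return(records)
  start <- if ("start" %in% names(records)) records$start else
    rep(0L, nrow(records))
  ord <- order(records$family, records$precursor_id, start)
  records <- records[ord, , drop = FALSE]
  records$name <- NA_character_
  for (f in unique(records$family)) {
    i <- which(records$family == f)
    records$name[i] <- paste0(prefix, "-miR", sub("^MIR", "", f),
                              letters[seq_along(i)])
  }
  rownames(records) <- NULL
  records
}

#' Summarize a miRNA catalog
#'
#' Computes the headline statistics of a conserved-miRNA catalog: counts,
#' mature length histogram and percentages, 5'-terminal-U count and
#' percentage, MFEI mean/sd/min/max, and family sizes.  Percentages are
#' rounded half-up to integers; MFEI moments to 2 decimals.
#'
#' @param records catalog data.frame with \code{name}, \code{family},
#'   \code{mature}, \code{mfei}.
#' @return list of class \code{catalog_summary}.
#' @export
summarize_catalog <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("empty catalog", call. = FALSE)
  n <- nrow(records)
  len <- nchar(records$mature)
  hist <- table(len)
  length_histogram <- setNames(as.integer(hist), names(hist))
  pct_by_length <- setNames(
    as.integer(round_half_up(100 * as.integer(hist) / n)), names(hist))
  first <- substring(records$mature, 1, 1)
  u_count <- sum(first == "U")
  fam <- table(records$family)
  out <- list(
    n_mirnas = n,
    n_families = length(fam),
    length_histogram = length_histogram,
    pct_by_length = pct_by_length,
    five_prime_u_count = as.integer(u_count),
    five_prime_u_pct = as.integer(round_half_up(100 * u_count / n)),
    mfei_mean = round(mean(records$mfei), 2),
    mfei_sd = round(sd(records$mfei), 2),
    mfei_min = min(records$mfei),
    mfei_max = max(records$mfei),
    family_sizes = setNames(as.integer(fam), names(fam)))
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("miRNA catalog summary\n")
  cat("  miRNAs:", x$n_mirnas, " families:", x$n_families, "\n")
  cat("  mature lengths:",
      paste0(names(x$length_histogram), "nt:", x$length_histogram,
             " (", x$pct_by_length[names(x$length_histogram)], "%)",
             collapse = ", "), "\n")
  cat("  5' terminal U:", x$five_prime_u_count,
      paste0("(", x$five_prime_u_pct, "%)"), "\n")
  cat("  MFEI: mean", sprintf("%.2f", x$mfei_mean), "sd",
      sprintf("%.2f", x$mfei_sd), "range",
      sprintf("[%.2f, %.2f]", x$mfei_min, x$mfei_max), "\n")
  big <- sort(x$family_sizes[x$family_sizes > 1], decreasing = TRUE)
  if (length(big))
    cat("  multi-member families:",
        paste0(names(big), ":", big, collapse = ", "), "\n")
  cat("  singleton families:", sum(x$family_sizes == 1), "\n")
  invisible(x)
}

#' Load the packaged conserved-miRNA catalog fixture
#'
#' The 34 conserved mature miRNAs (25 families) of the pine
#' transcriptome-survey worked example, with per-record arm, length, A+U
#' content, folding energy and MFEI.
#'
#' @return catalog data.frame (34 rows).
#' @export
load_catalog_fixture <- function() {
  path <- system.file("extdata", "pde_mirnas_catalog.tsv",
                      package = "pinemir")
  tab <- read_catalog(path)
  stopifnot(nrow(tab) == 34L)
  tab
}

#' Reference mature set derived from the packaged catalog fixture
#'
#' @return data.frame in \code{\link{read_reference_mirnas}} layout.
#' @export
fixture_reference <- function() {
  tab <- load_catalog_fixture()
  data.frame(id = tab$name, family = tab$family, mature = tab$mature,
             species_tag = "pde", stringsAsFactors = FALSE)
}

#' Summary TSV/JSON writers for a catalog summary
#' @param summary \code{catalog_summary}.
#' @param path output path; format from extension (.json or .tsv).
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    flat <- c(
      n_mirnas = summary$n_mirnas, n_families = summary$n_families,
      five_prime_u_count = summary$five_prime_u_count,
      five_prime_u_pct = summary$five_prime_u_pct,
      mfei_mean = summary$mfei_mean, mfei_sd = summary$mfei_sd,
      mfei_min = summary$mfei_min, mfei_max = summary$mfei_max,
      setNames(summary$length_histogram,
               paste0("n_len", names(summary$length_histogram))),
      setNames(summary$family_sizes,
               paste0("family_", names(summary$family_sizes))))
    write.table(data.frame(key = names(flat), value = unname(flat)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
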