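# Sequence I/O and alphabet handling.
#
# All sequences are stored internally as RNA (U canonical, uppercase);
# T is accepted on input only.  Coordinates everywhere in the package are
# 0-based half-open on the + strand of the stored transcript; conversion to
# 1-based inclusive happens only at the GFF3/report boundary.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside \code{A,C,G,U,N} after
#' normalization raise an alphabet error.
#'
#' @param x character vector of sequences.
#' @param allow_n logical; if \code{FALSE} (default) an \code{N} is an error.
#' @return character vector over \code{{A,C,G,U}} (plus \code{N} if allowed).
#' @export
normalize_rna <- function(x, allow_n = FALSE) {
  x <- chartr("t", "u", tolower(x))
  x <- toupper(x)
  x <- chartr("T", "U", x)
  ok <- if (allow_n) "^[ACGUN]*$" else "^[ACGU]*$"
  bad <- !grepl(ok, x)
  if (any(bad)) {
    ch <- gsub(if (allow_n) "[ACGUN]" else "[ACGU]", "", x[bad][1])
    stop("alphabet error: character(s) '", substr(ch, 1, 5),
         "' outside the RNA alphabet", call. = FALSE)
  }
  x
}

#' Reverse complement of an RNA string
#'
#' @param x character vector of RNA sequences (U alphabet).
#' @return reverse complement(s), 5'->3'.
#' @export
revcomp_rna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUN", "UGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file into a transcript table
#'
#' Reads FASTA via \pkg{Biostrings} and normalizes every record to the
#' internal RNA alphabet (T->U, uppercase). Record order is preserved.
#'
#' @param path FASTA file.
#' @param alphabet \code{"rna"} or \code{"dna"}; both are normalized to RNA.
#' @param allow_n if \code{TRUE}, records containing N are kept and flagged in
#'   the \code{has_n} column instead of raising an error.
#' @return a \code{data.frame} (class \code{transcript_set}) with columns
#'   \code{id}, \code{sequence}, \code{length}, \code{has_n}.
#' @export
read_fasta <- function(path, alphabet = c("rna", "dna"), allow_n = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty input: no FASTA records in ", path,
                             call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate record id: ", ids[duplicated(ids)][1], call. = FALSE)
  seqs <- normalize_rna(as.character(ss), allow_n = allow_n)
  out <- data.frame(id = ids, sequence = seqs, length = nchar(seqs),
                    has_n = grepl("N", seqs, fixed = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a \code{transcript_set}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Parse a reference FASTA of known mature miRNAs
#'
#' Headers are expected as \code{>id [family]}; when the bracketed family tag
#' is absent the family is derived from the id (species prefix and trailing
#' member letter stripped, e.g. \code{pde-miR482a} -> \code{MIR482}).
#'
#' @param path FASTA of mature sequences.
#' @return data.frame with \code{id}, \code{family}, \code{mature},
#'   \code{species_tag}.
#' @export
read_reference_mirnas <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty input: ", path, call. = FALSE)
  full <- names(ss)
  ids <- sub("\\s.*$", "", full)
  fam <- ifelse(grepl("\\[[^]]+\\]", full),
                sub(".*\\[([^]]+)\\].*", "\\1", full),
                vapply(ids, family_from_id, character(1)))
  mature <- normalize_rna(as.character(ss))
  bad <- nchar(mature) < 18 | nchar(mature) > 26
  if (any(bad))
    stop("mature length outside 18-26 nt: ", ids[bad][1], call. = FALSE)
  data.frame(id = ids, family = unname(fam), mature = mature,
             species_tag = sub("-.*$", "", ids), stringsAsFactors = FALSE)
}

#' Derive a miRNA family label from a member id
#'
#' \code{pde-miR482a} -> \code{MIR482}; the species prefix, the miR/MIR
#' casing and any trailing letter suffix are dropped.
#'
#' @param id miRNA identifier.
#' @return family label such as \code{"MIR482"}.
#' @export
family_from_id <- function(id) {
  x <- sub("^[a-z]{2,4}-", "", id)
  x <- sub("^mi[rR]", "MIR", x, ignore.case = TRUE)
  sub("^(MIR[0-9]+)[a-z]*(-[0-9]+)?$", "\\1", x)
}

.catalog_cols <- c("name", "family", "mature", "arm", "length", "au_pct",
                   "mfe", "mfei", "precursor_id")

#' Write a miRNA catalog to TSV
#'
#' Column layout mirrors the catalog table of the discovery output:
#' name, family, mature sequence, arm, length (nt), A+U (%), folding energy
#' (kcal/mol), MFEI, precursor reference. Round-trips bit-exactly through
#' \code{\link{read_catalog}}.
#'
#' @param records data.frame of catalog records (see \code{.catalog_cols}).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(records, path) {
  if (nrow(records) > 0 && anyDuplicated(records$name))
    stop("duplicate record names: ",
         records$name[duplicated(records$name)][1], call. = FALSE)
  missing_cols <- setdiff(.catalog_cols, names(records))
  if (length(missing_cols))
    stop("catalog records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  write.table(records[, .catalog_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a miRNA catalog TSV written by \code{\link{write_catalog}}
#' @param path TSV file.
#' @return data.frame of catalog records.
#' @export
read_catalog <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    name = "character", family = "character", mature = "character",
    arm = "character", precursor_id = "character"))
}

#' Write precursor candidates to GFF3
#'
#' Emits one \code{miRNA_primary_transcript} feature per candidate with a
#' child \code{miRNA} feature for the mature; internal 0-based half-open
#' coordinates are converted to GFF3 1-based inclusive here and only here.
#'
#' @param candidates data.frame with \code{transcript_id}, \code{strand},
#'   \code{win_start}, \code{win_end}, \code{mat_start}, \code{mat_end}
#'   (mature on + strand), \code{name}, and optionally \code{transcript_len}.
#' @param path output GFF3 path.
#' @return \code{path}, invisibly.
#' @export
write_gff3 <- function(candidates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(candidates))) {
    r <- candidates[i, ]
    if (r$win_start < 0 || r$mat_start < r$win_start || r$mat_end > r$win_end)
      stop("coordinates outside transcript/window for ", r$name,
           call. = FALSE)
    if (!is.null(r$transcript_len) && !is.na(r$transcript_len) &&
        r$win_end > r$transcript_len)
      stop("coordinate outside transcript for ", r$name, call. = FALSE)
    writeLines(sprintf(
      "%s\tpinemir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
      r$transcript_id, r$win_start + 1L, r$win_end, r$strand, r$name), con)
    writeLines(sprintf(
      "%s\tpinemir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
      r$transcript_id, r$mat_start + 1L, r$mat_end, r$strand, r$name,
      r$name), con)
  }
  invisible(path)
}
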