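# MFE secondary-structure prediction: R interface over the C++ dynamic
# program, the standalone structure scorer, and a Vienna-format adapter so
# structures from an external folder can be used interchangeably.

#' Load the packaged nearest-neighbor energy parameter table
#'
#' The table holds stacking energies for the canonical pair stacks plus
#' hairpin/bulge/internal loop length penalties and affine multiloop terms
#' (kcal/mol at 37 C).  Values are converted to integer deci-kcal internally
#' so folding and the enumeration oracle compare exactly.
#'
#' @param path TSV parameter file; default is the packaged table.
#' @return parameter list consumed by \code{\link{fold_mfe}}.
#' @export
load_energy_params <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pinemir_env$energy_params))
      return(.pinemir_env$energy_params)
    path <- system.file("extdata", "energy_params.tsv", package = "pinemir")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  deci <- function(x) as.integer(round(x * 10))
  pairs <- c("AU", "CG", "GC", "UA", "GU", "UG")
  st <- matrix(0L, 6, 6, dimnames = list(pairs, pairs))
  srows <- tab[tab$category == "stack", ]
  for (r in seq_len(nrow(srows)))
    st[srows$key1[r], srows$key2[r]] <- deci(srows$value[r])
  INF <- 100000000L
  loop_vec <- function(cat, min_size) {
    rows <- tab[tab$category == cat, ]
    sizes <- as.integer(rows$key1)
    v <- rep(INF, max(sizes) + 1L)
    v[sizes + 1L] <- deci(rows$value)      # index = size (0-based shift)
    v
  }
  pv <- function(key) tab$value[tab$category == "param" & tab$key1 == key]
  par <- list(
    stack = st,
    hairpin = loop_vec("hairpin", 3L),
    bulge = loop_vec("bulge", 1L),
    internal = loop_vec("internal", 2L),
    ml_a = deci(pv("ml_closing")),
    ml_b = deci(pv("ml_branch")),
    ml_c = deci(pv("ml_unpaired")),
    lncoef = deci(pv("loop_ln_coef")),
    maxloop = as.integer(pv("max_interior_loop")))
  if (is.null(path) || grepl("extdata", path, fixed = TRUE))
    .pinemir_env$energy_params <- par
  par
}

# pairs vector (0-based partner, -1 unpaired) from a dot-bracket string
.pairs_from_dotbracket <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("invalid character in dot-bracket string", call. = FALSE)
  pr <- rep(-1L, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr[i] <- j - 1L
      pr[j] <- i - 1L
    }
  }
  if (length(stack)) stop("unbalanced brackets", call. = FALSE)
  pr
}

.dotbracket_from_pairs <- function(pr) {
  n <- length(pr)
  ch <- rep(".", n)
  ip <- which(pr >= 0 & pr > seq_len(n) - 1L)
  ch[ip] <- "("
  ch[pr[ip] + 1L] <- ")"
  paste(ch, collapse = "")
}

#' Predict the minimum-free-energy secondary structure
#'
#' Zuker-style dynamic programming under the packaged nearest-neighbor
#' table; fully nested structures, minimum hairpin loop of 3 nt, canonical
#' pairs (including G:U) only, lonely pairs allowed.  Only the single MFE
#' structure is returned, with a deterministic tie-break that prefers
#' pairing the leftmost position.
#'
#' @param sequence RNA string, 10 to 1000 nt.
#' @param params energy parameters (\code{\link{load_energy_params}}).
#' @return object of class \code{rna_structure}: list with
#'   \code{dotbracket}, \code{mfe} (kcal/mol, <= 0) and \code{pairs}
#'   (0-based partner per position, -1 when unpaired).
#' @export
fold_mfe <- function(sequence, params = load_energy_params()) {
  n <- nchar(sequence)
  if (n < 10 || n > 1000)
    stop("sequence length must be in [10, 1000], got ", n, call. = FALSE)
  sequence <- normalize_rna(sequence)
  res <- .fold_mfe_cpp(sequence, params)
  structure(list(dotbracket = res$dotbracket, mfe = res$mfe_deci / 10,
                 pairs = res$pairs, sequence = sequence),
            class = "rna_structure")
}

#' Score an explicit secondary structure
#'
#' Total nearest-neighbor energy of exactly the given structure (loop
#' decomposition; exterior bases are free).
#'
#' @param sequence RNA string.
#' @param dotbracket structure string over \code{(, ), .} of equal length.
#' @param params energy parameters.
#' @return energy in kcal/mol.
#' @export
energy_of <- function(sequence, dotbracket, params = load_energy_params()) {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) != nchar(dotbracket))
    stop("sequence and structure lengths differ", call. = FALSE)
  pr <- .pairs_from_dotbracket(dotbracket)
  .validate_structure(sequence, pr)
  .energy_pairs_cpp(sequence, pr, params) / 10
}

# invariant checks shared by energy_of and parse_external_fold
.validate_structure <- function(sequence, pr) {
  ch <- strsplit(sequence, "")[[1]]
  comp <- c(A = "U", U = "AG", G = "CU", C = "G")
  idx <- which(pr >= 0)
  for (i in idx) {
    j <- pr[i] + 1L
    if (pr[j] != i - 1L) stop("pair table not symmetric", call. = FALSE)
    if (abs(j - i) - 1L < 3L && j > i)
      stop("hairpin loop shorter than 3 nt", call. = FALSE)
    if (j > i && !grepl(ch[j], comp[[ch[i]]], fixed = TRUE))
      stop("non-canonical pair ", ch[i], ":", ch[j], " at ", i, call. = FALSE)
  }
  invisible(TRUE)
}

#' Exhaustive-enumeration MFE (test oracle)
#'
#' Enumerates every valid nested structure of a short sequence and returns
#' the minimum energy under the same parameter table, independently of the
#' dynamic program.  Limited to 40 nt.
#'
#' @inheritParams fold_mfe
#' @return list with \code{mfe} (kcal/mol) and \code{n_structures}.
#' @export
enumerate_mfe <- function(sequence, params = load_energy_params()) {
  sequence <- normalize_rna(sequence)
  res <- .enumerate_mfe_cpp(sequence, params)
  list(mfe = res$mfe_deci / 10, n_structures = res$n_structures)
}

#' Parse Vienna-format fold output
#'
#' Accepts the \code{"sequence\\nstructure (energy)"} dialect (optionally
#' with a leading \code{>id} header line) and returns a validated
#' \code{rna_structure}.
#'
#' @param text character scalar or vector of lines.
#' @return \code{rna_structure} object.
#' @export
parse_external_fold <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1], ">")) lines <- lines[-1]
  if (length(lines) < 2)
    stop("expected sequence and structure lines", call. = FALSE)
  seq <- normalize_rna(trimws(lines[1]))
  m <- regmatches(lines[2],
                  regexec("^\\s*([().]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                          lines[2]))[[1]]
  if (length(m) != 3)
    stop("cannot parse structure/energy line: ", lines[2], call. = FALSE)
  db <- m[2]
  mfe <- as.numeric(m[3])
  if (nchar(db) != nchar(seq))
    stop("sequence and structure lengths differ", call. = FALSE)
  pr <- .pairs_from_dotbracket(db)
  .validate_structure(seq, pr)
  structure(list(dotbracket = db, mfe = mfe, pairs = pr, sequence = seq),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, " (", sprintf("%.2f", x$mfe), ")\n",
      sep = "")
  invisible(x)
}

#' Format an \code{rna_structure} as Vienna text
#' @param structure \code{rna_structure}.
#' @param id optional record id for a FASTA-style header.
#' @return character scalar.
#' @export
format_vienna <- function(structure, id = NULL) {
  hdr <- if (is.null(id)) "" else paste0(">", id, "\n")
  paste0(hdr, structure$sequence, "\n", structure$dotbracket,
         sprintf(" (%.2f)", structure$mfe))
}
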