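# Comparative-Ct (2^-ddCt) relative quantification across tissues.
#
# Replicates are averaged on the Ct scale before ddCt; amplification
# efficiency is fixed at 2 (no efficiency correction).  The spread of
# replicate-level dCt is propagated through the exponent.

#' Read a qPCR Ct table
#'
#' @param path TSV with columns \code{gene}, \code{sample},
#'   \code{replicate}, \code{ct}.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  ct
}

#' Relative quantification by the comparative-Ct method
#'
#' \code{dCt(g, s) = mean Ct(g, s) - mean Ct(ref, s)};
#' \code{ddCt = dCt(g, s) - dCt(g, calibrator)}; \code{fold = 2^-ddCt}.
#' The calibrator sample has fold 1 for every gene by construction.
#' \code{sd_fold} is the replicate dCt standard deviation propagated
#' through the exponent: \code{fold * (2^sd - 2^-sd) / 2}.
#'
#' @param ct data.frame with \code{gene}, \code{sample}, \code{replicate},
#'   \code{ct}.
#' @param reference_gene normalizer gene (e.g. \code{"5S_rRNA"}); must be
#'   measured in every sample.
#' @param calibrator_sample sample whose level defines fold 1 (e.g.
#'   \code{"stem"}).
#' @return data.frame with \code{gene}, \code{sample}, \code{fold},
#'   \code{sd_fold}.
#' @export
relative_quant <- function(ct, reference_gene, calibrator_sample) {
  samples <- unique(ct$sample)
  genes <- setdiff(unique(ct$gene), reference_gene)
  if (!(reference_gene %in% ct$gene))
    stop("reference gene ", reference_gene, " absent from table",
         call. = FALSE)
  if (!(calibrator_sample %in% samples))
    stop("calibrator sample ", calibrator_sample, " absent from table",
         call. = FALSE)
  ref_mean <- sapply(samples, function(s) {
    v <- ct$ct[ct$gene == reference_gene & ct$sample == s]
    if (!length(v))
      stop("reference gene missing in sample ", s, call. = FALSE)
    mean(v)
  })
  rows <- list()
  for (g in genes) {
    dct <- numeric(length(samples))
    names(dct) <- samples
    dct_sd <- dct
    for (s in samples) {
      v <- ct$ct[ct$gene == g & ct$sample == s]
      if (!length(v))
        stop("gene ", g, " missing in sample ", s, call. = FALSE)
      reps_dct <- v - ref_mean[[s]]
      dct[[s]] <- mean(reps_dct)
      dct_sd[[s]] <- if (length(v) > 1) sd(reps_dct) else 0
    }
    ddct <- dct - dct[[calibrator_sample]]
    fold <- 2^(-ddct)
    sdf <- fold * (2^dct_sd - 2^(-dct_sd)) / 2
    rows[[g]] <- data.frame(gene = g, sample = samples,
                            fold = unname(fold), sd_fold = unname(sdf),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes exceeding a fold-change threshold outside the calibrator
#'
#' @param expr output of \code{\link{relative_quant}}.
#' @param threshold fold threshold, strict (default 2.0).
#' @param calibrator_sample calibrator sample name to exclude.
#' @return character vector of genes with \code{fold > threshold} in at
#'   least one non-calibrator sample.
#' @export
classify_fold <- function(expr, threshold = 2.0, calibrator_sample = NULL) {
  x <- expr
  if (!is.null(calibrator_sample))
    x <- x[x$sample != calibrator_sample, , drop = FALSE]
  sort(unique(x$gene[x$fold > threshold]))
}
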