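#' InjuryRescueExperiment: counts plus arm assignments
#'
#' An \linkS4class{SummarizedExperiment} holding a non-negative integer
#' gene-by-sample count matrix (assay \code{"counts"}) together with the
#' injury-rescue design: every sample is assigned to an arm, one arm is the
#' normal control (default \code{"NC"}), one is the injury model (default
#' \code{"ADM"}), and the remaining arms are treatments. Optional per-gene
#' lengths (base pairs) in \code{rowData} enable FPKM computation; simulated
#' objects additionally carry the ground-truth columns written by
#' \code{\link{simulateCounts}}.
#'
#' @slot normalArm single arm label for the untreated control.
#' @slot modelArm single arm label for the injured model.
#'
#' @seealso \code{\link{InjuryRescueExperiment}} (constructor),
#'   \code{\link{simulateCounts}}, \code{\link{nbWaldTest}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("InjuryRescueExperiment",
  contains = "SummarizedExperiment",
  slots = c(normalArm = "character", modelArm = "character")
)

setValidity("InjuryRescueExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is required")
  } else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
      msg <- c(msg, "counts must be finite, non-negative integers")
    }
  }
  if (!"arm" %in% colnames(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData column 'arm' is required")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  }
  if (length(object@normalArm) != 1L || length(object@modelArm) != 1L) {
    msg <- c(msg, "normalArm and modelArm must be single labels")
  }
  if (length(msg)) msg else TRUE
})

#' Per-gene differential-expression results for one two-arm contrast
#'
#' A \linkS4class{DFrame} with one row per gene and columns
#' \code{gene_id}, \code{base_mean} (mean of normalized counts over both
#' arms), \code{log2fc} (numerator over denominator), \code{dispersion}
#' (NB dispersion used by the Wald test), \code{p_value} and \code{fdr}
#' (Benjamini-Hochberg adjusted). Genes with zero counts in every sample of
#' both arms carry \code{NA} p-values and are excluded from the FDR ranking.
#'
#' @slot contrast character of length 2: numerator arm, denominator arm.
#' @seealso \code{\link{nbWaldTest}}, \code{\link{callDEGs}}
#' @importClassesFrom S4Vectors DFrame
#' @export
setClass("DEResults",
  contains = "DFrame",
  slots = c(contrast = "character")
)

setValidity("DEResults", function(object) {
  need <- c("gene_id", "base_mean", "log2fc", "dispersion", "p_value", "fdr")
  msg <- character(0)
  if (!all(need %in% colnames(object))) {
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, colnames(object)), collapse = ", ")))
  }
  if (length(object@contrast) != 2L) {
    msg <- c(msg, "contrast must be c(numerator, denominator)")
  }
  ok <- !is.na(object$fdr) & !is.na(object$p_value)
  if (any(ok) && any(object$fdr[ok] + 1e-12 < object$p_value[ok])) {
    msg <- c(msg, "fdr must be >= p_value")
  }
  if (length(msg)) msg else TRUE
})
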