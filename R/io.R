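#' Read a counts TSV plus sample sheet into an InjuryRescueExperiment
#'
#' The counts file is tab-separated with a header row and first column
#' \code{gene_id}; the sample sheet has columns \code{sample_id},
#' \code{arm}, and optionally \code{replicate}; the optional lengths file
#' has \code{gene_id} and \code{gene_length} (base pairs).
#'
#' @param countsPath,samplesPath,lengthsPath file paths.
#' @param normalArm,modelArm arm labels (defaults "NC", "ADM").
#' @return an \linkS4class{InjuryRescueExperiment}.
#' @export
readCountMatrix <- function(countsPath, samplesPath, lengthsPath = NULL,
                            normalArm = "NC", modelArm = "ADM") {
  cnt <- utils::read.delim(countsPath, check.names = FALSE)
  if (colnames(cnt)[1] != "gene_id") {
    stop(countsPath, ": first column must be 'gene_id'")
  }
  mat <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(mat) <- cnt$gene_id
  ss <- utils::read.delim(samplesPath)
  miss <- setdiff(colnames(mat), ss$sample_id)
  if (length(miss)) {
    stop(samplesPath, ": samples missing from sheet: ",
         paste(miss, collapse = ", "))
  }
  ss <- ss[match(colnames(mat), ss$sample_id), ]
  lens <- NULL
  if (!is.null(lengthsPath)) {
    lt <- utils::read.delim(lengthsPath)
    lens <- stats::setNames(lt$gene_length, lt$gene_id)
  }
  InjuryRescueExperiment(mat, arms = ss$arm, geneLengths = lens,
                         normalArm = normalArm, modelArm = modelArm,
                         replicate = if ("replicate" %in% colnames(ss))
                           ss$replicate else NULL)
}

#' Read a qPCR Ct TSV
#'
#' Expects columns gene_id, sample_id, arm, ct and optionally
#' is_reference.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  ct <- utils::read.delim(path)
  need <- c("gene_id", "sample_id", "arm", "ct")
  miss <- setdiff(need, colnames(ct))
  if (length(miss)) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  ct
}

writeTSV <- function(df, path, rownamesCol = NULL) {
  if (!is.null(rownamesCol)) {
    df <- cbind(stats::setNames(data.frame(rownames(df)), rownamesCol),
                as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
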