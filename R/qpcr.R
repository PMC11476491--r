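#' 2^-ddCt relative expression
#'
#' For each target gene and sample, \eqn{\Delta Ct = Ct_{target} -
#' Ct_{reference}} within the same sample; \eqn{\Delta\Delta Ct} subtracts
#' the gene's mean calibrator-arm \eqn{\Delta Ct}; the per-arm fold change
#' is \eqn{2^{-\overline{\Delta\Delta Ct}}} (so the calibrator arm has fold
#' exactly 1 by construction). Samples missing the reference Ct are
#' excluded with a warning.
#'
#' @param ct data.frame with columns gene_id, sample_id, arm, ct, and
#'   either an is_reference column or a \code{referenceGene} argument.
#' @param calibratorArm calibrator condition (default "NC").
#' @param referenceGene id of the reference gene (overrides is_reference).
#' @return data.frame per (gene, arm): n replicates, delta_ct (mean),
#'   delta_delta_ct (mean), fold = 2^-ddCt, sd_delta_delta_ct, and the
#'   per-replicate spread fold_lo/fold_hi (fold at ddCt mean +/- sd).
#' @examples
#' ct <- data.frame(
#'   gene_id = rep(c("tgt", "ref"), 2),
#'   sample_id = rep(c("t1", "c1"), each = 2),
#'   arm = rep(c("T", "NC"), each = 2),
#'   ct = c(20, 15, 24, 16))
#' ddct(ct, referenceGene = "ref")  # arm T: ddCt -3, fold 8
#' @export
ddct <- function(ct, calibratorArm = "NC", referenceGene = NULL) {
  if (is.null(referenceGene)) {
    if (!"is_reference" %in% colnames(ct)) {
      stop("provide 'referenceGene' or an is_reference column")
    }
    referenceGene <- unique(ct$gene_id[ct$is_reference])
  }
  if (length(referenceGene) != 1L) {
    stop("exactly one reference gene is required")
  }
  if (!calibratorArm %in% ct$arm) {
    stop("calibrator arm '", calibratorArm, "' absent from the Ct table")
  }
  ref <- ct[ct$gene_id == referenceGene, c("sample_id", "ct")]
  names(ref)[2] <- "ref_ct"
  tgt <- ct[ct$gene_id != referenceGene, , drop = FALSE]
  tgt <- merge(tgt, ref, by = "sample_id", all.x = TRUE)
  if (anyNA(tgt$ref_ct)) {
    drop <- unique(tgt$sample_id[is.na(tgt$ref_ct)])
    warning("samples without reference Ct excluded: ",
            paste(drop, collapse = ", "))
    tgt <- tgt[!is.na(tgt$ref_ct), ]
  }
  tgt$dct <- tgt$ct - tgt$ref_ct
  out <- list()
  for (g in unique(tgt$gene_id)) {
    sub <- tgt[tgt$gene_id == g, ]
    cal <- sub$dct[sub$arm == calibratorArm]
    if (!length(cal)) {
      stop("gene ", g, " absent in calibrator arm '", calibratorArm, "'")
    }
    sub$ddct <- sub$dct - mean(cal)
    agg <- do.call(rbind, lapply(split(sub, sub$arm), function(a) {
      mdd <- mean(a$ddct)
      sdd <- stats::sd(a$ddct)
      data.frame(gene_id = g, arm = a$arm[1], n = nrow(a),
                 delta_ct = mean(a$dct), delta_delta_ct = mdd,
                 fold = 2^(-mdd), sd_delta_delta_ct = sdd,
                 fold_lo = 2^(-(mdd + sdd)), fold_hi = 2^(-(mdd - sdd)),
                 stringsAsFactors = FALSE)
    }))
    out[[g]] <- agg
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}

#' Concordance between qPCR and RNA-seq fold changes
#'
#' Pairs qPCR log2 fold changes (from \code{\link{ddct}}, arm vs
#' calibrator, differenced for treatment-vs-model contrasts) with RNA-seq
#' log2 fold changes over genes and contrasts, and reports the Pearson
#' correlation, the fraction of matching signs, and the correlation test
#' p-value (descriptive).
#'
#' @param rel output of \code{\link{ddct}} (calibrator = normal arm).
#' @param deList named list of \linkS4class{DEResults}; names are ignored,
#'   contrasts are read from each object. Supported contrasts are
#'   model-vs-calibrator and treatment-vs-model.
#' @param genes gene ids to use (default: all shared).
#' @param modelArm,calibratorArm arm labels (defaults "ADM", "NC").
#' @return list with \code{pairs} (gene, contrast, log2 qPCR, log2 RNA-seq),
#'   \code{correlation}, \code{sign_agreement}, \code{p_value}, \code{n}.
#' @export
qpcrConcordance <- function(rel, deList, genes = NULL,
                            modelArm = "ADM", calibratorArm = "NC") {
  if (methods::is(deList, "DEResults")) deList <- list(deList)
  qlfc <- function(g, arm) {
    r <- rel[rel$gene_id == g & rel$arm == arm, ]
    if (!nrow(r)) return(NA_real_)
    -r$delta_delta_ct[1]
  }
  pairs <- list()
  for (de in deList) {
    ca <- contrastArms(de)
    df <- as.data.frame(de)
    gg <- if (is.null(genes)) intersect(df$gene_id, rel$gene_id) else genes
    for (g in gg) {
      i <- match(g, df$gene_id)
      if (is.na(i) || is.na(df$log2fc[i])) next
      q <- if (identical(ca, c(modelArm, calibratorArm))) {
        qlfc(g, modelArm)
      } else if (ca[2] == modelArm) {
        qlfc(g, ca[1]) - qlfc(g, modelArm)
      } else if (ca[2] == calibratorArm) {
        qlfc(g, ca[1])
      } else NA_real_
      if (is.na(q)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene_id = g, contrast = paste(ca, collapse = "_vs_"),
        log2_qpcr = q, log2_rnaseq = df$log2fc[i],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3L) {
    stop("need >= 3 gene/contrast pairs with both measurements")
  }
  ctest <- stats::cor.test(pairs$log2_qpcr, pairs$log2_rnaseq)
  nz <- pairs$log2_qpcr != 0 & pairs$log2_rnaseq != 0
  list(pairs = pairs,
       correlation = unname(ctest$estimate),
       sign_agreement = mean(sign(pairs$log2_qpcr[nz]) ==
                               sign(pairs$log2_rnaseq[nz])),
       p_value = ctest$p.value,
       n = nrow(pairs))
}
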