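#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over genes
#' with positive counts in every sample, of the ratio of its count to the
#' gene's geometric mean across samples. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts integer gene-by-sample matrix.
#' @param method \code{"ratio"} (median-of-ratios, default) or
#'   \code{"total"} (total-count fallback for matrices where no gene is
#'   expressed in all samples).
#' @return positive numeric vector, one factor per sample, geometric mean 1.
#' @examples
#' m <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
#' medianRatioSizeFactors(m)  # c(0.7071, 1.4142)
#' @export
medianRatioSizeFactors <- function(counts, method = c("ratio", "total")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (method == "total") {
    sf <- colSums(counts)
    if (any(sf <= 0)) stop("a sample has zero total counts")
    return(sf / exp(mean(log(sf))))
  }
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no gene has positive counts in every sample; filter the matrix ",
         "or use method = \"total\"")
  }
  sf <- apply(counts, 2, function(cnt) {
    exp(stats::median(log(cnt[use]) - loggeo[use]))
  })
  sf / exp(mean(log(sf)))
}

#' Compute and attach size factors
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @param method passed to \code{\link{medianRatioSizeFactors}}.
#' @return \code{x} with \code{sizeFactors(x)} filled in.
#' @export
addSizeFactors <- function(x, method = c("ratio", "total")) {
  sizeFactors(x) <- medianRatioSizeFactors(counts(x), method)
  x
}

normalizedCounts <- function(x) {
  sf <- sizeFactors(x)
  if (is.null(sf)) sf <- medianRatioSizeFactors(counts(x))
  sweep(counts(x), 2, sf, "/")
}

#' FPKM expression matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \eqn{FPKM_{gj} = count_{gj} / (length_g[\mathrm{kb}] \cdot
#' total_j[\mathrm{millions}])}, with the per-sample total taken as the sum
#' of counts over the genes in the matrix.
#'
#' @param x an \linkS4class{InjuryRescueExperiment} with gene lengths, or a
#'   count matrix (then \code{lengths} is required).
#' @param lengths numeric gene lengths in base pairs (taken from
#'   \code{geneLengths(x)} when \code{x} is an InjuryRescueExperiment).
#' @return numeric matrix of FPKM values, same dimnames as the counts.
#' @examples
#' fpkm(matrix(c(100, 9999900), 2, dimnames = list(c("a", "b"), "s1")),
#'      lengths = c(2000, 1000))["a", ]  # 5
#' @export
fpkm <- function(x, lengths = NULL) {
  if (methods::is(x, "InjuryRescueExperiment")) {
    if (is.null(lengths)) lengths <- geneLengths(x)
    x <- counts(x)
  }
  x <- as.matrix(x)
  if (is.null(lengths)) {
    stop("gene lengths are required for FPKM")
  }
  if (!is.null(names(lengths))) lengths <- lengths[rownames(x)]
  bad <- !is.finite(lengths) | lengths <= 0
  if (any(bad)) {
    stop("missing or non-positive gene lengths for: ",
         paste(utils::head(rownames(x)[bad], 10), collapse = ", "))
  }
  totals <- colSums(x)
  sweep(x / (lengths / 1e3), 2, totals / 1e6, "/")
}

#' Pairwise replicate correlation on the log scale
#'
#' Pearson correlation of \code{log2(expr + 1)} between every pair of
#' samples; the standard replicate-quality check (same-arm pairs are
#' expected to exceed ~0.98 in clean data).
#'
#' @param expr FPKM (or other expression) matrix, genes by samples.
#' @return symmetric correlation matrix with unit diagonal; columns with
#'   zero variance give \code{NA} with a warning.
#' @export
replicateCorrelation <- function(expr) {
  lg <- log2(as.matrix(expr) + 1)
  sds <- apply(lg, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(lg)[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  }
  cc <- suppressWarnings(stats::cor(lg, method = "pearson"))
  diag(cc) <- ifelse(sds > 0, 1, NA_real_)
  cc
}

#' Sample PCA coordinates on a gene subset
#'
#' Principal components of centered \code{log2(expr + 1)} restricted to
#' \code{geneSubset} (typically the DEGs). Component signs are
#' canonicalized: the loading with the largest magnitude on each component
#' is made positive, so coordinates are reproducible.
#'
#' @param expr expression matrix, genes by samples.
#' @param geneSubset character vector of gene ids (>= 2 required).
#' @return list with \code{scores} (samples x components),
#'   \code{loadings}, and \code{varianceExplained} (proportions).
#' @export
pcaCoordinates <- function(expr, geneSubset = rownames(expr)) {
  geneSubset <- intersect(geneSubset, rownames(expr))
  if (length(geneSubset) < 2L) {
    stop("at least two genes are required for PCA")
  }
  lg <- t(log2(as.matrix(expr)[geneSubset, , drop = FALSE] + 1))
  pc <- stats::prcomp(lg, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, varianceExplained = ve)
}
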