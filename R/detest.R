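#' Method-of-moments NB dispersion estimates with trend shrinkage
#'
#' Per-gene raw estimates \eqn{\hat\alpha_g = \max(0, (s^2_g - \hat\mu_g) /
#' \hat\mu_g^2)} are computed on normalized counts within each contrast arm
#' (pooled with replicate-count weights), a dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} is fitted across genes by least
#' squares, and the reported value is the conservative maximum of the gene
#' estimate, the trend at the gene's mean, and the floor.
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @param contrast character of length 2, \code{c(numerator, denominator)}
#'   arm labels.
#' @param floor minimum reported dispersion (default 1e-8).
#' @return data.frame with gene_id, base_mean (mean normalized count over
#'   both arms), raw, trend, and dispersion (the shrunk value).
#' @export
estimateNBDispersions <- function(x, contrast, floor = 1e-8) {
  sel <- contrastColumns(x, contrast)
  norm <- normalizedCounts(x)[, c(sel$num, sel$den), drop = FALSE]
  arm <- rep(c("num", "den"), c(length(sel$num), length(sel$den)))
  mu <- rowMeans(norm)
  raw_num <- 0; wsum <- 0
  for (a in c("num", "den")) {
    sub <- norm[, arm == a, drop = FALSE]
    w <- ncol(sub) - 1L
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    est <- ifelse(m > 0, (v - m) / m^2, 0)
    raw_num <- raw_num + w * est
    wsum <- wsum + w
  }
  raw <- pmax(0, raw_num / wsum)
  ok <- mu > 0
  if (sum(ok) >= 3L) {
    fit <- stats::lm(raw[ok] ~ I(1 / mu[ok]))
    a0 <- max(stats::coef(fit)[1], floor)
    a1 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- floor; a1 <- 0
  }
  trend <- ifelse(ok, a0 + a1 / mu, floor)
  data.frame(gene_id = rownames(x), base_mean = mu, raw = raw,
             trend = trend, dispersion = pmax(raw, trend, floor),
             row.names = NULL, stringsAsFactors = FALSE)
}

contrastColumns <- function(x, contrast) {
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop("contrast must be two distinct arm labels c(numerator, denominator)")
  }
  a <- arms(x)
  missing_arm <- setdiff(contrast, a)
  if (length(missing_arm)) {
    stop("unknown arm label(s): ", paste(missing_arm, collapse = ", "))
  }
  num <- which(a == contrast[1]); den <- which(a == contrast[2])
  if (length(num) < 2L || length(den) < 2L) {
    stop("each contrast arm needs >= 2 replicates (no variance otherwise)")
  }
  list(num = num, den = den)
}

#' Negative-binomial Wald test for a two-arm contrast
#'
#' The log2 fold change is computed from mean normalized counts with a
#' pseudo-count, \eqn{\log_2((\bar q_1 + pc)/(\bar q_0 + pc))}, and tested
#' two-sidedly with a Wald statistic whose standard error comes from the
#' delta method under the NB variance model
#' \eqn{Var(K_{gj}) = s_j q_g + \alpha_g (s_j q_g)^2}. Genes with all-zero
#' counts in both arms get missing p-values and are excluded from the BH
#' ranking.
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @param contrast c(numerator arm, denominator arm).
#' @param dispersions optional data.frame from
#'   \code{\link{estimateNBDispersions}} (computed when missing).
#' @param pc pseudo-count on the normalized-count scale (default 0.5).
#' @return a \linkS4class{DEResults} object.
#' @examples
#' ire <- simulateCounts(simConfig(nGenes = 200, seed = 3))
#' res <- nbWaldTest(ire, c("ADM", "NC"))
#' head(as.data.frame(res))
#' @export
nbWaldTest <- function(x, contrast, dispersions = NULL, pc = 0.5) {
  sel <- contrastColumns(x, contrast)
  sf <- sizeFactors(x)
  if (is.null(sf)) {
    x <- addSizeFactors(x)
    sf <- sizeFactors(x)
  }
  if (is.null(dispersions)) dispersions <- estimateNBDispersions(x, contrast)
  alpha <- dispersions$dispersion[match(rownames(x), dispersions$gene_id)]
  norm <- sweep(counts(x), 2, sf, "/")
  q1 <- rowMeans(norm[, sel$num, drop = FALSE])
  q0 <- rowMeans(norm[, sel$den, drop = FALSE])
  lfc <- log2((q1 + pc) / (q0 + pc))
  varOfArmMean <- function(q, idx) {
    n <- length(idx)
    (q / n^2) * sum(1 / sf[idx]) + alpha * q^2 / n
  }
  v1 <- varOfArmMean(q1, sel$num)
  v0 <- varOfArmMean(q0, sel$den)
  se2 <- v1 / ((q1 + pc) * log(2))^2 + v0 / ((q0 + pc) * log(2))^2
  z <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  untested <- q1 == 0 & q0 == 0
  p[untested] <- NA_real_
  df <- S4Vectors::DataFrame(gene_id = rownames(x),
                             base_mean = (q1 + q0) / 2,
                             log2fc = lfc,
                             dispersion = alpha,
                             p_value = p,
                             fdr = bhAdjust(p))
  methods::new("DEResults", df, contrast = as.character(contrast))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts the non-missing p-values (m = number of non-missing values);
#' missing values stay missing.
#'
#' @param p numeric vector of p-values in [0, 1], possibly with NA.
#' @return adjusted values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed genes
#'
#' DEG rule: \code{fdr < fdrThreshold} and \code{|log2fc| >= lfcThreshold}
#' (the boundary is inclusive for the fold change).
#'
#' @param results a \linkS4class{DEResults} object or data.frame with
#'   columns gene_id, log2fc, fdr.
#' @param lfcThreshold minimum |log2 fold change| (default 0.5).
#' @param fdrThreshold FDR cutoff (default 0.05).
#' @return data.frame with gene_id, log2fc, fdr, direction ("up"/"down").
#' @export
callDEGs <- function(results, lfcThreshold = 0.5, fdrThreshold = 0.05) {
  df <- as.data.frame(results)
  keep <- !is.na(df$fdr) & df$fdr < fdrThreshold &
    abs(df$log2fc) >= lfcThreshold
  out <- df[keep, c("gene_id", "log2fc", "fdr")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
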