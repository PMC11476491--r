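#' Read a GMT gene-set file
#'
#' Tab-separated lines: term id, description, then member gene ids.
#'
#' @param path file path.
#' @param category category label stamped on every set (GMT does not carry
#'   one).
#' @return a \code{GeneSetCollection} (see \code{\link{simulateGeneSets}}).
#' @export
readGMT <- function(path, category = "gene_set") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, 0L) < 2L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  structure(list(
    term_id = vapply(fields, `[`, "", 1L),
    term_name = vapply(fields, `[`, "", 2L),
    category = rep(category, length(fields)),
    members = lapply(fields, function(f) unique(f[-(1:2)])),
    enriched = rep(NA, length(fields))
  ), class = "GeneSetCollection")
}

#' Write a GeneSetCollection as GMT
#'
#' @param sets a \code{GeneSetCollection}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(seq_along(sets$term_id), function(i) {
    paste(c(sets$term_id[i], sets$term_name[i], sets$members[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each term, with universe size N, term size K (after restriction to
#' the universe), query size n, and overlap k, the upper-tail p-value
#' \eqn{P(X \ge k)} of the hypergeometric distribution is computed exactly.
#' Terms with no overlap are reported with p = 1. The rich factor is k/K.
#'
#' @param query character vector of gene ids (restricted to the universe).
#' @param sets a \code{GeneSetCollection}.
#' @param universe character vector of background gene ids.
#' @return data.frame with term_id, term_name, category, N, K, n, k,
#'   rich_factor, p_value.
#' @export
hypergeomEnrich <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- intersect(unique(query), universe)
  if (!length(query)) {
    stop("empty query after restriction to the universe (nothing to test)")
  }
  N <- length(universe); n <- length(query)
  K <- vapply(sets$members, function(m) length(intersect(m, universe)), 0L)
  k <- vapply(sets$members, function(m) {
    length(intersect(intersect(m, universe), query))
  }, 0L)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(term_id = sets$term_id, term_name = sets$term_name,
             category = sets$category, N = N, K = K, n = n, k = k,
             rich_factor = ifelse(K > 0, k / K, NA_real_),
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Multiple-testing correction for enrichment results
#'
#' \code{bonferroni}: \eqn{\min(1, m p)} with m the number of testable
#' terms (K >= 1 in the universe), the GO-style correction;
#' \code{bh}: Benjamini-Hochberg step-up over the same terms, the
#' pathway-style correction. Both raw and corrected p are retained.
#'
#' @param results data.frame from \code{\link{hypergeomEnrich}}.
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @param threshold significance cutoff on the corrected p (default 0.05,
#'   inclusive).
#' @return \code{results} with columns corrected_p and significant added.
#' @export
correctPvalues <- function(results, method = c("bonferroni", "bh"),
                           threshold = 0.05) {
  method <- match.arg(method)
  if (!nrow(results)) stop("no enrichment results to correct")
  testable <- results$K >= 1L
  m <- sum(testable)
  cp <- rep(NA_real_, nrow(results))
  if (method == "bonferroni") {
    cp[testable] <- pmin(1, m * results$p_value[testable])
  } else {
    cp[testable] <- bhAdjust(results$p_value[testable])
  }
  results$corrected_p <- cp
  results$significant <- !is.na(cp) & cp <= threshold
  results
}

#' Enrichment tables per call-back level and direction
#'
#' Runs the hypergeometric test for each of the six query lists of one
#' treatment (levels 1-3 crossed with the up/down call-back classes) and
#' returns long-format tables including rich factor and category. Empty
#' query lists give empty tables with a warning.
#'
#' @param assignment output of \code{\link{classifyCallback}}.
#' @param sets a \code{GeneSetCollection}.
#' @param universe background gene ids (typically all genes tested in the
#'   DE contrast and annotated to at least one term).
#' @param method,threshold passed to \code{\link{correctPvalues}}.
#' @return data.frame stacking all six tables, with treatment, level, and
#'   direction_class columns prepended.
#' @export
enrichByLevel <- function(assignment, sets, universe,
                          method = c("bonferroni", "bh"), threshold = 0.05) {
  method <- match.arg(method)
  out <- list()
  for (lvl in c("1", "2", "3")) {
    for (dc in c("up-called-back", "down-called-back")) {
      query <- assignment$gene_id[assignment$level == lvl &
                                    assignment$direction %in%
                                    directionClassLevels(dc)]
      query <- intersect(query, universe)
      if (!length(query)) {
        warning("no level-", lvl, " ", dc, " genes in the universe; ",
                "empty table")
        next
      }
      res <- correctPvalues(hypergeomEnrich(query, sets, universe),
                            method = method, threshold = threshold)
      out[[paste(lvl, dc)]] <- cbind(
        treatment = assignment$treatment[1], level = lvl,
        direction_class = dc, res)
    }
  }
  if (!length(out)) {
    return(data.frame())
  }
  ans <- do.call(rbind, out)
  rownames(ans) <- NULL
  ans
}
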