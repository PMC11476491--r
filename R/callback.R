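#' Thresholds for the three-level call-back classification
#'
#' Defaults follow the published rule set: level 1 requires |log2FC| > 0.5
#' in both contrasts, level 2 requires > 0.1, level 3 requires a
#' non-significant model contrast (FDR > fdr) together with
#' |log2FC|_treatment > 0.1; all significance gates use FDR < 0.05. Note
#' the level thresholds are strict (">"), unlike the DEG rule's ">=".
#'
#' @param level1Lfc,level2Lfc,level3TreatLfc log2 fold-change thresholds.
#' @param fdr significance cutoff.
#' @return validated list of class \code{CallbackThresholds}.
#' @export
callbackThresholds <- function(level1Lfc = 0.5, level2Lfc = 0.1,
                               level3TreatLfc = 0.1, fdr = 0.05) {
  if (!(level1Lfc > level2Lfc && level2Lfc > 0)) {
    stop("thresholds must satisfy level1Lfc > level2Lfc > 0")
  }
  structure(list(level1Lfc = level1Lfc, level2Lfc = level2Lfc,
                 level3TreatLfc = level3TreatLfc, fdr = fdr),
            class = "CallbackThresholds")
}

#' Classify genes into call-back levels for one treatment
#'
#' Compares the injury contrast (model vs normal) with the treatment
#' contrast (treatment vs model) gene by gene:
#' \describe{
#'   \item{level 1}{|lfc| > 0.5 and FDR < 0.05 in both contrasts, with
#'     opposite signs — a strong call-back.}
#'   \item{level 2}{otherwise, the same pattern at the 0.1 threshold.}
#'   \item{level 3}{otherwise, model contrast non-significant (FDR > 0.05)
#'     but |lfc_treat| > 0.1 with FDR_treat < 0.05 — a treatment-specific
#'     change.}
#'   \item{none}{anything else, including same-direction changes and genes
#'     untested (all-zero) in either contrast.}
#' }
#' Directions: genes suppressed by injury and restored upward are
#' \emph{up-called-back}; the inverse pattern is \emph{down-called-back};
#' level-3 genes are \emph{treatment-up}/\emph{treatment-down} by the sign
#' of the treatment fold change. Levels are mutually exclusive, assigned in
#' order 1 then 2 then 3.
#'
#' @param modelDE \linkS4class{DEResults} (or data.frame) for model vs
#'   normal.
#' @param treatDE \linkS4class{DEResults} (or data.frame) for treatment vs
#'   model.
#' @param thresholds a \code{\link{callbackThresholds}} list.
#' @param treatment label recorded in the output (taken from
#'   \code{contrastArms(treatDE)} when available).
#' @return data.frame with gene_id, treatment, level
#'   (\code{"1","2","3","none"}), direction, lfc_model, fdr_model,
#'   lfc_treat, fdr_treat.
#' @export
classifyCallback <- function(modelDE, treatDE,
                             thresholds = callbackThresholds(),
                             treatment = NULL) {
  if (is.null(treatment)) {
    treatment <- if (methods::is(treatDE, "DEResults")) {
      contrastArms(treatDE)[1]
    } else "treatment"
  }
  m <- as.data.frame(modelDE)
  t <- as.data.frame(treatDE)
  extra_m <- setdiff(m$gene_id, t$gene_id)
  extra_t <- setdiff(t$gene_id, m$gene_id)
  if (length(extra_m) || length(extra_t)) {
    stop("DE tables cover different gene universes; asymmetric genes: ",
         paste(utils::head(c(extra_m, extra_t), 10), collapse = ", "))
  }
  t <- t[match(m$gene_id, t$gene_id), ]
  lm_ <- m$log2fc; fm <- m$fdr
  lt <- t$log2fc; ft <- t$fdr
  tested <- !is.na(fm) & !is.na(ft)
  f <- thresholds$fdr
  opp <- lm_ * lt < 0
  sig <- function(lfc_thr) {
    tested & abs(lm_) > lfc_thr & fm < f & abs(lt) > lfc_thr & ft < f & opp
  }
  lvl1 <- sig(thresholds$level1Lfc)
  lvl2 <- !lvl1 & sig(thresholds$level2Lfc)
  lvl3 <- !lvl1 & !lvl2 & tested & fm > f &
    abs(lt) > thresholds$level3TreatLfc & ft < f
  level <- rep("none", nrow(m))
  level[lvl3] <- "3"; level[lvl2] <- "2"; level[lvl1] <- "1"
  direction <- rep("none", nrow(m))
  called <- lvl1 | lvl2
  direction[called & lm_ < 0] <- "up-called-back"
  direction[called & lm_ > 0] <- "down-called-back"
  direction[lvl3 & lt > 0] <- "treatment-up"
  direction[lvl3 & lt < 0] <- "treatment-down"
  data.frame(gene_id = m$gene_id, treatment = treatment,
             level = level, direction = direction,
             lfc_model = lm_, fdr_model = fm,
             lfc_treat = lt, fdr_treat = ft,
             row.names = NULL, stringsAsFactors = FALSE)
}

directionClassLevels <- function(direction_class) {
  switch(direction_class,
         "up-called-back" = c("up-called-back", "treatment-up"),
         "down-called-back" = c("down-called-back", "treatment-down"),
         stop("unknown direction class: ", direction_class))
}

#' Shared and unique call-back genes across treatments
#'
#' For each level, intersects the gene sets of the requested direction
#' class across all treatments and reports per-treatment unique sets. For
#' levels 1 and 2 the class is the called-back direction; for level 3 the
#' corresponding treatment direction (up-called-back pairs with
#' treatment-up).
#'
#' @param assignments named list (by treatment) of
#'   \code{\link{classifyCallback}} outputs; >= 2 treatments.
#' @param directionClass \code{"up-called-back"} or
#'   \code{"down-called-back"}.
#' @return list with one element per level ("1","2","3"), each containing
#'   \code{perTreatment} (the gene sets), \code{shared}, \code{unique}
#'   (per treatment), and \code{counts}.
#' @export
sharedCallback <- function(assignments, directionClass = "up-called-back") {
  if (length(assignments) < 2L) stop("need >= 2 treatments to intersect")
  dirs <- directionClassLevels(directionClass)
  out <- list()
  for (lvl in c("1", "2", "3")) {
    sets <- lapply(assignments, function(a) {
      a$gene_id[a$level == lvl & a$direction %in% dirs]
    })
    shared <- Reduce(intersect, sets)
    uniq <- lapply(seq_along(sets), function(i) {
      setdiff(sets[[i]], unique(unlist(sets[-i])))
    })
    names(uniq) <- names(sets)
    out[[lvl]] <- list(perTreatment = sets, shared = shared, unique = uniq,
                       counts = c(shared = length(shared),
                                  vapply(sets, length, 0L)))
  }
  out
}

#' Exclusive intersection sizes over DEG lists (UpSet-style)
#'
#' Computes, for every non-empty combination of the input lists, the number
#' of genes belonging to exactly that combination. Sizes over all
#' combinations sum to the size of the union.
#'
#' @param lists named list (>= 2) of character vectors.
#' @return data.frame with one logical membership column per list, plus
#'   \code{combination} (names joined by "&"), \code{degree}, and
#'   \code{size}; sorted by degree then size.
#' @export
upsetCounts <- function(lists) {
  if (length(lists) < 2L) stop("need >= 2 lists")
  if (is.null(names(lists))) names(lists) <- paste0("set", seq_along(lists))
  universe <- unique(unlist(lists))
  memb <- vapply(lists, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(lists)))
  pat <- apply(memb, 1, paste, collapse = "")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(lists)))[-1, ,
                                                                  drop = FALSE]
  colnames(combos) <- names(lists)
  key <- apply(combos, 1, paste, collapse = "")
  size <- vapply(key, function(k) sum(pat == k), 0L)
  out <- cbind(combos,
               combination = apply(combos, 1, function(z) {
                 paste(names(lists)[as.logical(z)], collapse = "&")
               }),
               degree = rowSums(combos), size = size)
  rownames(out) <- NULL
  out[order(out$degree, -out$size), ]
}
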