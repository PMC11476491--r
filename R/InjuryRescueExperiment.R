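#' Construct an InjuryRescueExperiment
#'
#' @param counts integer gene-by-sample matrix with unique rownames (gene
#'   ids) and colnames (sample ids).
#' @param arms character vector (or factor) of arm labels, one per sample,
#'   or a named vector matching \code{colnames(counts)}.
#' @param geneLengths optional numeric vector of gene lengths in base pairs
#'   (required later only for FPKM); recycled by name when named.
#' @param normalArm,modelArm labels of the untreated control and the injury
#'   model arm.
#' @param replicate optional integer replicate index per sample; derived
#'   from the within-arm order when missing.
#' @param rowData,colData,metadata passed through to
#'   \code{\link[SummarizedExperiment]{SummarizedExperiment}} and augmented.
#'
#' @return An \linkS4class{InjuryRescueExperiment}.
#' @examples
#' cnt <- matrix(rpois(24, 50), 4,
#'               dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' ire <- InjuryRescueExperiment(cnt, rep(c("NC", "ADM"), each = 3))
#' arms(ire)
#' @export
InjuryRescueExperiment <- function(counts, arms, geneLengths = NULL,
                                   normalArm = "NC", modelArm = "ADM",
                                   replicate = NULL, rowData = NULL,
                                   colData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  }
  arms <- as.character(arms)
  if (!is.null(names(arms))) arms <- arms[colnames(counts)]
  if (length(arms) != ncol(counts)) {
    stop("'arms' must assign one arm to each of the ", ncol(counts),
         " samples")
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(arms), arms, FUN = seq_along)
  }
  cd <- S4Vectors::DataFrame(arm = arms, replicate = as.integer(replicate),
                             row.names = colnames(counts))
  if (!is.null(colData)) cd <- cbind(cd, S4Vectors::DataFrame(colData))
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(geneLengths)) {
    if (!is.null(names(geneLengths))) geneLengths <- geneLengths[rownames(counts)]
    rd$gene_length <- as.numeric(geneLengths)
  }
  if (!is.null(rowData)) rd <- cbind(rd, S4Vectors::DataFrame(rowData))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd,
    metadata = metadata)
  methods::new("InjuryRescueExperiment", se,
               normalArm = normalArm, modelArm = modelArm)
}

#' Arm assignment of each sample
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @return named character vector, one arm label per sample.
#' @name arms
#' @aliases arms,InjuryRescueExperiment-method
#' @export
setMethod("arms", "InjuryRescueExperiment", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$arm),
                  colnames(x))
})

#' Gene lengths in base pairs
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @return named numeric vector, or NULL when no lengths are attached.
#' @name geneLengths
#' @aliases geneLengths,InjuryRescueExperiment-method
#' @export
setMethod("geneLengths", "InjuryRescueExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"gene_length" %in% colnames(rd)) return(NULL)
  stats::setNames(as.numeric(rd$gene_length), rownames(x))
})

#' Treatment arms (all arms except normal control and model)
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @return character vector of treatment arm labels, in order of appearance.
#' @name treatmentArms
#' @aliases treatmentArms,InjuryRescueExperiment-method
#' @export
setMethod("treatmentArms", "InjuryRescueExperiment", function(x) {
  setdiff(unique(arms(x)), c(x@normalArm, x@modelArm))
})

#' Ground-truth table of a simulated experiment
#'
#' For objects created by \code{\link{simulateCounts}}, returns the per-gene
#' truth: archetype, true injury log2 effect (model vs normal), true rescue
#' log2 effect per treatment (treatment vs model), and the call-back level
#' each treatment is expected to assign. NULL for non-simulated objects.
#'
#' @param x an \linkS4class{InjuryRescueExperiment}.
#' @return data.frame or NULL.
#' @name simulationTruth
#' @aliases simulationTruth,InjuryRescueExperiment-method
#' @export
setMethod("simulationTruth", "InjuryRescueExperiment", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"archetype" %in% colnames(rd)) return(NULL)
  keep <- c("archetype", "baseline_mean", "true_injury_log2fc",
            grep("^(true_rescue_log2fc|expected_level)\\.",
                 colnames(rd), value = TRUE))
  out <- as.data.frame(rd[, intersect(keep, colnames(rd)), drop = FALSE])
  cbind(gene_id = rownames(x), out, row.names = NULL,
        stringsAsFactors = FALSE)
})

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "InjuryRescueExperiment", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' @importFrom BiocGenerics sizeFactors
#' @export
setMethod("sizeFactors", "InjuryRescueExperiment", function(object, ...) {
  cd <- SummarizedExperiment::colData(object)
  if (!"size_factor" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$size_factor, colnames(object))
})

#' @importFrom BiocGenerics sizeFactors<-
#' @export
setReplaceMethod("sizeFactors", "InjuryRescueExperiment",
  function(object, ..., value) {
    if (any(!is.finite(value)) || any(value <= 0)) {
      stop("size factors must be positive and finite")
    }
    SummarizedExperiment::colData(object)$size_factor <- as.numeric(value)
    object
  })

#' @export
setMethod("show", "InjuryRescueExperiment", function(object) {
  cat("class: InjuryRescueExperiment\n")
  cat("dim:", nrow(object), "genes x", ncol(object), "samples\n")
  tab <- table(arms(object))
  cat("arms:", paste0(names(tab), "(", tab, ")", collapse = " "), "\n")
  cat("normal:", object@normalArm, " model:", object@modelArm,
      " treatments:", paste(treatmentArms(object), collapse = ", "), "\n")
  if (!is.null(simulationTruth(object))) {
    cat("simulated: yes (ground truth in rowData)\n")
  }
})

#' Numerator/denominator arms of a DEResults object
#'
#' @param x a \linkS4class{DEResults} object.
#' @return character of length 2: numerator arm, denominator arm.
#' @name contrastArms
#' @aliases contrastArms,DEResults-method
#' @export
setMethod("contrastArms", "DEResults", function(x) x@contrast)

#' @export
setMethod("show", "DEResults", function(object) {
  cat("DEResults:", object@contrast[1], "vs", object@contrast[2],
      "(", nrow(object), "genes )\n")
  methods::callNextMethod()
})
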