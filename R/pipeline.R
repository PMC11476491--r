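#' Validate pipeline input files
#'
#' Checks TSV schemas, arm coverage, gene-id consistency across files, and
#' GMT well-formedness. Every violation is reported, not just the first.
#'
#' @param countsPath,samplesPath counts matrix and sample sheet (required).
#' @param lengthsPath,gmtPath,ctPath optional further inputs.
#' @return data.frame with columns file, location, message; zero rows for
#'   a clean set of inputs.
#' @export
validateInputs <- function(countsPath, samplesPath, lengthsPath = NULL,
                           gmtPath = NULL, ctPath = NULL) {
  v <- list()
  note <- function(file, location, message) {
    v[[length(v) + 1L]] <<- data.frame(file = file, location = location,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  cnt <- tryCatch(utils::read.delim(countsPath, check.names = FALSE),
                  error = function(e) {
                    note(countsPath, "-", conditionMessage(e)); NULL
                  })
  ss <- tryCatch(utils::read.delim(samplesPath),
                 error = function(e) {
                   note(samplesPath, "-", conditionMessage(e)); NULL
                 })
  gene_ids <- NULL
  if (!is.null(cnt)) {
    if (colnames(cnt)[1] != "gene_id") {
      note(countsPath, "header", "first column must be 'gene_id'")
    } else {
      gene_ids <- cnt$gene_id
      if (anyDuplicated(gene_ids)) {
        note(countsPath, "column gene_id", "gene ids must be unique")
      }
      mat <- as.matrix(cnt[, -1, drop = FALSE])
      bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat),
                   arr.ind = TRUE)
      for (i in seq_len(min(nrow(bad), 20))) {
        note(countsPath,
             paste0("row ", bad[i, 1] + 1L, ", column ",
                    colnames(mat)[bad[i, 2]]),
             "non-negative integers required")
      }
    }
  }
  if (!is.null(ss)) {
    miss <- setdiff(c("sample_id", "arm"), colnames(ss))
    if (length(miss)) {
      note(samplesPath, "header",
           paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      if (!is.null(cnt) && colnames(cnt)[1] == "gene_id") {
        for (s in setdiff(colnames(cnt)[-1], ss$sample_id)) {
          note(countsPath, paste("column", s),
               "sample absent from sample sheet")
        }
        for (s in setdiff(ss$sample_id, colnames(cnt)[-1])) {
          note(samplesPath, paste("sample", s),
               "sample absent from counts matrix")
        }
      }
      tab <- table(ss$arm)
      for (a in names(tab)[tab < 2]) {
        note(samplesPath, paste("arm", a),
             "arms need >= 2 samples for any tested contrast")
      }
    }
  }
  if (!is.null(lengthsPath)) {
    lt <- tryCatch(utils::read.delim(lengthsPath),
                   error = function(e) {
                     note(lengthsPath, "-", conditionMessage(e)); NULL
                   })
    if (!is.null(lt)) {
      miss <- setdiff(c("gene_id", "gene_length"), colnames(lt))
      if (length(miss)) {
        note(lengthsPath, "header",
             paste("missing column(s):", paste(miss, collapse = ", ")))
      } else if (!is.null(gene_ids)) {
        absent <- setdiff(gene_ids, lt$gene_id)
        if (length(absent)) {
          note(lengthsPath, "column gene_id",
               paste("lengths missing for", length(absent), "genes"))
        }
      }
    }
  }
  if (!is.null(gmtPath)) {
    tryCatch(readGMT(gmtPath),
             error = function(e) note(gmtPath, "-", conditionMessage(e)))
  }
  if (!is.null(ctPath)) {
    tryCatch(readCtTable(ctPath),
             error = function(e) note(ctPath, "-", conditionMessage(e)))
  }
  if (!length(v)) {
    return(data.frame(file = character(0), location = character(0),
                      message = character(0)))
  }
  do.call(rbind, v)
}

#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file; top-level keys as in \code{\link{runAll}}'s
#'   \code{config}.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

pickQpcrGenes <- function(truth, nGenes = 13L) {
  cand <- truth[truth$archetype %in% c("restored_up", "restored_down"), ]
  cand <- cand[order(-cand$baseline_mean), ]
  targets <- utils::head(cand$gene_id, nGenes)
  ref_cand <- truth[truth$archetype == "null", ]
  ref <- ref_cand$gene_id[which.max(ref_cand$baseline_mean)]
  list(targets = targets, reference = ref)
}

#' Run the full injury-rescue analysis pipeline
#'
#' Executes simulate (or load) -> validate -> quantify -> DE testing ->
#' call-back classification -> enrichment -> qPCR concordance, writing one
#' tab-separated file per result plus a deterministic JSON manifest. Stage
#' timings and progress go to the message stream. Re-running with the same
#' config and seed reproduces every output file byte-identically.
#'
#' @param config list with either a \code{sim} block (arguments to
#'   \code{\link{simConfig}}) or an \code{inputs} block (paths: counts,
#'   samples, and optionally lengths, gmt, ct), plus optional
#'   \code{thresholds} (arguments to \code{\link{callbackThresholds}}),
#'   \code{deg} (lfc, fdr), \code{enrich} (method, threshold),
#'   \code{geneSets} (nSets, setSizeRange, enrichedFraction) and
#'   \code{qpcr} (nGenes, noiseSD) blocks for simulation mode.
#' @param outdir output directory (created if needed).
#' @param seed integer master seed for every stochastic stage.
#' @return invisibly, the manifest list.
#' @export
runAll <- function(config = list(), outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  manifest <- list(package = "CallbackSeq",
                   version = as.character(utils::packageVersion("CallbackSeq")),
                   seed = seed, config = config, stages = list())
  failed <- function(stage, e) {
    jsonlite::write_json(list(failed_stage = stage,
                              message = conditionMessage(e)),
                         file.path(outdir, "error.json"), auto_unbox = TRUE)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) failed(name, e))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  simMode <- is.null(config$inputs)
  thr <- do.call(callbackThresholds,
                 if (is.null(config$thresholds)) list() else config$thresholds)
  deg <- utils::modifyList(list(lfc = 0.5, fdr = 0.05),
                           if (is.null(config$deg)) list() else config$deg)
  enr <- utils::modifyList(list(method = "bonferroni", threshold = 0.05),
                           if (is.null(config$enrich)) list()
                           else config$enrich)

  gsc <- NULL; ctTable <- NULL
  if (simMode) {
    ire <- stage("simulate", {
      sc <- do.call(simConfig, utils::modifyList(
        if (is.null(config$sim)) list() else config$sim, list(seed = seed)))
      obj <- simulateCounts(sc)
      writeTSV(as.data.frame(counts(obj)), file.path(outdir, "counts.tsv"),
               rownamesCol = "gene_id")
      writeTSV(data.frame(sample_id = colnames(obj), arm = arms(obj),
                          replicate = SummarizedExperiment::colData(obj)$replicate,
                          depth_factor = SummarizedExperiment::colData(obj)$depth_factor),
               file.path(outdir, "samples.tsv"))
      truth <- simulationTruth(obj)
      writeTSV(truth, file.path(outdir, "truth.tsv"))
      gs_args <- utils::modifyList(list(nSets = 50L,
                                        setSizeRange = c(10L, 50L),
                                        enrichedFraction = 0.2),
                                   if (is.null(config$geneSets)) list()
                                   else config$geneSets)
      gsc <- do.call(simulateGeneSets,
                      c(list(truth = truth, seed = seed + 1L), gs_args))
      writeGMT(gsc, file.path(outdir, "genesets.gmt"))
      qp <- utils::modifyList(list(nGenes = 13L, noiseSD = 0.2),
                              if (is.null(config$qpcr)) list()
                              else config$qpcr)
      picks <- pickQpcrGenes(truth, qp$nGenes)
      ctTable <- simulateCtTable(truth, picks$targets, picks$reference,
                                  seed = seed + 2L, noiseSD = qp$noiseSD)
      writeTSV(ctTable, file.path(outdir, "ct.tsv"))
      manifest$stages$simulate <- list(genes = nrow(obj),
                                        samples = ncol(obj),
                                        gene_sets = length(gsc$term_id),
                                        qpcr_genes = length(picks$targets))
      obj
    })
  } else {
    ire <- stage("load", {
      inp <- config$inputs
      report <- validateInputs(inp$counts, inp$samples, inp$lengths,
                               inp$gmt, inp$ct)
      if (nrow(report)) {
        writeTSV(report, file.path(outdir, "validation.tsv"))
        stop("input validation failed with ", nrow(report),
             " violation(s); see validation.tsv")
      }
      if (!is.null(inp$gmt)) gsc <- readGMT(inp$gmt)
      if (!is.null(inp$ct)) ctTable <- readCtTable(inp$ct)
      obj <- readCountMatrix(inp$counts, inp$samples, inp$lengths)
      manifest$stages$load <- list(genes = nrow(obj), samples = ncol(obj))
      obj
    })
  }

  ire <- stage("quantify", {
    obj <- addSizeFactors(ire)
    writeTSV(data.frame(sample_id = colnames(obj),
                        size_factor = sizeFactors(obj)),
             file.path(outdir, "size_factors.tsv"))
    if (!is.null(geneLengths(obj))) {
      fk <- fpkm(obj)
      writeTSV(as.data.frame(fk), file.path(outdir, "fpkm.tsv"),
               rownamesCol = "gene_id")
      cc <- replicateCorrelation(fk)
      writeTSV(as.data.frame(cc), file.path(outdir, "correlation.tsv"),
               rownamesCol = "sample_id")
    }
    manifest$stages$quantify <- list(size_factors = ncol(obj))
    obj
  })

  treatments <- treatmentArms(ire)
  contrasts <- c(list(c(ire@modelArm, ire@normalArm)),
                 lapply(treatments, function(t) c(t, ire@modelArm)),
                 lapply(treatments, function(t) c(t, ire@normalArm)))
  deList <- stage("detest", {
    res <- lapply(contrasts, function(ct) nbWaldTest(ire, ct))
    names(res) <- vapply(contrasts, paste, "", collapse = "_vs_")
    for (nm in names(res)) {
      writeTSV(as.data.frame(res[[nm]]),
               file.path(outdir, paste0("de_", nm, ".tsv")))
    }
    manifest$stages$detest <- list(
      contrasts = length(res),
      degs = lapply(res, function(r) nrow(callDEGs(r, deg$lfc, deg$fdr))))
    res
  })

  stage("pca", {
    if (!is.null(geneLengths(ire))) {
      degs <- unique(unlist(lapply(deList, function(r) {
        callDEGs(r, deg$lfc, deg$fdr)$gene_id
      })))
      if (length(degs) >= 2L) {
        pc <- pcaCoordinates(fpkm(ire), degs)
        writeTSV(as.data.frame(pc$scores),
                 file.path(outdir, "pca_scores.tsv"),
                 rownamesCol = "sample_id")
        manifest$stages$pca <- list(genes = length(degs))
      }
    }
  })

  assignments <- NULL
  if (length(treatments)) {
    assignments <- stage("callback", {
      model_nm <- paste(c(ire@modelArm, ire@normalArm), collapse = "_vs_")
      asg <- lapply(treatments, function(t) {
        classifyCallback(deList[[model_nm]],
                         deList[[paste(c(t, ire@modelArm),
                                       collapse = "_vs_")]],
                         thresholds = thr, treatment = t)
      })
      names(asg) <- treatments
      for (t in treatments) {
        writeTSV(asg[[t]], file.path(outdir, paste0("callback_", t, ".tsv")))
      }
      if (length(treatments) >= 2L) {
        for (dc in c("up-called-back", "down-called-back")) {
          sh <- sharedCallback(asg, dc)
          tab <- do.call(rbind, lapply(names(sh), function(lvl) {
            data.frame(level = lvl,
                       direction_class = dc,
                       shared = length(sh[[lvl]]$shared),
                       t(vapply(sh[[lvl]]$unique, length, 0L)),
                       shared_genes = paste(sh[[lvl]]$shared,
                                            collapse = ","),
                       stringsAsFactors = FALSE)
          }))
          writeTSV(tab, file.path(outdir,
                                  paste0("shared_",
                                         sub("-called-back", "", dc),
                                         ".tsv")))
        }
      }
      degLists <- lapply(deList, function(r) {
        callDEGs(r, deg$lfc, deg$fdr)$gene_id
      })
      degLists <- degLists[vapply(degLists, length, 0L) > 0]
      if (length(degLists) >= 2L) {
        writeTSV(upsetCounts(degLists), file.path(outdir, "upset_counts.tsv"))
      }
      manifest$stages$callback <- list(
        levels = lapply(asg, function(a) as.list(table(a$level))))
      asg
    })
  } else {
    message("[callback] no treatment arms: nothing to do")
  }

  if (!is.null(gsc) && !is.null(assignments)) {
    stage("enrich", {
      rows <- 0L
      for (t in treatments) {
        tested <- deList[[paste(c(t, ire@modelArm), collapse = "_vs_")]]
        universe <- intersect(
          tested$gene_id[!is.na(tested$p_value)],
          unique(unlist(gsc$members)))
        tab <- suppressWarnings(
          enrichByLevel(assignments[[t]], gsc, universe,
                        method = enr$method, threshold = enr$threshold))
        writeTSV(tab, file.path(outdir, paste0("enrichment_", t, ".tsv")))
        rows <- rows + nrow(tab)
      }
      manifest$stages$enrich <- list(rows = rows)
    })
  }

  if (!is.null(ctTable)) {
    stage("qpcr", {
      rel <- ddct(ctTable, calibratorArm = ire@normalArm)
      writeTSV(rel, file.path(outdir, "qpcr_relative.tsv"))
      conc_contrasts <- c(paste(c(ire@modelArm, ire@normalArm),
                                collapse = "_vs_"),
                          vapply(treatments, function(t) {
                            paste(c(t, ire@modelArm), collapse = "_vs_")
                          }, ""))
      conc <- qpcrConcordance(rel, deList[conc_contrasts],
                              modelArm = ire@modelArm,
                              calibratorArm = ire@normalArm)
      writeTSV(data.frame(metric = c("pearson_r", "sign_agreement",
                                     "p_value", "n_pairs"),
                          value = c(conc$correlation, conc$sign_agreement,
                                    conc$p_value, conc$n)),
               file.path(outdir, "qpcr_concordance.tsv"))
      writeTSV(conc$pairs, file.path(outdir, "qpcr_pairs.tsv"))
      manifest$stages$qpcr <- list(pairs = conc$n)
    })
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
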