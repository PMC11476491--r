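#' Simulation configuration for injury-rescue count data
#'
#' Defines the design the generator emulates: a normal control arm
#' (\code{NC}), an injured model arm (\code{ADM}) and treatment arms
#' (default \code{W1CC}, \code{W5CC}), three replicates each, with
#' negative-binomial counts whose dispersion follows the trend
#' \eqn{\alpha(\mu) = \alpha_0 + \alpha_1/\mu} (so that
#' \eqn{Var = \mu + \alpha\mu^2}).
#'
#' Every gene is drawn from one of six archetypes:
#' \describe{
#'   \item{restored_up}{suppressed by injury, fully restored upward by every
#'     treatment (the up-called-back pattern).}
#'   \item{restored_down}{induced by injury, restored downward.}
#'   \item{partial_restored}{injured, but treatments reverse only
#'     \code{partialRescueFraction} of the injury effect (rebound without
#'     reaching normal).}
#'   \item{injury_only}{injured, no treatment response.}
#'   \item{treatment_only}{unaltered by injury, shifted by treatment
#'     (the level-3 pattern).}
#'   \item{null}{no effects at all.}
#' }
#'
#' @param nGenes number of genes.
#' @param nReplicates replicates per arm (>= 2 so variances are estimable).
#' @param treatments character vector of treatment arm labels.
#' @param baselineLog2MeanRange range of per-gene baseline log2 mean counts;
#'   baselines are drawn log-uniform over this range.
#' @param dispersion numeric of length 2, \code{c(alpha0, alpha1)} of the
#'   dispersion trend \eqn{\alpha_0 + \alpha_1/\mu}.
#' @param archetypeFractions named numeric over the six archetypes, summing
#'   to 1 (tolerance 1e-9).
#' @param injuryLog2FC magnitude of the injury effect (model vs normal).
#' @param rescueFraction fraction of the injury effect reversed by each
#'   treatment for restored archetypes (1 = full rescue).
#' @param partialRescueFraction rescue fraction for the partial_restored
#'   archetype (default 0.3, exercising the level-2-but-not-level-1 band).
#' @param librarySizeLogSD standard deviation of per-sample log depth
#'   factors (lognormal, fixed per sample, exposed in colData).
#' @param seed integer seed; identical configs give bit-identical data.
#'
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nGenes = 2000L,
                      nReplicates = 3L,
                      treatments = c("W1CC", "W5CC"),
                      baselineLog2MeanRange = c(3, 13),
                      dispersion = c(alpha0 = 0.05, alpha1 = 1),
                      archetypeFractions = c(restored_up = 0.15,
                                             restored_down = 0.15,
                                             partial_restored = 0.10,
                                             injury_only = 0.10,
                                             treatment_only = 0.10,
                                             null = 0.40),
                      injuryLog2FC = 1.5,
                      rescueFraction = 1,
                      partialRescueFraction = 0.3,
                      librarySizeLogSD = 0.1,
                      seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes),
              nReplicates = as.integer(nReplicates),
              treatments = as.character(treatments),
              baselineLog2MeanRange = as.numeric(baselineLog2MeanRange),
              dispersion = as.numeric(dispersion),
              archetypeFractions = archetypeFractions,
              injuryLog2FC = as.numeric(injuryLog2FC),
              rescueFraction = as.numeric(rescueFraction),
              partialRescueFraction = as.numeric(partialRescueFraction),
              librarySizeLogSD = as.numeric(librarySizeLogSD),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

ARCHETYPES <- c("restored_up", "restored_down", "partial_restored",
                "injury_only", "treatment_only", "null")

validateSimConfig <- function(cfg) {
  af <- cfg$archetypeFractions
  if (!all(ARCHETYPES %in% names(af)) || length(af) != 6L) {
    stop("archetypeFractions must name exactly the six archetypes: ",
         paste(ARCHETYPES, collapse = ", "))
  }
  if (abs(sum(af) - 1) > 1e-9) {
    stop("archetypeFractions must sum to 1 (got ", sum(af), ")")
  }
  if (any(af < 0)) stop("archetypeFractions must be non-negative")
  if (cfg$nReplicates < 2L) {
    stop("nReplicates must be >= 2 so variances are estimable")
  }
  if (length(cfg$dispersion) != 2L || cfg$dispersion[1] <= 0 ||
      cfg$dispersion[2] < 0) {
    stop("dispersion must be c(alpha0 > 0, alpha1 >= 0) so that ",
         "alpha(mu) > 0 for all simulated means")
  }
  if (length(cfg$baselineLog2MeanRange) != 2L ||
      any(!is.finite(cfg$baselineLog2MeanRange))) {
    stop("baselineLog2MeanRange must be a finite pair")
  }
  for (p in c("injuryLog2FC", "rescueFraction", "partialRescueFraction",
              "librarySizeLogSD")) {
    if (!is.finite(cfg[[p]])) stop("non-finite value for parameter '", p, "'")
  }
  maxlog2 <- max(cfg$baselineLog2MeanRange) + abs(cfg$injuryLog2FC) *
    (1 + abs(cfg$rescueFraction))
  if (!is.finite(2^maxlog2)) {
    stop("non-finite simulated mean: reduce 'baselineLog2MeanRange' or ",
         "'injuryLog2FC'")
  }
  invisible(cfg)
}

#' Expected call-back level implied by true effects
#'
#' Applies the three-level classification rules to noiseless true effects:
#' statistical significance corresponds to a nonzero true effect, and
#' "unaltered after injury" to a true injury effect of exactly zero.
#' Level 1: both |effects| > \code{level1Lfc} with opposite signs;
#' level 2: both > \code{level2Lfc} with opposite signs;
#' level 3: injury effect 0 and |treatment effect| > \code{level3TreatLfc}.
#'
#' @param injuryLfc,rescueLfc numeric vectors of true log2 effects
#'   (model vs normal; treatment vs model).
#' @param thresholds a \code{\link{callbackThresholds}} list.
#' @return character vector over \code{c("1","2","3","none")}.
#' @export
expectedCallbackLevel <- function(injuryLfc, rescueLfc,
                                  thresholds = callbackThresholds()) {
  t1 <- thresholds$level1Lfc; t2 <- thresholds$level2Lfc
  t3 <- thresholds$level3TreatLfc
  opp <- injuryLfc * rescueLfc < 0
  lvl1 <- abs(injuryLfc) > t1 & abs(rescueLfc) > t1 & opp
  lvl2 <- !lvl1 & abs(injuryLfc) > t2 & abs(rescueLfc) > t2 & opp
  lvl3 <- !lvl1 & !lvl2 & injuryLfc == 0 & abs(rescueLfc) > t3
  out <- rep("none", length(injuryLfc))
  out[lvl3] <- "3"; out[lvl2] <- "2"; out[lvl1] <- "1"
  out
}

#' Simulate an injury-rescue count dataset with ground truth
#'
#' Draws negative-binomial counts \eqn{K_{gj} \sim NB(s_j q_{g,arm(j)},
#' \alpha(q))} where the arm-level expected expression applies the gene's
#' true log2 effects to its baseline, \eqn{s_j} is the sample's depth
#' factor, and \eqn{\alpha(\mu) = \alpha_0 + \alpha_1/\mu}. The returned
#' object carries the full truth table (archetype, true effects, expected
#' call-back level per treatment) in \code{rowData} and the depth factors in
#' \code{colData}, so downstream recovery is testable.
#'
#' @param config a \code{\link{simConfig}} object.
#' @return an \linkS4class{InjuryRescueExperiment}.
#' @examples
#' ire <- simulateCounts(simConfig(nGenes = 100, seed = 7))
#' head(simulationTruth(ire))
#' @export
simulateCounts <- function(config = simConfig()) {
  validateSimConfig(config)
  withr::with_seed(config$seed, {
    n <- config$nGenes
    nr <- config$nReplicates
    arms_all <- c("NC", "ADM", config$treatments)
    arm <- rep(arms_all, each = nr)
    sample_id <- paste(arm, rep(seq_len(nr), times = length(arms_all)),
                       sep = "_")

    n_arch <- floor(config$archetypeFractions[ARCHETYPES] * n)
    rem <- n - sum(n_arch)
    if (rem > 0) {
      top <- order(config$archetypeFractions[ARCHETYPES] * n - n_arch,
                   decreasing = TRUE)[seq_len(rem)]
      n_arch[top] <- n_arch[top] + 1L
    }
    archetype <- rep(ARCHETYPES, times = n_arch)

    mag <- config$injuryLog2FC
    rand_sign <- function(k) sample(c(-1, 1), k, replace = TRUE)
    injury <- numeric(n)
    injury[archetype == "restored_up"] <- -mag
    injury[archetype == "restored_down"] <- mag
    ip <- archetype == "partial_restored"
    injury[ip] <- mag * rand_sign(sum(ip))
    io <- archetype == "injury_only"
    injury[io] <- mag * rand_sign(sum(io))
    treat_sign <- numeric(n)
    tt <- archetype == "treatment_only"
    treat_sign[tt] <- rand_sign(sum(tt))

    rescue <- numeric(n)
    ir <- archetype %in% c("restored_up", "restored_down")
    rescue[ir] <- -config$rescueFraction * injury[ir]
    rescue[ip] <- -config$partialRescueFraction * injury[ip]
    rescue[tt] <- mag * treat_sign[tt]

    baseline <- 2^stats::runif(n, config$baselineLog2MeanRange[1],
                               config$baselineLog2MeanRange[2])
    gene_length <- round(stats::runif(n, 500, 5000))
    depth <- exp(stats::rnorm(length(arm), 0, config$librarySizeLogSD))

    a0 <- config$dispersion[1]; a1 <- config$dispersion[2]
    cnt <- matrix(0L, n, length(arm))
    for (j in seq_along(arm)) {
      e <- switch(arm[j],
                  NC = 0,
                  ADM = injury,
                  injury + rescue)  # every treatment applies the same rescue
      q <- baseline * 2^e
      if (any(!is.finite(q))) {
        stop("non-finite simulated mean for parameter 'injuryLog2FC' / ",
             "'baselineLog2MeanRange'")
      }
      alpha <- a0 + a1 / q
      cnt[, j] <- stats::rnbinom(n, mu = depth[j] * q, size = 1 / alpha)
    }
    rownames(cnt) <- sprintf("gene_%05d", seq_len(n))
    colnames(cnt) <- sample_id

    rd <- S4Vectors::DataFrame(archetype = archetype,
                               baseline_mean = baseline,
                               true_injury_log2fc = injury,
                               row.names = rownames(cnt))
    thr <- callbackThresholds()
    for (tr in config$treatments) {
      rd[[paste0("true_rescue_log2fc.", tr)]] <- rescue
      rd[[paste0("expected_level.", tr)]] <-
        expectedCallbackLevel(injury, rescue, thr)
    }
    InjuryRescueExperiment(cnt, arms = arm,
                           geneLengths = gene_length,
                           rowData = rd,
                           colData = S4Vectors::DataFrame(depth_factor = depth),
                           metadata = list(sim_config = config))
  })
}

#' Simulate gene-set annotations matched to a simulation truth
#'
#' Builds \code{nSets} gene sets over the simulated gene universe. A stated
#' fraction are "truly enriched": they oversample restored-archetype genes
#' (restored_up, restored_down, partial_restored) at rate
#' \code{restoredMemberFraction}; the rest are uniform draws. The enriched
#' flag is returned so that enrichment rankings can be validated.
#'
#' @param truth data.frame from \code{\link{simulationTruth}}.
#' @param nSets number of gene sets.
#' @param setSizeRange integer pair, inclusive range of set sizes.
#' @param enrichedFraction fraction of sets built as truly enriched.
#' @param seed integer seed.
#' @param restoredMemberFraction fraction of an enriched set drawn from the
#'   restored-archetype pool (default 0.8).
#' @param category category label stamped on every set.
#' @return a \code{GeneSetCollection}: list with elements \code{term_id},
#'   \code{term_name}, \code{category}, \code{members} (list of character
#'   vectors), \code{enriched} (logical). GMT-serializable via
#'   \code{\link{writeGMT}}.
#' @export
simulateGeneSets <- function(truth, nSets = 50L, setSizeRange = c(10L, 50L),
                             enrichedFraction = 0.2, seed = 1L,
                             restoredMemberFraction = 0.8,
                             category = "biological_process") {
  if (enrichedFraction < 0 || enrichedFraction > 1) {
    stop("enrichedFraction must be in [0, 1]")
  }
  if (max(setSizeRange) > nrow(truth)) {
    stop("set sizes must not exceed the number of genes")
  }
  genes <- truth$gene_id
  restored <- genes[truth$archetype %in%
                      c("restored_up", "restored_down", "partial_restored")]
  other <- setdiff(genes, restored)
  withr::with_seed(seed, {
    nSets <- as.integer(nSets)
    n_enriched <- round(enrichedFraction * nSets)
    enriched <- rep(c(TRUE, FALSE), c(n_enriched, nSets - n_enriched))
    sizes <- if (nSets) {
      sample(seq(setSizeRange[1], setSizeRange[2]), nSets, replace = TRUE)
    } else integer(0)
    members <- vector("list", nSets)
    for (i in seq_len(nSets)) {
      if (enriched[i] && length(restored)) {
        k_r <- min(round(restoredMemberFraction * sizes[i]), length(restored))
        members[[i]] <- c(sample(restored, k_r),
                          sample(other, sizes[i] - k_r))
      } else {
        members[[i]] <- sample(genes, sizes[i])
      }
    }
    structure(list(term_id = sprintf("SET:%04d", seq_len(nSets)),
                   term_name = sprintf("simulated_set_%04d", seq_len(nSets)),
                   category = rep(category, nSets),
                   members = members,
                   enriched = enriched),
              class = "GeneSetCollection")
  })
}

#' Simulate a qPCR Ct table consistent with a simulation truth
#'
#' Ct values follow the inverse of the 2^-ddCt model:
#' \eqn{Ct = Ct_{base} - \log_2(\mathrm{relative\ expression\ in\ arm}) +
#' \epsilon}, with Gaussian cycle noise of standard deviation
#' \code{noiseSD}. The reference gene must have the null archetype so its
#' Ct is constant across arms up to noise.
#'
#' @param truth data.frame from \code{\link{simulationTruth}}.
#' @param genes target gene ids (subset of the truth's genes).
#' @param referenceGene id of the reference (normalizer) gene.
#' @param seed integer seed.
#' @param noiseSD Gaussian Ct noise in cycles (default 0.2).
#' @param baseCt baseline Ct at normal expression (default 20 cycles).
#' @param nReplicates replicates per arm (default 3).
#' @return data.frame with columns gene_id, sample_id, arm, ct,
#'   is_reference.
#' @export
simulateCtTable <- function(truth, genes, referenceGene, seed = 1L,
                            noiseSD = 0.2, baseCt = 20, nReplicates = 3L) {
  if (!all(genes %in% truth$gene_id)) {
    stop("unknown gene ids: ",
         paste(setdiff(genes, truth$gene_id), collapse = ", "))
  }
  ref_row <- truth[truth$gene_id == referenceGene, , drop = FALSE]
  if (nrow(ref_row) != 1L || ref_row$archetype != "null") {
    stop("reference gene must be present with the null archetype ",
         "(invalid normalizer)")
  }
  treatments <- sub("^true_rescue_log2fc\\.", "",
                    grep("^true_rescue_log2fc\\.", colnames(truth),
                         value = TRUE))
  arms_all <- c("NC", "ADM", treatments)
  all_genes <- unique(c(genes, referenceGene))
  tt <- truth[match(all_genes, truth$gene_id), , drop = FALSE]
  log2rel <- function(arm) {
    if (arm == "NC") return(rep(0, nrow(tt)))
    if (arm == "ADM") return(tt$true_injury_log2fc)
    tt$true_injury_log2fc + tt[[paste0("true_rescue_log2fc.", arm)]]
  }
  withr::with_seed(seed, {
    rows <- list()
    for (arm in arms_all) {
      lr <- log2rel(arm)
      for (r in seq_len(nReplicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = all_genes,
          sample_id = paste(arm, r, sep = "_"),
          arm = arm,
          ct = baseCt - lr + stats::rnorm(length(all_genes), 0, noiseSD),
          is_reference = all_genes == referenceGene,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
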