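test_that("config validation rejects impossible designs", {
  expect_error(simConfig(nReplicates = 1), "variances")
  expect_error(simConfig(archetypeFractions = c(restored_up = 0.5,
                                                restored_down = 0.5,
                                                partial_restored = 0,
                                                injury_only = 0,
                                                treatment_only = 0,
                                                null = 0.1)),
               "sum to 1")
  expect_error(simConfig(dispersion = c(0, 0)), "alpha")
  expect_error(simConfig(baselineLog2MeanRange = c(3, 2000),
                         injuryLog2FC = 500), "non-finite")
})

test_that("an all-null design carries zero effects and no expected levels", {
  cfg <- simConfig(nGenes = 50,
                   archetypeFractions = c(restored_up = 0, restored_down = 0,
                                          partial_restored = 0,
                                          injury_only = 0,
                                          treatment_only = 0, null = 1),
                   seed = 11)
  tr <- simulationTruth(simulateCounts(cfg))
  expect_true(all(tr$archetype == "null"))
  expect_true(all(tr$true_injury_log2fc == 0))
  expect_true(all(tr$true_rescue_log2fc.W1CC == 0))
  expect_true(all(tr$expected_level.W1CC == "none"))
})

test_that("same config and seed give bit-identical data", {
  cfg <- simConfig(nGenes = 80, seed = 5)
  a <- simulateCounts(cfg)
  b <- simulateCounts(cfg)
  expect_identical(counts(a), counts(b))
  expect_identical(simulationTruth(a), simulationTruth(b))
  expect_false(identical(counts(a),
                         counts(simulateCounts(simConfig(nGenes = 80,
                                                         seed = 6)))))
})

test_that("sample means converge to baselines at vanishing dispersion", {
  cfg <- simConfig(nGenes = 150, nReplicates = 50,
                   baselineLog2MeanRange = c(7, 10),
                   dispersion = c(1e-6, 0), librarySizeLogSD = 0,
                   archetypeFractions = c(restored_up = 0, restored_down = 0,
                                          partial_restored = 0,
                                          injury_only = 0,
                                          treatment_only = 0, null = 1),
                   seed = 21)
  ire <- simulateCounts(cfg)
  tr <- simulationTruth(ire)
  nc <- counts(ire)[, arms(ire) == "NC"]
  sel <- tr$baseline_mean >= 100
  rel_err <- abs(rowMeans(nc)[sel] - tr$baseline_mean[sel]) /
    tr$baseline_mean[sel]
  expect_lt(max(rel_err), 0.05)
})

test_that("expected levels agree with a brute-force application of the rules", {
  withr::with_seed(31, {
    inj <- sample(c(0, -1.5, 1.5, 0.3, -0.3, 0.05), 400, replace = TRUE)
    res <- sample(c(0, -1.5, 1.5, 0.45, -0.45, 0.08), 400, replace = TRUE)
  })
  got <- expectedCallbackLevel(inj, res)
  # truth-level oracle: significance <=> nonzero true effect
  fdr_m <- ifelse(inj == 0, 1, 0)
  fdr_t <- ifelse(res == 0, 1, 0)
  want <- oracleCallback(inj, fdr_m, res, fdr_t)$level
  expect_identical(got, want)
})

test_that("restored archetypes reverse the injury sign and nulls are inert", {
  tr <- simulationTruth(simulateCounts(simConfig(nGenes = 400, seed = 41)))
  restored <- tr$archetype %in% c("restored_up", "restored_down",
                                  "partial_restored")
  expect_true(all(sign(tr$true_rescue_log2fc.W1CC[restored]) ==
                    -sign(tr$true_injury_log2fc[restored])))
  nulls <- tr$archetype == "null"
  expect_true(all(tr$true_injury_log2fc[nulls] == 0 &
                    tr$true_rescue_log2fc.W1CC[nulls] == 0))
})

test_that("gene-set simulation honours the enriched fraction", {
  tr <- simulationTruth(simulateCounts(simConfig(nGenes = 300, seed = 51)))
  none <- simulateGeneSets(tr, nSets = 10, enrichedFraction = 0, seed = 1)
  expect_false(any(none$enriched))
  empty <- simulateGeneSets(tr, nSets = 0, seed = 1)
  expect_length(empty$term_id, 0)
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(empty, path)
  expect_identical(readLines(path), character(0))
  expect_error(simulateGeneSets(tr, enrichedFraction = 2), "\\[0, 1\\]")

  gsc <- simulateGeneSets(tr, nSets = 40, enrichedFraction = 0.5, seed = 2)
  restored <- tr$gene_id[tr$archetype %in%
                           c("restored_up", "restored_down",
                             "partial_restored")]
  frac <- vapply(gsc$members, function(m) {
    mean(m %in% restored)
  }, 0)
  expect_gt(mean(frac[gsc$enriched]), mean(frac[!gsc$enriched]))
})

test_that("simulated Ct tables invert exactly at zero noise", {
  tr <- simulationTruth(simulateCounts(simConfig(nGenes = 200, seed = 61)))
  ref <- tr$gene_id[tr$archetype == "null"][1]
  genes <- tr$gene_id[tr$archetype %in% c("restored_up", "restored_down")][1:5]
  ct <- simulateCtTable(tr, genes, ref, seed = 1, noiseSD = 0)
  rel <- ddct(ct, calibratorArm = "NC")
  for (g in genes) {
    i <- match(g, tr$gene_id)
    adm <- rel[rel$gene_id == g & rel$arm == "ADM", ]
    expect_equal(-adm$delta_delta_ct, tr$true_injury_log2fc[i],
                 tolerance = 1e-12)
    w1 <- rel[rel$gene_id == g & rel$arm == "W1CC", ]
    expect_equal(-w1$delta_delta_ct,
                 tr$true_injury_log2fc[i] + tr$true_rescue_log2fc.W1CC[i],
                 tolerance = 1e-12)
  }
  # seeded noisy table is reproducible
  expect_identical(simulateCtTable(tr, genes, ref, seed = 9),
                   simulateCtTable(tr, genes, ref, seed = 9))
  # a non-null normalizer is rejected
  expect_error(simulateCtTable(tr, genes, genes[1], seed = 1),
               "normalizer")
})

test_that("low-dispersion replicates correlate above 0.98 within arms", {
  ire <- simulateCounts(simConfig(nGenes = 1500, dispersion = c(0.02, 1),
                                  seed = 71))
  cc <- replicateCorrelation(fpkm(ire))
  arm <- arms(ire)
  for (a in unique(arm)) {
    idx <- which(arm == a)
    pairs <- utils::combn(idx, 2)
    vals <- cc[cbind(pairs[1, ], pairs[2, ])]
    expect_true(all(vals > 0.98))
  }
})
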