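makeSets <- function(members, ids = NULL) {
  n <- length(members)
  if (is.null(ids)) ids <- sprintf("T%02d", seq_len(n))
  structure(list(term_id = ids, term_name = ids,
                 category = rep("test", n), members = members,
                 enriched = rep(NA, n)),
            class = "GeneSetCollection")
}

test_that("the combinatorial worked example reproduces exactly", {
  universe <- paste0("g", 1:20)
  sets <- makeSets(list(universe[1:5]))
  res <- hypergeomEnrich(universe[2:5], sets, universe)
  expect_equal(res$p_value, 5 / 4845, tolerance = 1e-12)
  expect_equal(res$k, 4)
  expect_equal(res$rich_factor, 4 / 5)
})

test_that("degenerate overlaps behave as forced", {
  universe <- paste0("g", 1:12)
  sets <- makeSets(list(universe[1:4], universe))
  res <- hypergeomEnrich(universe[5:8], sets, universe)
  expect_equal(res$p_value[1], 1)  # k = 0
  expect_equal(res$k[2], 4)        # term = universe forces k = n
  expect_equal(res$p_value[2], 1)
  expect_error(hypergeomEnrich("absent", sets, universe), "empty query")
  expect_error(hypergeomEnrich("g1", sets, character(0)), "universe")
})

test_that("hypergeometric p equals brute-force enumeration for N <= 12", {
  for (N in c(5, 8, 12)) {
    universe <- paste0("g", seq_len(N))
    for (K in c(1, 3, N - 1)) {
      for (n in c(2, min(4, N - 1))) {
        sets <- makeSets(list(universe[seq_len(K)]))
        query <- universe[seq(N - n + 1, N)]
        res <- hypergeomEnrich(query, sets, universe)
        expect_equal(res$p_value, oracleHyperEnum(N, K, n, res$k),
                     tolerance = 1e-12,
                     info = sprintf("N=%d K=%d n=%d", N, K, n))
      }
    }
  }
})

test_that("enrichment p is non-increasing in the overlap", {
  universe <- paste0("g", 1:40)
  term <- universe[1:10]
  ps <- vapply(0:8, function(k) {
    query <- c(term[seq_len(k)], universe[31:(38 - k + 1)])[1:8]
    hypergeomEnrich(query, makeSets(list(term)), universe)$p_value
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("corrections follow their definitions and ordering", {
  res <- data.frame(term_id = paste0("T", 1:10), term_name = "t",
                    category = "c", N = 100, K = 10, n = 10,
                    k = c(5, rep(1, 9)), rich_factor = 0.1,
                    p_value = c(0.004, 0.01, seq(0.1, 0.8, length.out = 8)))
  bonf <- correctPvalues(res, "bonferroni")
  expect_equal(bonf$corrected_p[1], 0.04)
  expect_true(bonf$significant[1])
  expect_equal(bonf$corrected_p[2], 0.1)
  expect_false(bonf$significant[2])
  bh <- correctPvalues(res[1:3, ], "bh")
  expect_equal(bh$corrected_p,
               bhAdjust(res$p_value[1:3]))
  expect_equal(correctPvalues(data.frame(res[1:3, -9],
                                         p_value = c(0.01, 0.02, 0.04)),
                              "bh")$corrected_p,
               c(0.03, 0.03, 0.04))
  # Bonferroni >= BH >= raw, elementwise
  expect_true(all(bonf$corrected_p >=
                    correctPvalues(res, "bh")$corrected_p - 1e-12))
  expect_true(all(correctPvalues(res, "bh")$corrected_p >=
                    res$p_value - 1e-12))
  expect_error(correctPvalues(res[0, ], "bonferroni"), "no enrichment")
  # untestable terms (K = 0) are excluded from m and flagged NA
  res0 <- res; res0$K[10] <- 0L; res0$k[10] <- 0L
  b0 <- correctPvalues(res0, "bonferroni")
  expect_equal(b0$corrected_p[1], 9 * 0.004)
  expect_true(is.na(b0$corrected_p[10]))
})

test_that("per-level enrichment ranks truly enriched sets first", {
  ire <- simulateCounts(simConfig(nGenes = 600, seed = 29))
  tr <- simulationTruth(ire)
  gsc <- simulateGeneSets(tr, nSets = 30, enrichedFraction = 0.3, seed = 30)
  model <- nbWaldTest(ire, c("ADM", "NC"))
  asg <- classifyCallback(model, nbWaldTest(ire, c("W1CC", "ADM")),
                          treatment = "W1CC")
  universe <- intersect(model$gene_id[!is.na(model$p_value)],
                        unique(unlist(gsc$members)))
  tab <- suppressWarnings(enrichByLevel(asg, gsc, universe))
  lvl1 <- tab[tab$level == "1", ]
  lvl1 <- lvl1[order(lvl1$p_value), ]
  flagged <- gsc$term_id[gsc$enriched]
  rank_flagged <- which(lvl1$term_id %in% flagged)
  rank_other <- which(!lvl1$term_id %in% flagged)
  expect_lt(median(rank_flagged), median(rank_other))
})

test_that("empty queries give empty tables with a warning", {
  universe <- paste0("g", 1:20)
  gsc <- makeSets(list(universe[1:5]))
  asg <- data.frame(gene_id = "g1", treatment = "T", level = "none",
                    direction = "none")
  w <- capture_warnings(tab <- enrichByLevel(asg, gsc, universe))
  expect_length(w, 6)
  expect_true(all(grepl("empty table", w)))
  expect_equal(nrow(tab), 0)
})

test_that("GMT files round-trip", {
  sets <- makeSets(list(c("a", "b", "c"), c("d", "e")),
                   ids = c("GO:1", "GO:2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sets, path)
  back <- readGMT(path, category = "test")
  expect_identical(back$term_id, sets$term_id)
  expect_identical(back$members, sets$members)
  writeLines("only_one_field", path)
  expect_error(readGMT(path), "malformed")
})
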