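test_that("the worked classification examples come out as stated", {
  m <- deTable(paste0("g", 1:4),
               log2fc = c(-0.8, 0.3, 0.05, -0.8),
               fdr = c(0.001, 0.01, 0.60, 0.001))
  t <- deTable(paste0("g", 1:4),
               log2fc = c(0.6, -0.2, 0.4, -0.6),
               fdr = c(0.01, 0.02, 0.001, 0.01))
  a <- classifyCallback(m, t, treatment = "W1CC")
  expect_equal(a$level, c("1", "2", "3", "none"))
  expect_equal(a$direction, c("up-called-back", "down-called-back",
                              "treatment-up", "none"))
})

test_that("classification matches the straight-line oracle on random tables", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- 200
      m <- deTable(paste0("g", 1:n), rnorm(n), runif(n))
      t <- deTable(paste0("g", 1:n), rnorm(n), runif(n))
      a <- classifyCallback(m, t, treatment = "T")
      want <- oracleCallback(m$log2fc, m$fdr, t$log2fc, t$fdr)
      expect_identical(a$level, want$level)
      expect_identical(a$direction, want$direction)
    }
  })
})

test_that("levels partition the gene universe exactly once per treatment", {
  withr::with_seed(18, {
    n <- 500
    m <- deTable(paste0("g", 1:n), rnorm(n), runif(n))
    t <- deTable(paste0("g", 1:n), rnorm(n), runif(n))
  })
  a <- classifyCallback(m, t)
  expect_equal(nrow(a), n)
  expect_true(all(a$level %in% c("1", "2", "3", "none")))
  expect_equal(anyDuplicated(a$gene_id), 0)
})

test_that("raising the level-2 threshold never recruits new level-2 genes", {
  withr::with_seed(19, {
    n <- 400
    m <- deTable(paste0("g", 1:n), rnorm(n, sd = 0.5), runif(n))
    t <- deTable(paste0("g", 1:n), rnorm(n, sd = 0.5), runif(n))
  })
  lo <- classifyCallback(m, t, callbackThresholds(level2Lfc = 0.1))
  hi <- classifyCallback(m, t, callbackThresholds(level2Lfc = 0.3))
  moved_in <- lo$level == "none" & hi$level == "2"
  expect_false(any(moved_in))
})

test_that("genes untested in a contrast are classified none, never level 3", {
  m <- deTable(c("g1", "g2"), c(0.0, 0.0), c(NA, 0.9))
  t <- deTable(c("g1", "g2"), c(1.0, 1.0), c(0.001, NA))
  a <- classifyCallback(m, t)
  expect_equal(a$level, c("none", "none"))
})

test_that("asymmetric gene universes are rejected with the offending ids", {
  m <- deTable(c("g1", "g2"), c(0, 0), c(1, 1))
  t <- deTable(c("g1", "g3"), c(0, 0), c(1, 1))
  expect_error(classifyCallback(m, t), "g2")
})

test_that("shared and unique call-back sets follow set identities", {
  mk <- function(genes, lvl, dir) {
    data.frame(gene_id = genes, treatment = "x", level = lvl,
               direction = dir, stringsAsFactors = FALSE)
  }
  a1 <- mk(c("a", "b", "c"), "1", "up-called-back")
  a2 <- mk(c("b", "c", "d"), "1", "up-called-back")
  sh <- sharedCallback(list(W1CC = a1, W5CC = a2), "up-called-back")
  expect_setequal(sh[["1"]]$shared, c("b", "c"))
  expect_setequal(sh[["1"]]$unique$W1CC, "a")
  expect_setequal(sh[["1"]]$unique$W5CC, "d")
  same <- sharedCallback(list(W1CC = a1, W5CC = a1), "up-called-back")
  expect_setequal(same[["1"]]$shared, c("a", "b", "c"))
  expect_length(same[["1"]]$unique$W1CC, 0)
  expect_error(sharedCallback(list(W1CC = a1, W5CC = a2), "sideways"),
               "direction class")
})

test_that("restored genes dominate the shared level-1 call-back set", {
  ire <- simulateCounts(simConfig(nGenes = 800, seed = 23))
  model <- nbWaldTest(ire, c("ADM", "NC"))
  asg <- lapply(c("W1CC", "W5CC"), function(t) {
    classifyCallback(model, nbWaldTest(ire, c(t, "ADM")), treatment = t)
  })
  names(asg) <- c("W1CC", "W5CC")
  tr <- simulationTruth(ire)
  shared <- unlist(lapply(c("up-called-back", "down-called-back"),
                          function(dc) {
                            sharedCallback(asg, dc)[["1"]]$shared
                          }))
  frac_restored_shared <- mean(tr$archetype[match(shared, tr$gene_id)] %in%
                                 c("restored_up", "restored_down"))
  frac_null_shared <- mean(tr$archetype[match(shared, tr$gene_id)] == "null")
  expect_gt(frac_restored_shared, frac_null_shared)
  expect_gt(frac_restored_shared, 0.5)
})

test_that("upset counts are exclusive and sum to the union", {
  u <- upsetCounts(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(u$size[u$combination == "A"], 1)
  expect_equal(u$size[u$combination == "B"], 1)
  expect_equal(u$size[u$combination == "A&B"], 1)
  expect_equal(sum(u$size), 3)
  d <- upsetCounts(list(A = c("a"), B = c("b"), C = c("c")))
  expect_true(all(d$size[d$degree > 1] == 0))
  withr::with_seed(25, {
    for (i in 1:10) {
      lists <- lapply(1:3, function(j) {
        sample(letters, sample(5:20, 1))
      })
      names(lists) <- c("x", "y", "z")
      got <- upsetCounts(lists)
      want <- oracleUpset(lists)
      expect_equal(sum(got$size), length(unique(unlist(lists))))
      for (r in seq_len(nrow(got))) {
        key <- paste(unlist(got[r, c("x", "y", "z")]), collapse = "")
        expect_equal(got$size[r],
                     if (is.null(want[[key]])) 0L else want[[key]])
      }
    }
  })
})
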