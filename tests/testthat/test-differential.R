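test_that("self-comparison of identical condition groups yields no signal", {
  db <- tinyDB()
  base <- tinyDataset(nPerType = 20L)
  m <- assay(base, "logcounts")
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("c%03d", seq_len(ncol(m2)))
  ds <- CCCExperiment(m2, cellType = rep(cellType(base), 2),
                      sample = rep(c("s1", "s2"), each = ncol(m)),
                      condition = c(s1 = "case", s2 = "control"))
  gc <- suppressWarnings(globalCompare(ds, db, cccParams(), seed = 5))
  expect_true(all(gc$count_diff == 0))
  expect_true(all(gc$strength_diff == 0))
  expect_true(all(gc$pathway$direction == "ns"))
})

test_that("count differences equal the per-condition count difference", {
  db <- tinyDB()
  ds <- local({
    base <- tinyDataset(nPerType = 20L)
    m <- assay(base, "logcounts")
    m2 <- cbind(m, m)
    m2[, seq_len(ncol(m))][c("FGF1", "FGF2"), ] <- 0  # condition A loses FGF
    colnames(m2) <- sprintf("c%03d", seq_len(ncol(m2)))
    CCCExperiment(m2, cellType = rep(cellType(base), 2),
                  sample = rep(c("s1", "s2"), each = ncol(m)),
                  condition = c(s1 = "case", s2 = "control"))
  })
  gc <- suppressWarnings(globalCompare(ds, db, cccParams(), seed = 5,
                                       conditionA = "case"))
  mA <- countStrengthMaps(gc$tensorA)
  mB <- countStrengthMaps(gc$tensorB)
  expect_equal(gc$count_diff, mA$counts - mB$counts)
  expect_true(gc$count_diff["A", "B"] < 0)
})

test_that("rank-sum p-values match full enumeration and known examples", {
  m <- rbind(matrix(c(1, 2, 3), 3, 1), matrix(c(4, 5, 6), 3, 1))
  colnames(m) <- "P1"
  rownames(m) <- sprintf("s%d", 1:6)
  sls <- mkScores(m, cond = setNames(rep(c("g1", "g2"), each = 3),
                                     rownames(m)))
  res <- suppressMessages(sampleWilcoxon(sls, "pathway", conditionA = "g1"))
  expect_equal(res$p, 0.1)   # frozen from enumeration of C(6,3) assignments
  expect_equal(res$p, ranksumEnumP(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$direction, "ns")
  # identical groups
  m2 <- m; m2[] <- c(1, 2, 3, 1, 2, 3)
  sls2 <- mkScores(m2, cond = sls@condition)
  res2 <- suppressMessages(sampleWilcoxon(sls2, "pathway"))
  expect_equal(res2$p, 1)
  # degenerate constant unit
  m3 <- m; m3[] <- 2
  res3 <- suppressMessages(sampleWilcoxon(mkScores(m3, sls@condition),
                                          "pathway"))
  expect_equal(res3$p, 1)
  expect_true(res3$degenerate)
})

test_that("rank-sum p equals enumeration over random small groups", {
  set.seed(99)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(rnorm(n1), 3); b <- round(rnorm(n2, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    m <- matrix(c(a, b), ncol = 1, dimnames = list(
      sprintf("s%02d", seq_len(n1 + n2)), "P1"))
    m <- m - min(m) + 0.1   # scores are non-negative
    sls <- mkScores(m, setNames(rep(c("g1", "g2"), c(n1, n2)), rownames(m)))
    res <- suppressMessages(sampleWilcoxon(sls, "pathway", conditionA = "g1"))
    expect_equal(res$p, ranksumEnumP(m[1:n1, 1], m[(n1 + 1):(n1 + n2), 1]),
                 tolerance = 1e-12)
  }
})

test_that("BH q-values dominate p and are monotone", {
  set.seed(11)
  m <- matrix(rlnorm(23 * 40), 23, 40,
              dimnames = list(sprintf("s%02d", 1:23),
                              sprintf("P%02d", 1:40)))
  m[1:13, 1:3] <- m[1:13, 1:3] * 3   # a few strong effects
  cond <- setNames(rep(c("case", "control"), c(13, 10)), rownames(m))
  res <- suppressMessages(sampleWilcoxon(mkScores(m, cond), "pathway"))
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  ord <- order(res$p)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
})

test_that("fold changes use the documented pseudocount", {
  m <- matrix(c(2, 2, 2, 0, 0, 0), 6, 1,
              dimnames = list(sprintf("s%d", 1:6), "P1"))
  cond <- setNames(rep(c("g1", "g2"), each = 3), rownames(m))
  expect_message(res <- sampleWilcoxon(mkScores(m, cond), "pathway",
                                       conditionA = "g1"),
                 "eps")
  eps <- attr(res, "eps")
  expect_equal(eps, 2e-3)             # smallest positive score x 1e-3
  expect_equal(res$fold_change, (2 + eps) / eps)
})

test_that("pathway detection filtering respects the 5-sample boundary", {
  m <- matrix(0, 23, 3, dimnames = list(sprintf("s%02d", 1:23),
                                        c("P4", "P5", "P0")))
  m[1:4, "P4"] <- 1    # detected in 4 of 23 -> removed
  m[1:5, "P5"] <- 1    # detected in exactly 5 -> retained
  cond <- setNames(rep(c("case", "control"), c(13, 10)), rownames(m))
  sls <- mkScores(m, cond)
  f <- filterPathways(sls, minSamples = 5L)
  expect_equal(colnames(f@pathway_scores), "P5")
  expect_equal(f@lr_anno$pathway, "P5")
})

test_that("PCA coordinates come with variance fractions summing to one", {
  set.seed(2)
  m <- matrix(rlnorm(12 * 6), 12, 6,
              dimnames = list(sprintf("s%02d", 1:12), sprintf("P%d", 1:6)))
  cond <- setNames(rep(c("case", "control"), each = 6), rownames(m))
  pc <- pcaSamples(mkScores(m, cond))
  expect_equal(sum(pc$variance_explained), 1)
  # rank-1 matrix: PC1 explains everything
  r1 <- outer(seq_len(12), seq_len(6)) + 0
  dimnames(r1) <- dimnames(m)
  pc1 <- pcaSamples(mkScores(r1, cond))
  expect_equal(pc1$variance_explained[1L], 1)
  # constant matrix is rank-0
  cm <- m; cm[] <- 3
  expect_error(pcaSamples(mkScores(cm, cond)), "rank-0")
})

test_that("subsampling at frac = 1 reproduces the full comparison exactly", {
  db <- tinyDB()
  base <- tinyDataset(nPerType = 15L)
  m <- assay(base, "logcounts")
  m2 <- cbind(m, m * 1.5)
  colnames(m2) <- sprintf("c%03d", seq_len(ncol(m2)))
  ds <- CCCExperiment(m2, cellType = rep(cellType(base), 2),
                      sample = rep(c("s1", "s2"), each = ncol(m)),
                      condition = c(s1 = "case", s2 = "control"))
  rob <- suppressWarnings(
    subsampleRobustness(ds, db, cccParams(nPerm = 30L), frac = 1,
                        reps = 2L, seed = 4))
  expect_equal(rob$mean_diff, rob$full_diff)
  expect_true(all(rob$sd_diff == 0))
  expect_equal(rob$correlation, 1)
  rob2 <- suppressWarnings(
    subsampleRobustness(ds, db, cccParams(nPerm = 30L), frac = 1,
                        reps = 2L, seed = 4))
  expect_identical(rob$mean_diff, rob2$mean_diff)
  expect_error(suppressWarnings(
    subsampleRobustness(ds, db, frac = 1.2, reps = 2L)), "frac")
})

test_that("per-sample scores are deterministic and conserve pathway totals", {
  db <- tinyDB()
  base <- tinyDataset(nPerType = 15L)
  m <- assay(base, "logcounts")
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("c%03d", seq_len(ncol(m2)))
  ds <- CCCExperiment(m2, cellType = rep(cellType(base), 2),
                      sample = rep(c("s1", "s2"), each = ncol(m)),
                      condition = c(s1 = "case", s2 = "control"))
  sls <- suppressWarnings(perSampleScores(ds, db, cccParams(nPerm = 50L),
                                          seed = 9))
  # identical cells in both samples -> identical rows
  expect_equal(sls@pathway_scores["s1", ], sls@pathway_scores["s2", ])
  # pathway total equals total significant L-R strength per sample
  expect_equal(unname(rowSums(sls@pathway_scores)),
               unname(rowSums(sls@lr_scores)))
})

test_that("an explicit group map reruns the design on regrouped samples", {
  db <- tinyDB()
  base <- tinyDataset(nPerType = 6L)
  m <- assay(base, "logcounts")
  blocks <- lapply(1:8, function(i) m)
  m2 <- do.call(cbind, blocks)
  colnames(m2) <- sprintf("c%04d", seq_len(ncol(m2)))
  samp <- rep(sprintf("s%d", 1:8), each = ncol(m))
  ds <- CCCExperiment(m2, cellType = rep(cellType(base), 8), sample = samp,
                      condition = setNames(rep(c("case", "control"),
                                               each = 4),
                                           sprintf("s%d", 1:8)))
  map <- setNames(rep(c("g1", "g2"), 4), sprintf("s%d", 1:8))
  out <- suppressWarnings(suppressMessages(
    runPipeline(ds, db, cccParams(nPerm = 20L), mode = "per-sample",
                outDir = NULL, seed = 2, minSamples = 1L, groupMap = map)))
  expect_setequal(unique(out$scores@condition), c("g1", "g2"))
})
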