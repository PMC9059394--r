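test_that("hypergeometric ORA matches the closed form and brute force", {
  uni <- sprintf("G%02d", 1:10)
  gsc <- geneSetCollection(list(S = uni[1:5]), uni)
  res <- ora(uni[1:2], gsc)
  expect_equal(res$p, 10 / 45)           # C(5,2)/C(10,2)
  expect_equal(res$p, hyperEnumP(N = 10, K = 5, n = 2, k = 2))
  # query disjoint from the set: k = 0 tail is 1
  res0 <- ora(uni[6:7], gsc)
  expect_equal(res0$p, 1)
  # set equal to the universe forces the overlap
  gscU <- geneSetCollection(list(S = uni), uni)
  expect_equal(ora(uni[3:6], gscU)$p, 1)
  expect_error(ora(uni[1], geneSetCollection(list(S = "G01"),
                                             character(0))),
               "universe")
})

test_that("ORA p-values match enumeration across random small instances", {
  set.seed(7)
  for (i in 1:30) {
    N <- sample(6:12, 1)
    uni <- sprintf("g%02d", seq_len(N))
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    gsc <- geneSetCollection(list(S = uni[seq_len(K)]), uni)
    query <- sample(uni, n)
    k <- sum(query %in% uni[seq_len(K)])
    expect_equal(ora(query, gsc)$p, hyperEnumP(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("list overlap reports the sample odds ratio and Fisher p", {
  uni <- sprintf("G%03d", 1:100)
  A <- uni[1:10]; B <- uni[c(1:5, 11:25)]
  res <- overlapTest(A, B, uni)
  expect_equal(unlist(res[, c("a", "b", "c", "d")], use.names = FALSE),
               c(5, 5, 15, 75))
  expect_equal(res$odds_ratio, 5)
  expect_equal(res$p, fisherEnumP(5, 5, 15, 75), tolerance = 1e-9)
  # zero overlap: Haldane-corrected OR below 1 (anti-enrichment) on a small
  # universe; with a roomy universe the two-sided Fisher p is near 1
  res0 <- overlapTest(uni[1:3], uni[4:6], uni[1:10])
  expect_lt(res0$odds_ratio, 1)
  expect_gt(overlapTest(uni[1:3], uni[4:6], uni)$p, 0.5)
  # degenerate all-universe case is flagged
  resD <- overlapTest(uni, uni, uni)
  expect_equal(resD$flag, "degenerate")
  # empty list after intersection
  resE <- overlapTest(character(0), uni[1:3], uni)
  expect_equal(resE$flag, "empty_list")
  expect_equal(resE$p, 1)
})

test_that("GSEA running sum hits +1 for the top-ranked singleton", {
  ranking <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  gsc <- geneSetCollection(list(top = "A"), names(ranking))
  res <- prerankedGSEA(ranking, gsc, nPerm = 200L, seed = 1, minSize = 1L)
  expect_equal(res$es, 1)
  # reversing the ranking negates the ES of a singleton set
  resRev <- prerankedGSEA(-ranking, gsc, nPerm = 200L, seed = 1,
                          minSize = 1L)
  expect_equal(resRev$es, -1)
})

test_that("GSEA enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(31)
  for (i in 1:10) {
    n <- 40L
    ranking <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(ranking) <- sprintf("G%02d", seq_len(n))
    sz <- sample(3:10, 1)
    setGenes <- sample(names(ranking), sz)
    gsc <- geneSetCollection(list(S = setGenes), names(ranking))
    ours <- prerankedGSEA(ranking, gsc, nPerm = 10L, seed = 1, minSize = 1L)
    ref <- fgsea::calcGseaStat(ranking,
                               selectedStats = which(names(ranking) %in%
                                                       setGenes),
                               gseaParam = 1)
    expect_equal(ours$es, ref, tolerance = 1e-9)
  }
})

test_that("extreme-placed sets score larger than central sets", {
  set.seed(13)
  wins <- 0L
  for (i in 1:20) {
    n <- 50L
    ranking <- sort(abs(rnorm(n, sd = 2)) + 0.1, decreasing = TRUE)
    names(ranking) <- sprintf("G%02d", seq_len(n))
    extreme <- names(ranking)[1:5]
    central <- names(ranking)[23:27]
    gsc <- geneSetCollection(list(ext = extreme, cen = central),
                             names(ranking))
    res <- prerankedGSEA(ranking, gsc, nPerm = 10L, seed = i, minSize = 1L)
    if (abs(res$es[res$set == "ext"]) > abs(res$es[res$set == "cen"]))
      wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("GSEA permutation p-values flag planted enrichment", {
  set.seed(4)
  n <- 100L
  ranking <- sort(rnorm(n, sd = 2), decreasing = TRUE)
  names(ranking) <- sprintf("G%03d", seq_len(n))
  gsc <- geneSetCollection(list(top = names(ranking)[1:10],
                                rand = sample(names(ranking), 10)),
                           names(ranking))
  res <- prerankedGSEA(ranking, gsc, nPerm = 500L, seed = 9)
  expect_lt(res$p[res$set == "top"], 0.05)
  expect_gt(res$p[res$set == "rand"], 0.05)
  expect_true(all(res$fdr >= 0 & res$fdr <= 1, na.rm = TRUE))
})

test_that("GMT and gene-list readers round the formats", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG2\tG4"), f)
  gsc <- readGMT(f, universe = sprintf("G%d", 1:5))
  expect_equal(lengths(gsc@sets), c(setA = 3L, setB = 2L))
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("g1", "G2", "", "g1"), g)
  expect_equal(readGeneList(g), c("G1", "G2"))
})
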