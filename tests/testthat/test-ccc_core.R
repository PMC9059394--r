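test_that("per-type summaries apply the trimean and the 20% filter", {
  # 20 cells of one type; gene g1 expressed in 3 of 20 (fraction 0.15 < 0.2)
  m <- matrix(0, 3, 20, dimnames = list(c("g1", "g2", "g3"),
                                        sprintf("c%02d", 1:20)))
  m["g1", 1:3] <- 5
  m["g2", ] <- 4                   # constant
  m["g3", ] <- rep(c(0, 10), each = 10)  # half zeros, half tens
  ds <- CCCExperiment(m, cellType = rep("T", 20), sample = rep("s1", 20),
                      condition = rep("x", 20))
  for (summ in c("trimean", "mean")) {
    pr <- summarizeProfiles(ds, summary = summ)
    expect_equal(pr$frac["g1", "T"], 0.15)
    expect_equal(pr$mean["g1", "T"], 0)          # filtered out
    expect_equal(pr$mean["g2", "T"], 4)          # constant under either mode
  }
  # trimean of {0 x 10, 10 x 10}: drop 5 from each tail -> mean of {0x5,10x5}
  pr <- summarizeProfiles(ds, summary = "trimean")
  expect_equal(pr$mean["g3", "T"], mean(sort(m["g3", ])[6:15]))
  expect_equal(pr$mean["g3", "T"], 5)
  # the documented example: {0,0,0,0,10,10,10,10} -> mean of {0,0,10,10} = 5
  m8 <- matrix(c(0, 0, 0, 0, 10, 10, 10, 10), 1, 8,
               dimnames = list("g", sprintf("c%d", 1:8)))
  ds8 <- CCCExperiment(m8, cellType = rep("T", 8), sample = rep("s1", 8),
                       condition = rep("x", 8))
  expect_equal(summarizeProfiles(ds8, threshold = 0.2)$mean["g", "T"], 5)
  expect_error(summarizeProfiles(ds, threshold = 1.5), "threshold")
})

test_that("complex expression is the geometric mean with null propagation", {
  m <- matrix(c(2, 8, 5, 0, 7), 5, 4,
              dimnames = list(c("A", "B", "C", "D", "E"), paste0("c", 1:4)))
  ds <- CCCExperiment(m, cellType = rep("T", 4), sample = rep("s1", 4),
                      condition = rep("x", 4))
  pr <- summarizeProfiles(ds, threshold = 0)
  expect_equal(complexExpression(pr, c("A", "B"), "T"), 4)
  expect_equal(complexExpression(pr, "C", "T"), 5)
  expect_equal(complexExpression(pr, c("D", "E"), "T"), 0)
  expect_error(complexExpression(pr, character(0), "T"), "empty complex")
})

test_that("the mass-action response matches its closed forms", {
  expect_equal(interactionStrength(0, 7), 0)
  expect_equal(interactionStrength(1, 0.5), 0.5)   # L*R = kh = 0.5
  expect_equal(interactionStrength(1, 1), 2 / 3, tolerance = 1e-12)
  expect_error(interactionStrength(-1, 1), "negative")
})

test_that("the response is monotone in each input", {
  set.seed(42)
  for (i in 1:50) {
    L <- runif(1, 0, 3); R <- runif(1, 0, 3)
    AG <- runif(1, 0, 2); AN <- runif(1, 0, 2)
    CS <- runif(1, 0, 2); CI <- runif(1, 0, 2)
    d <- runif(1, 0.01, 0.5)
    s0 <- interactionStrength(L, R, AG, AN, CS, CI)
    expect_gte(interactionStrength(L + d, R, AG, AN, CS, CI), s0)
    expect_gte(interactionStrength(L, R + d, AG, AN, CS, CI), s0)
    expect_gte(interactionStrength(L, R, AG + d, AN, CS, CI), s0)
    expect_gte(interactionStrength(L, R, AG, AN, CS + d, CI), s0)
    expect_lte(interactionStrength(L, R, AG, AN + d, CS, CI), s0)
    expect_lte(interactionStrength(L, R, AG, AN, CS, CI + d), s0)
    expect_lt(s0, 2)
    expect_lt(interactionStrength(L, R, params = cccParams(useCofactors = FALSE)), 1)
  }
})

test_that("tensor strengths match a hand-computed oracle to 1e-12", {
  db <- tinyDB()
  ds <- tinyDataset(nPerType = 10L, high = 3)
  tens <- suppressWarnings(
    inferCommunication(ds, db, cccParams(nPerm = 5L), seed = 1))
  pr <- summarizeProfiles(ds)
  # independent arithmetic per triple
  expectStrength <- function(sender, receiver, lig, rec, ag = NULL,
                             an = NULL) {
    gm <- function(genes, tp) {
      v <- pr$mean[genes, tp]
      if (any(v <= 0)) 0 else exp(mean(log(v)))
    }
    am <- function(genes, tp) if (is.null(genes)) 0 else
      mean(pr$mean[genes, tp])
    oracleStrength(gm(lig, sender), gm(rec, receiver),
                   AG = am(ag, sender), AN = am(an, sender))
  }
  expect_equal(strengths(tens)["A", "B", "I1"],
               expectStrength("A", "B", "FGF1", "FGFR1", ag = "AGA"),
               tolerance = 1e-12)
  expect_equal(strengths(tens)["A", "B", "I2"],
               expectStrength("A", "B", "FGF2", c("FGFR1", "FGFR2"),
                              an = "ANB"),
               tolerance = 1e-12)
  expect_equal(strengths(tens)["A", "B", "I3"],
               expectStrength("A", "B", "NLGN1", "NRXN1"),
               tolerance = 1e-12)
  # receiver lacks ligands: A <- B direction must be null here
  expect_equal(unname(strengths(tens)["B", "A", ]), c(0, 0, 0))
  expect_equal(unname(pvalues(tens)["B", "A", ]), c(1, 1, 1))
})

test_that("permutation p-values are reproducible and detect planted signal", {
  db <- tinyDB()
  ds <- tinyDataset(nPerType = 25L)
  p1 <- permutationTest(ds, db, "A", "B", "I1",
                        cccParams(nPerm = 100L), seed = 7)
  p2 <- permutationTest(ds, db, "A", "B", "I1",
                        cccParams(nPerm = 100L), seed = 7)
  expect_identical(p1, p2)
  expect_lte(p1, 0.02)   # exclusive sender/receiver expression
  # zero observed strength reports p = 1
  expect_equal(permutationTest(ds, db, "B", "A", "I1",
                               cccParams(nPerm = 20L), seed = 1), 1)
  # full tensors are deterministic under a fixed seed
  t1 <- suppressWarnings(inferCommunication(ds, db, cccParams(), seed = 3))
  t2 <- suppressWarnings(inferCommunication(ds, db, cccParams(), seed = 3))
  expect_identical(strengths(t1), strengths(t2))
  expect_identical(pvalues(t1), pvalues(t2))
})

test_that("pathway aggregation keeps only significant strengths", {
  st <- array(0, dim = c(2, 2, 2),
              dimnames = list(c("A", "B"), c("A", "B"), c("I1", "I2")))
  pv <- array(1, dim = dim(st), dimnames = dimnames(st))
  st["A", "B", "I1"] <- 0.2; pv["A", "B", "I1"] <- 0.2   # not significant
  st["A", "B", "I2"] <- 0.3; pv["A", "B", "I2"] <- 0.01
  anno <- data.frame(id = c("I1", "I2"), ligand = "L", receptor = "R",
                     pathway = c("P1", "P1"), category = "secreted")
  tens <- new("CommunicationTensor", strength = st, pval = pv,
              alpha = 0.05, anno = anno)
  db <- makeLRDatabase(data.frame(id = c("I1", "I2"), ligand_name = "L",
                                  ligand_subunits = "L", receptor_name = "R",
                                  receptor_subunits = "R",
                                  pathway = c("P1", "P1")))
  ps <- aggregatePathways(tens, db)
  expect_equal(pathwayScores(ps)["A", "B", "P1"], 0.3)
  # both significant -> sum
  pv["A", "B", "I1"] <- 0.02
  tens2 <- new("CommunicationTensor", strength = st, pval = pv,
               alpha = 0.05, anno = anno)
  expect_equal(pathwayScores(aggregatePathways(tens2, db))["A", "B", "P1"],
               0.5)
  # an undetected pathway is flagged
  db2 <- makeLRDatabase(data.frame(id = c("I1", "I2"), ligand_name = "L",
                                   ligand_subunits = "L",
                                   receptor_name = "R",
                                   receptor_subunits = "R",
                                   pathway = c("P1", "P2")))
  anno2 <- anno; anno2$pathway <- c("P1", "P2")
  pv["A", "B", "I2"] <- 1
  tens3 <- new("CommunicationTensor", strength = st, pval = pv,
               alpha = 0.05, anno = anno2)
  ps3 <- aggregatePathways(tens3, db2)
  expect_true(ps3@detected[["P1"]])
  expect_false(ps3@detected[["P2"]])
})

test_that("count and strength maps summarize the significance mask", {
  st <- array(0, dim = c(2, 2, 3),
              dimnames = list(c("A", "B"), c("A", "B"),
                              c("I1", "I2", "I3")))
  pv <- array(1, dim = dim(st), dimnames = dimnames(st))
  st["A", "B", ] <- c(0.1, 0.2, 0.3)
  pv["A", "B", ] <- 0.01
  anno <- data.frame(id = c("I1", "I2", "I3"), ligand = "L", receptor = "R",
                     pathway = "P1", category = "secreted")
  tens <- new("CommunicationTensor", strength = st, pval = pv,
              alpha = 0.05, anno = anno)
  maps <- countStrengthMaps(tens)
  expect_equal(maps$counts["A", "B"], 3)
  expect_equal(maps$totals["A", "B"], 0.6)
  expect_equal(sum(maps$counts), 3)
  # relabeling interactions leaves the counts unchanged
  perm <- c(3, 1, 2)
  tensP <- new("CommunicationTensor", strength = st[, , perm],
               pval = pv[, , perm], alpha = 0.05, anno = anno[perm, ])
  expect_equal(countStrengthMaps(tensP)$counts, maps$counts)
  # all-nonsignificant mask gives zero matrices
  pv[] <- 1
  st0 <- st; st0[] <- 0
  tens0 <- new("CommunicationTensor", strength = st0, pval = pv,
               alpha = 0.05, anno = anno)
  expect_true(all(countStrengthMaps(tens0)$counts == 0))
  expect_true(all(countStrengthMaps(tens0)$totals == 0))
})

test_that("information flow sums scores and is conserved", {
  sc <- array(0, dim = c(2, 2, 2),
              dimnames = list(c("A", "B"), c("A", "B"), c("P1", "P2")))
  sc["A", "B", "P1"] <- 0.1
  sc["B", "A", "P1"] <- 0.4
  ps <- new("PathwayScores", score = sc,
            detected = c(P1 = TRUE, P2 = FALSE))
  expect_equal(unname(informationFlow(ps)["P1"]), 0.5)
  # contributions conserve the flow and normalize to a unit column maximum
  outc <- celltypeContributions(ps, "outgoing")
  inc <- celltypeContributions(ps, "incoming")
  expect_equal(colSums(outc), informationFlow(ps))
  expect_equal(colSums(inc), informationFlow(ps))
  expect_equal(outc["A", "P1"], 0.1)
  expect_equal(inc["B", "P1"], 0.1)
  rel <- celltypeContributions(ps, "outgoing", relative = TRUE)
  expect_equal(max(rel[, "P1"]), 1)
})

test_that("relative flow normalizes across conditions and labels specifics", {
  mk <- function(v1, v2) {
    sc <- array(0, dim = c(1, 1, 2),
                dimnames = list("A", "A", c("P1", "P2")))
    sc[1, 1, ] <- c(v1, v2)
    new("PathwayScores", score = sc,
        detected = c(P1 = v1 > 0, P2 = v2 > 0))
  }
  rf <- relativeFlow(mk(2, 0), mk(3, 1.2))
  expect_equal(rf$rel_A[rf$pathway == "P1"], 0.4)
  expect_equal(rf$rel_B[rf$pathway == "P1"], 0.6)
  expect_equal(rf$specific[rf$pathway == "P2"], "B")
  expect_message(relativeFlow(mk(1, 0), mk(1, 0)), "zero flow")
})

test_that("a dataset failing the expression filter yields a null tensor", {
  db <- tinyDB()
  # every database gene expressed in only 1 of 10 cells per type
  genes <- cccdiff:::.db_genes(db)
  m <- matrix(0, length(genes), 20,
              dimnames = list(genes, sprintf("c%02d", 1:20)))
  m[, c(1, 11)] <- 5
  ds <- CCCExperiment(m, cellType = rep(c("A", "B"), each = 10),
                      sample = rep("s1", 20), condition = rep("x", 20))
  tens <- suppressWarnings(
    inferCommunication(ds, db, cccParams(nPerm = 10L), seed = 1))
  expect_true(all(strengths(tens) == 0))
  expect_true(all(pvalues(tens) == 1))
})
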