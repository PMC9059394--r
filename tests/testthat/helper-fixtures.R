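# Shared fixtures and independent oracles, all built in code.

# small two-pathway database with a heteromeric receptor and cofactors
tinyDB <- function() {
  makeLRDatabase(data.frame(
    id = c("I1", "I2", "I3"),
    ligand_name = c("FGF1", "FGF2", "NLGN1"),
    ligand_subunits = c("FGF1", "FGF2", "NLGN1"),
    receptor_name = c("FGFR1", "FGFR1_FGFR2", "NRXN1"),
    receptor_subunits = c("FGFR1", "FGFR1_FGFR2", "NRXN1"),
    pathway = c("FGF", "FGF", "NRXN"),
    agonists = c("AGA", "", ""),
    antagonists = c("", "ANB", ""),
    co_stimulatory = "", co_inhibitory = "",
    category = c("secreted", "secreted", "cell_contact"),
    stringsAsFactors = FALSE))
}

# deterministic dataset: two cell types, explicit values, one sample per
# condition unless told otherwise
tinyDataset <- function(nPerType = 10L, genes = c("FGF1", "FGF2", "FGFR1",
                                                  "FGFR2", "NRXN1", "NLGN1",
                                                  "AGA", "ANB"),
                        senderHigh = c("FGF1", "FGF2", "NLGN1", "AGA", "ANB"),
                        receiverHigh = c("FGFR1", "FGFR2", "NRXN1"),
                        high = 3, low = 0) {
  n <- 2L * nPerType
  m <- matrix(low, length(genes), n,
              dimnames = list(genes, sprintf("c%03d", seq_len(n))))
  sender <- seq_len(nPerType)
  m[senderHigh, sender] <- high
  m[receiverHigh, -sender] <- high
  CCCExperiment(m, cellType = rep(c("A", "B"), each = nPerType),
                sample = rep("s1", n), condition = rep("case", n))
}

# exchangeable-label dataset: every gene iid across all cells
nullDataset <- function(nTypes = 4L, cellsPerType = 30L, genes, seed) {
  set.seed(seed)
  n <- nTypes * cellsPerType
  m <- matrix(abs(rnorm(length(genes) * n, mean = 2, sd = 0.5)),
              length(genes), n,
              dimnames = list(genes, sprintf("c%04d", seq_len(n))))
  CCCExperiment(m, cellType = rep(LETTERS[seq_len(nTypes)],
                                  each = cellsPerType),
                sample = rep("s1", n), condition = rep("case", n))
}

# rank-sum two-sided exact p by full enumeration of group assignments
ranksumEnumP <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u <- apply(combs, 2L, function(idx)
    sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u <= uObs), mean(u >= uObs)))
}

# hypergeometric upper tail by brute-force enumeration of query draws
hyperEnumP <- function(N, K, n, k) {
  combs <- utils::combn(N, n)
  hits <- apply(combs, 2L, function(idx) sum(idx <= K))
  mean(hits >= k)
}

# two-sided Fisher exact p by enumerating the hypergeometric support
fisherEnumP <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# direct arithmetic mass-action oracle (independent of the package path)
oracleStrength <- function(L, R, kh = 0.5, AG = 0, AN = 0, CS = 0, CI = 0) {
  R2 <- R * (1 + CS / (kh + CS)) * (kh / (kh + CI))
  (L * R2) / (kh + L * R2) * (1 + AG / (kh + AG)) * (kh / (kh + AN))
}

# planted two-block non-negative matrix for NMF tests
blockMatrix <- function(nRows = 10L, nCols = 8L, noise = 0, seed = 1L) {
  set.seed(seed)
  half <- nRows %/% 2L
  m <- matrix(0.05, nRows, nCols)
  m[seq_len(half), seq_len(nCols %/% 2L)] <- 1
  m[(half + 1L):nRows, (nCols %/% 2L + 1L):nCols] <- 1
  if (noise > 0) m <- pmax(m + matrix(rnorm(nRows * nCols, 0, noise),
                                      nRows, nCols), 0)
  rownames(m) <- sprintf("T%02d", seq_len(nRows))
  colnames(m) <- sprintf("P%02d", seq_len(nCols))
  m
}

# small sample-level fixture built directly
mkScores <- function(m, cond, pathwayOf = NULL) {
  units <- colnames(m)
  anno <- data.frame(unit = units, sender = "A", receiver = "B",
                     interaction = units,
                     pathway = if (is.null(pathwayOf)) units else pathwayOf,
                     stringsAsFactors = FALSE)
  new("SampleLevelScores", pathway_scores = m, lr_scores = m,
      detected = m > 0, condition = cond, lr_anno = anno,
      flagged = character(0))
}

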