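#' @importFrom stats wilcox.test p.adjust prcomp sd cor
NULL

.split_conditions <- function(ds) {
  lev <- unique(condition(ds))
  if (length(lev) != 2L)
    stop("exactly two conditions required, found: ",
         paste(lev, collapse = ", "))
  lev
}

#' Global (merged) two-condition comparison
#'
#' Merges all cells of each condition into one group, infers communication
#' per condition over the cell types shared by both, and reports per
#' cell-pair differences in significant interaction counts and total
#' strengths (condition A minus condition B), plus a per-pathway two-sided
#' Wilcoxon signed-rank test pairing the (sender, receiver) pathway-score
#' vectors of the two conditions (zeros included; all-zero difference
#' vectors report p = 1).
#'
#' @param ds a [CCCExperiment-class] with two conditions.
#' @param db an [LRDatabase-class].
#' @param params a [cccParams()] list.
#' @param seed optional integer seed.
#' @param conditionA which condition plays "A" (default: first encountered).
#' @return list with `conditionA`, `conditionB`, `tensorA`, `tensorB`,
#'   `scoresA`, `scoresB`, `count_diff`, `strength_diff` (sender x receiver
#'   matrices) and `pathway` (data.frame: pathway, flow per condition, p,
#'   direction).
#' @export
globalCompare <- function(ds, db, params = cccParams(), seed = NULL,
                          conditionA = NULL) {
  lev <- .split_conditions(ds)
  if (is.null(conditionA)) conditionA <- lev[1L]
  conditionB <- setdiff(lev, conditionA)
  typesA <- unique(cellType(ds)[condition(ds) == conditionA])
  typesB <- unique(cellType(ds)[condition(ds) == conditionB])
  shared <- intersect(typesA, typesB)
  only <- setdiff(union(typesA, typesB), shared)
  if (length(only))
    warning("cell type(s) present in only one condition excluded: ",
            paste(only, collapse = ", "))
  if (length(shared) < 2L)
    stop("fewer than two cell types shared by both conditions")
  if (!is.null(seed)) set.seed(seed)
  keep <- cellType(ds) %in% shared
  dsA <- ds[, keep & condition(ds) == conditionA]
  dsB <- ds[, keep & condition(ds) == conditionB]
  tA <- suppressWarnings(inferCommunication(dsA, db, params))
  tB <- suppressWarnings(inferCommunication(dsB, db, params))
  mA <- countStrengthMaps(tA)
  mB <- countStrengthMaps(tB)
  types <- sort(shared)
  cd <- mA$counts[types, types] - mB$counts[types, types]
  sdm <- mA$totals[types, types] - mB$totals[types, types]
  psA <- aggregatePathways(tA, db)
  psB <- aggregatePathways(tB, db)
  upw <- dimnames(psA@score)[[3L]]
  path <- lapply(upw, function(p) {
    a <- as.vector(psA@score[types, types, p])
    b <- as.vector(psB@score[types, types, p])
    pv <- if (all(a == b)) 1 else
      suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
    data.frame(pathway = p, flow_A = sum(a), flow_B = sum(b), p = pv,
               direction = if (pv < params$alpha && sum(a) > sum(b)) "up_in_A"
                           else if (pv < params$alpha && sum(a) < sum(b))
                             "down_in_A" else "ns",
               stringsAsFactors = FALSE)
  })
  list(conditionA = conditionA, conditionB = conditionB,
       tensorA = tA, tensorB = tB, scoresA = psA, scoresB = psB,
       count_diff = cd, strength_diff = sdm,
       pathway = do.call(rbind, path))
}

#' Per-sample pseudo-bulk communication scores
#'
#' Runs the inference independently within each sample (permutations shuffle
#' labels within the sample) and assembles sample x pathway and
#' sample x (cell pair, interaction) score matrices. Samples with fewer than
#' two populated cell types get a row of zeros and are flagged.
#'
#' @param ds a [CCCExperiment-class].
#' @param db an [LRDatabase-class].
#' @param params a [cccParams()] list.
#' @param seed optional integer seed.
#' @return a [SampleLevelScores-class].
#' @export
perSampleScores <- function(ds, db, params = cccParams(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- unique(sampleId(ds))
  types <- sort(unique(cellType(ds)))
  upw <- unique(db@interactions$pathway)
  ids <- db@interactions$id
  grid <- expand.grid(sender = types, receiver = types, interaction = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$pathway <- db@interactions$pathway[match(grid$interaction, ids)]
  units <- paste(grid$sender, grid$receiver, grid$interaction, sep = "|")
  pmat <- matrix(0, length(samples), length(upw),
                 dimnames = list(samples, upw))
  lmat <- matrix(0, length(samples), length(units),
                 dimnames = list(samples, units))
  flagged <- character(0)
  .db_expr(ds, db)  # one aggregated absent-gene warning up front
  for (s in samples) {
    dss <- ds[, sampleId(ds) == s]
    tys <- unique(cellType(dss))
    if (length(tys) < 2L) {
      flagged <- c(flagged, s)
      next
    }
    tens <- suppressWarnings(inferCommunication(dss, db, params))
    sig <- tens@strength * significantMask(tens)
    ps <- aggregatePathways(tens, db)
    pmat[s, ] <- informationFlow(ps)[upw]
    # scatter this sample's triples into the full type x type x id grid
    idx <- which(grid$sender %in% tys & grid$receiver %in% tys)
    lmat[s, idx] <- sig[cbind(match(grid$sender[idx], dimnames(sig)[[1L]]),
                              match(grid$receiver[idx], dimnames(sig)[[2L]]),
                              match(grid$interaction[idx],
                                    dimnames(sig)[[3L]]))]
  }
  if (length(flagged))
    warning("sample(s) with fewer than two cell types scored as zero: ",
            paste(flagged, collapse = ", "))
  scond <- vapply(samples, function(s)
    condition(ds)[match(s, sampleId(ds))], "")
  anno <- data.frame(unit = units, grid, stringsAsFactors = FALSE)
  methods::new("SampleLevelScores", pathway_scores = pmat, lr_scores = lmat,
               detected = pmat > 0, condition = scond, lr_anno = anno,
               flagged = flagged)
}

#' Remove pathways detected in too few samples
#'
#' A pathway counts as identified in a sample when its per-sample score is
#' positive (after within-sample significance filtering). Pathways
#' identified in fewer than `minSamples` samples (both groups pooled) are
#' removed; one identified in exactly `minSamples` is retained. L-R units of
#' removed pathways are dropped too.
#'
#' @param sls a [SampleLevelScores-class].
#' @param minSamples minimum number of samples (default 5).
#' @return a filtered [SampleLevelScores-class].
#' @export
filterPathways <- function(sls, minSamples = 5L) {
  n <- colSums(sls@detected)
  keep <- names(n)[n >= minSamples]
  keepUnit <- sls@lr_anno$pathway %in% keep
  methods::new("SampleLevelScores",
               pathway_scores = sls@pathway_scores[, keep, drop = FALSE],
               lr_scores = sls@lr_scores[, keepUnit, drop = FALSE],
               detected = sls@detected[, keep, drop = FALSE],
               condition = sls@condition,
               lr_anno = sls@lr_anno[keepUnit, , drop = FALSE],
               flagged = sls@flagged)
}

.wilcox_p <- function(a, b) {
  if (sd(c(a, b)) == 0) return(1)
  suppressWarnings(wilcox.test(a, b, exact = length(a) <= 50 &&
                                 length(b) <= 50,
                               correct = TRUE)$p.value)
}

#' Pseudo-bulk Wilcoxon tests between sample groups
#'
#' Two-sided Wilcoxon rank-sum tests per pathway (or per cell-pair L-R unit)
#' comparing the per-sample scores of the two condition groups, with
#' Benjamini-Hochberg FDR within the tested family. The exact null
#' distribution is used when there are no ties; otherwise the normal
#' approximation with tie correction. Units constant across all samples are
#' flagged degenerate with p = 1.
#'
#' @param sls a [SampleLevelScores-class] (typically after
#'   [filterPathways()]).
#' @param what `"pathway"` or `"lr"` family.
#' @param alpha nominal significance level used for the direction call.
#' @param conditionA which condition plays "A" (default: first encountered).
#' @return data.frame with `unit`, `mean_A`, `mean_B`, `sd_A`, `sd_B`,
#'   `fold_change`, `p`, `fdr`, `direction` (`up_in_A` / `down_in_A` / `ns`)
#'   and `degenerate`. Fold change is `(mean_A + eps)/(mean_B + eps)` with
#'   `eps` = smallest positive score x 1e-3 (stored in the `"eps"`
#'   attribute).
#' @export
sampleWilcoxon <- function(sls, what = c("pathway", "lr"), alpha = 0.05,
                           conditionA = NULL) {
  what <- match.arg(what)
  m <- if (what == "pathway") sls@pathway_scores else sls@lr_scores
  lev <- unique(sls@condition)
  if (length(lev) != 2L)
    stop("exactly two condition groups required")
  if (is.null(conditionA)) conditionA <- lev[1L]
  conditionB <- setdiff(lev, conditionA)
  ga <- sls@condition == conditionA
  gb <- sls@condition == conditionB
  if (sum(ga) < 2L || sum(gb) < 2L)
    stop("both groups need at least two samples")
  if (ncol(m) == 0L) {
    out <- data.frame(unit = character(0), mean_A = numeric(0),
                      mean_B = numeric(0), sd_A = numeric(0),
                      sd_B = numeric(0), fold_change = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      direction = character(0), degenerate = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "conditionA") <- conditionA
    return(out)
  }
  pos <- m[m > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1e-9
  message("fold-change pseudocount eps = ", signif(eps, 3L))
  res <- lapply(colnames(m), function(u) {
    a <- m[ga, u]; b <- m[gb, u]
    degen <- sd(c(a, b)) == 0
    p <- .wilcox_p(a, b)
    ma <- mean(a); mb <- mean(b)
    data.frame(unit = u, mean_A = ma, mean_B = mb,
               sd_A = sd(a), sd_B = sd(b),
               fold_change = (ma + eps) / (mb + eps),
               p = p, degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$direction <- ifelse(out$p < alpha & out$mean_A > out$mean_B, "up_in_A",
                          ifelse(out$p < alpha & out$mean_A < out$mean_B,
                                 "down_in_A", "ns"))
  out <- out[, c("unit", "mean_A", "mean_B", "sd_A", "sd_B", "fold_change",
                 "p", "fdr", "direction", "degenerate")]
  attr(out, "eps") <- eps
  attr(out, "conditionA") <- conditionA
  out
}

#' PCA of samples on pathway scores
#'
#' Centered (unscaled by default) principal components of the
#' sample x pathway score matrix.
#'
#' @param sls a [SampleLevelScores-class] with at least 3 samples and 2
#'   pathways.
#' @param scale. scale pathways to unit variance (default `FALSE`).
#' @return list with `coordinates` (samples x PCs, with the sample condition
#'   as a `condition` column in the accompanying data.frame
#'   `coordinates_df`), and `variance_explained` summing to 1.
#' @export
pcaSamples <- function(sls, scale. = FALSE) {
  m <- sls@pathway_scores
  if (nrow(m) < 3L) stop("at least 3 samples required")
  if (ncol(m) < 2L) stop("at least 2 pathways required")
  keep <- apply(m, 2L, sd) > 0
  if (scale.) m <- m[, keep, drop = FALSE]
  if (all(apply(m, 2L, sd) == 0)) stop("rank-0 score matrix")
  pc <- prcomp(m, center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x,
       coordinates_df = data.frame(sample = rownames(m),
                                   condition = unname(sls@condition),
                                   pc$x, stringsAsFactors = FALSE),
       variance_explained = ve)
}

#' Subsampling robustness of the global comparison
#'
#' Repeats the global comparison on random subsets of cells (fraction
#' `frac`, `reps` times) and reports, for every cell pair, the mean and SD
#' of the subsampled strength differences and their Pearson correlation with
#' the full-data differences.
#'
#' @param ds a [CCCExperiment-class] with two conditions.
#' @param db an [LRDatabase-class].
#' @param params a [cccParams()] list.
#' @param frac fraction of cells kept per repeat, in `(0, 1]`.
#' @param reps number of repeats (>= 2, default 10; `frac = 1` repeats are
#'   identical to the full data).
#' @param seed optional integer seed.
#' @return list with `full_diff`, `mean_diff`, `sd_diff` (matrices), a
#'   long-form `table` per cell pair (write it as `robustness.tsv`),
#'   `correlation` (Pearson r of mean subsampled vs full differences) and
#'   `per_rep_correlation`.
#' @export
subsampleRobustness <- function(ds, db, params = cccParams(), frac = 0.5,
                                reps = 10L, seed = NULL) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]")
  if (reps < 2L) stop("reps must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  # one shared permutation seed so that frac = 1 reproduces the full run
  permSeed <- sample.int(.Machine$integer.max - 1L, 1L)
  keeps <- lapply(seq_len(reps), function(r)
    sort(sample(ncol(ds), max(2L, round(frac * ncol(ds))))))
  full <- globalCompare(ds, db, params, seed = permSeed)
  diffs <- vector("list", reps)
  for (r in seq_len(reps)) {
    gc <- globalCompare(ds[, keeps[[r]]], db, params, seed = permSeed,
                        conditionA = full$conditionA)
    d <- matrix(0, nrow(full$strength_diff), ncol(full$strength_diff),
                dimnames = dimnames(full$strength_diff))
    shared <- intersect(rownames(d), rownames(gc$strength_diff))
    d[shared, shared] <- gc$strength_diff[shared, shared]
    diffs[[r]] <- d
  }
  arr <- simplify2array(diffs)
  mean_diff <- apply(arr, c(1L, 2L), mean)
  sd_diff <- apply(arr, c(1L, 2L), sd)
  types <- rownames(full$strength_diff)
  grid <- expand.grid(sender = types, receiver = types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- data.frame(grid, full_diff = as.vector(full$strength_diff),
                    mean_diff = as.vector(mean_diff),
                    sd_diff = as.vector(sd_diff),
                    stringsAsFactors = FALSE)
  list(full_diff = full$strength_diff, mean_diff = mean_diff,
       sd_diff = sd_diff, table = tab,
       correlation = cor(as.vector(mean_diff),
                         as.vector(full$strength_diff)),
       per_rep_correlation = vapply(diffs, function(d)
         cor(as.vector(d), as.vector(full$strength_diff)), 1))
}
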