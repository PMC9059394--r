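#' @useDynLib cccdiff, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Inference parameters
#'
#' Parameters of the mass-action communication model and its permutation
#' test.
#'
#' @param kh half-saturation constant of the Hill-type response
#'   (default 0.5, the value used by the mass-action formulation this model
#'   follows), on the scale of summarized log expression.
#' @param useCofactors apply agonist/antagonist and co-stimulatory /
#'   co-inhibitory modulation (default `TRUE`).
#' @param nPerm number of label permutations (default 100).
#' @param alpha significance level for the permutation test (default 0.05).
#' @param threshold minimum fraction of expressing cells per cell type; genes
#'   below it contribute zero expression (default 0.2).
#' @param summary per-cell-type expression summary: `"trimean"` (25%
#'   truncated mean, robust to zero inflation) or `"mean"`.
#' @return a validated list of class `CCCParams`.
#' @export
cccParams <- function(kh = 0.5, useCofactors = TRUE, nPerm = 100L,
                      alpha = 0.05, threshold = 0.2,
                      summary = c("trimean", "mean")) {
  summary <- match.arg(summary)
  if (kh <= 0) stop("kh must be positive")
  if (nPerm < 1L) stop("nPerm must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  structure(list(kh = kh, useCofactors = useCofactors,
                 nPerm = as.integer(nPerm), alpha = alpha,
                 threshold = threshold, summary = summary),
            class = "CCCParams")
}

# dense expression submatrix over the database's genes (uppercase symbol
# match); genes named in the database but absent from the matrix become
# zero rows, reported once.
.db_expr <- function(ds, db, warn = TRUE) {
  genes <- .db_genes(db)
  rn <- toupper(rownames(ds))
  idx <- match(genes, rn)
  absent <- genes[is.na(idx)]
  if (length(absent) && warn)
    warning(length(absent), " database gene(s) absent from the matrix, ",
            "treated as zero expression: ",
            paste(utils::head(absent, 5L), collapse = ", "),
            if (length(absent) > 5L) ", ...")
  a <- assay(ds, "logcounts")
  X <- matrix(0, nrow = length(genes), ncol = ncol(ds),
              dimnames = list(genes, colnames(ds)))
  ok <- !is.na(idx)
  X[ok, ] <- as.matrix(a[idx[ok], , drop = FALSE])
  X
}

.interaction_indices <- function(db, genes) {
  x <- db@interactions
  f <- function(col) lapply(x[[col]], function(g) match(g, genes))
  list(lig = f("ligand_subunits"), rec = f("receptor_subunits"),
       ago = f("agonists"), ant = f("antagonists"),
       cst = f("co_stimulatory"), cin = f("co_inhibitory"))
}

#' Summarize expression per cell type
#'
#' Computes, for each (cell type, gene), a summary expression value and the
#' fraction of cells with non-zero expression. Any summary whose expression
#' fraction falls below `threshold` is forced to zero, so genes expressed in
#' less than that share of a type's cells are excluded from communication
#' scoring.
#'
#' @param ds a [CCCExperiment-class].
#' @param threshold expression-fraction cutoff in `[0, 1]` (default 0.2).
#' @param summary `"trimean"` (25% truncated mean) or `"mean"`.
#' @return list with `mean` and `frac`, both genes x cell-type matrices.
#' @export
summarizeProfiles <- function(ds, threshold = 0.2,
                              summary = c("trimean", "mean")) {
  summary <- match.arg(summary)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ct <- factor(cellType(ds))
  X <- as.matrix(assay(ds, "logcounts"))
  res <- group_summary_cpp(X, as.integer(ct), nlevels(ct),
                           0.25, summary == "trimean", threshold)
  dimnames(res$mean) <- dimnames(res$frac) <-
    list(rownames(ds), levels(ct))
  res
}

#' Complex-level expression
#'
#' Geometric mean of the summary expression of a complex's subunits; the
#' absence (zero summary) of any subunit nulls the complex.
#'
#' @param profile output of [summarizeProfiles()].
#' @param subunits character vector of subunit gene symbols (length >= 1).
#' @param cellType cell-type label (column of the profile).
#' @return a single non-negative value.
#' @export
complexExpression <- function(profile, subunits, cellType) {
  if (length(subunits) < 1L) stop("empty complex")
  v <- vapply(toupper(subunits), function(g) {
    if (!g %in% rownames(profile$mean)) {
      warning("subunit ", g, " absent from profile; treated as zero")
      return(0)
    }
    profile$mean[g, cellType]
  }, 1)
  if (any(v <= 0)) return(0)
  exp(mean(log(v)))
}

#' Mass-action interaction strength
#'
#' Hill-type response `L*R / (kh + L*R)` of ligand and receptor complex
#' expression, optionally modulated by cofactors: the receiver-side
#' co-stimulatory and co-inhibitory terms rescale R to
#' `R * (1 + CS/(kh+CS)) * kh/(kh+CI)` before the response, and the
#' sender-side agonist and antagonist terms multiply the response by
#' `(1 + AG/(kh+AG)) * kh/(kh+AN)`. Without cofactors the value lies in
#' `[0, 1)`; with cofactors it is bounded by 2. The strength is
#' non-decreasing in L, R, AG and CS and non-increasing in AN and CI.
#'
#' @param L,R ligand and receptor complex expression (non-negative).
#' @param AG,AN,CS,CI cofactor summary expressions (arithmetic means over the
#'   respective gene sets; 0 disables a term).
#' @param params a [cccParams()] list.
#' @return a single value in `[0, 2)`.
#' @examples
#' interactionStrength(1, 1)  # 2/3 at the default kh = 0.5
#' @export
interactionStrength <- function(L, R, AG = 0, AN = 0, CS = 0, CI = 0,
                                params = cccParams()) {
  if (any(c(L, R, AG, AN, CS, CI) < 0)) stop("negative inputs")
  kh <- params$kh
  if (params$useCofactors)
    R <- R * (1 + CS / (kh + CS)) * (kh / (kh + CI))
  base <- (L * R) / (kh + L * R)
  if (params$useCofactors)
    base <- base * (1 + AG / (kh + AG)) * (kh / (kh + AN))
  base
}

#' Infer the cell-cell communication tensor
#'
#' Computes mass-action strengths for every (sender cell type, receiver cell
#' type, interaction) triple from per-type summarized expression, and assigns
#' each triple a permutation p-value by shuffling cell-type labels across all
#' cells of the dataset (`nPerm` times, counts per type preserved) and
#' recomputing the strengths. The p-value uses the add-one estimator
#' `(1 + k)/(1 + nPerm)` with inclusive ties, so it is never zero and a zero
#' observed strength reports p = 1.
#'
#' @param ds a [CCCExperiment-class] with at least two cell types.
#' @param db an [LRDatabase-class].
#' @param params a [cccParams()] list.
#' @param seed optional integer seed for reproducible permutations.
#' @return a [CommunicationTensor-class].
#' @export
inferCommunication <- function(ds, db, params = cccParams(), seed = NULL) {
  ct <- factor(cellType(ds))
  if (nlevels(ct) < 2L) stop("at least two cell types required")
  if (!is.null(seed)) set.seed(seed)
  genes <- .db_genes(db)
  X <- .db_expr(ds, db)
  # genes absent from the matrix map to a dedicated all-zero row
  X <- rbind(X, `.absent.` = 0)
  zrow <- nrow(X)
  idx <- .interaction_indices(db, genes)
  idx <- lapply(idx, function(l) lapply(l, function(v) {
    v[is.na(v)] <- zrow
    as.integer(v)
  }))
  res <- ccc_infer_cpp(X, as.integer(ct), nlevels(ct),
                       idx$lig, idx$rec, idx$ago, idx$ant, idx$cst, idx$cin,
                       params$kh, 0.25, params$summary == "trimean",
                       params$threshold, params$useCofactors, params$nPerm)
  dn <- list(levels(ct), levels(ct), db@interactions$id)
  dimnames(res$strength) <- dimnames(res$pval) <- dn
  anno <- data.frame(id = db@interactions$id,
                     ligand = db@interactions$ligand_name,
                     receptor = db@interactions$receptor_name,
                     pathway = db@interactions$pathway,
                     category = db@interactions$category,
                     stringsAsFactors = FALSE)
  methods::new("CommunicationTensor", strength = res$strength,
               pval = res$pval, alpha = params$alpha, anno = anno)
}

#' Permutation test for a single communication triple
#'
#' @param ds a [CCCExperiment-class].
#' @param db an [LRDatabase-class].
#' @param sender,receiver cell-type labels.
#' @param interaction interaction id in `db`.
#' @param params a [cccParams()] list.
#' @param seed optional integer seed.
#' @return the permutation p-value for the triple.
#' @export
permutationTest <- function(ds, db, sender, receiver, interaction,
                            params = cccParams(), seed = NULL) {
  keep <- db@interactions$id == interaction
  if (!any(keep)) stop("unknown interaction: ", interaction)
  sub <- methods::new("LRDatabase",
                      interactions = db@interactions[keep, , drop = FALSE])
  tens <- suppressWarnings(
    inferCommunication(ds, sub, params = params, seed = seed))
  pvalues(tens)[sender, receiver, 1L]
}

#' Aggregate significant interaction strengths to pathway scores
#'
#' For every (sender, receiver, pathway), sums the strengths of the pathway's
#' interactions whose permutation p-value is below `alpha`; non-significant
#' strengths are excluded. Pathways with all-zero scores are flagged as not
#' detected.
#'
#' @param tensor a [CommunicationTensor-class].
#' @param db the [LRDatabase-class] used to build it.
#' @return a [PathwayScores-class].
#' @export
aggregatePathways <- function(tensor, db) {
  pw <- db@interactions$pathway
  upw <- unique(pw)
  d <- dim(tensor@strength)
  sig <- tensor@strength * significantMask(tensor)
  score <- array(0, dim = c(d[1L], d[2L], length(upw)),
                 dimnames = c(dimnames(tensor@strength)[1:2], list(upw)))
  for (p in seq_along(upw)) {
    sel <- which(pw == upw[p])
    score[, , p] <- apply(sig[, , sel, drop = FALSE], c(1L, 2L), sum)
  }
  detected <- apply(score, 3L, function(m) any(m > 0))
  names(detected) <- upw
  methods::new("PathwayScores", score = score, detected = detected)
}

#' Per-cell-pair interaction counts and total strengths
#'
#' @param tensor a [CommunicationTensor-class].
#' @return list with `counts` (number of significant interactions per
#'   sender/receiver pair) and `totals` (their summed strengths), both
#'   sender x receiver matrices.
#' @export
countStrengthMaps <- function(tensor) {
  mask <- significantMask(tensor)
  list(counts = apply(mask, c(1L, 2L), sum),
       totals = apply(tensor@strength * mask, c(1L, 2L), sum))
}

#' Pathway information flow
#'
#' The information flow of a pathway is its score summed over all
#' sender-receiver cell pairs.
#'
#' @param ps a [PathwayScores-class].
#' @return named numeric vector of per-pathway flows.
#' @export
informationFlow <- function(ps) {
  apply(ps@score, 3L, sum)
}

#' Relative information flow between two conditions
#'
#' Normalizes each pathway's flow across two conditions:
#' `flowA / (flowA + flowB)` versus `flowB / (flowA + flowB)`. Pathways with
#' flow in exactly one condition are labeled specific to it; pathways with
#' zero flow in both are dropped with a message.
#'
#' @param psA,psB [PathwayScores-class] for the two conditions, scored on the
#'   same pathway universe (the union is used, missing pathways counting 0).
#' @return data.frame with `pathway`, `flow_A`, `flow_B`, `rel_A`, `rel_B`
#'   and `specific` (`""`, `"A"` or `"B"`).
#' @export
relativeFlow <- function(psA, psB) {
  fA <- informationFlow(psA)
  fB <- informationFlow(psB)
  upw <- union(names(fA), names(fB))
  a <- ifelse(upw %in% names(fA), fA[upw], 0)
  b <- ifelse(upw %in% names(fB), fB[upw], 0)
  drop <- a == 0 & b == 0
  if (any(drop))
    message("dropping ", sum(drop), " pathway(s) with zero flow in both ",
            "conditions: ", paste(upw[drop], collapse = ", "))
  upw <- upw[!drop]; a <- a[!drop]; b <- b[!drop]
  tot <- a + b
  data.frame(pathway = upw, flow_A = unname(a), flow_B = unname(b),
             rel_A = unname(a / tot), rel_B = unname(b / tot),
             specific = ifelse(a > 0 & b == 0, "A",
                               ifelse(b > 0 & a == 0, "B", "")),
             stringsAsFactors = FALSE)
}

#' Cell-type contributions to pathway signaling
#'
#' Outgoing contribution of a cell type to a pathway is its pathway score
#' summed over receivers; incoming sums over senders. In relative form each
#' pathway column is divided by its maximum, so every detected pathway has
#' column maximum 1.
#'
#' @param ps a [PathwayScores-class].
#' @param direction `"outgoing"` or `"incoming"`.
#' @param relative divide each pathway column by its maximum.
#' @return cell_type x pathway matrix.
#' @export
celltypeContributions <- function(ps, direction = c("outgoing", "incoming"),
                                  relative = FALSE) {
  direction <- match.arg(direction)
  m <- if (direction == "outgoing") apply(ps@score, c(1L, 3L), sum)
       else apply(ps@score, c(2L, 3L), sum)
  if (relative) {
    mx <- apply(m, 2L, max)
    m <- sweep(m, 2L, ifelse(mx > 0, mx, 1), "/")
  }
  m
}
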