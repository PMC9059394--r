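#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# LRDatabase
# ---------------------------------------------------------------------------

#' Ligand-receptor interaction database
#'
#' Holds curated ligand-receptor interactions with heteromeric complexes,
#' optional cofactor annotations (soluble agonists / antagonists and
#' membrane-bound co-stimulatory / co-inhibitory co-receptors) and a
#' signaling-pathway family label per interaction. Pathways partition the
#' interactions: every interaction belongs to exactly one pathway.
#'
#' The `interactions` slot is a data.frame with columns `id`, `ligand_name`,
#' `ligand_subunits` (list of character), `receptor_name`,
#' `receptor_subunits` (list), `pathway`, `agonists`, `antagonists`,
#' `co_stimulatory`, `co_inhibitory` (lists), and `category` (one of
#' `"secreted"`, `"ecm_receptor"`, `"cell_contact"`).
#'
#' @slot interactions data.frame as described above.
#' @seealso [readLRDatabase()], [pathwayGeneSet()], [generateToyDB()]
#' @export
setClass("LRDatabase", representation(interactions = "data.frame"))

.lr_list_cols <- c("ligand_subunits", "receptor_subunits", "agonists",
                   "antagonists", "co_stimulatory", "co_inhibitory")
.lr_categories <- c("secreted", "ecm_receptor", "cell_contact")

setValidity("LRDatabase", function(object) {
  x <- object@interactions
  need <- c("id", "ligand_name", "ligand_subunits", "receptor_name",
            "receptor_subunits", "pathway", .lr_list_cols[-(1:2)], "category")
  miss <- setdiff(need, names(x))
  if (length(miss))
    return(paste("missing interaction columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(x$id))
    return(paste("duplicate interaction id(s):",
                 paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  for (col in c("ligand_subunits", "receptor_subunits")) {
    n <- vapply(x[[col]], length, 1L)
    if (any(n < 1L))
      return(paste0("empty complex in ", col, " (id ",
                    x$id[which(n < 1L)[1L]], ")"))
    if (any(vapply(x[[col]], anyDuplicated, 1L) > 0L))
      return(paste("duplicate subunits within a complex in", col))
  }
  if (any(!nzchar(x$pathway)) || anyNA(x$pathway))
    return("every interaction needs a non-empty pathway label")
  if (any(grepl("[;,|]", x$pathway)))
    return("multi-pathway membership is not supported (one pathway per interaction)")
  if (!all(x$category %in% .lr_categories))
    return(paste("category must be one of:", paste(.lr_categories, collapse = ", ")))
  # a complex name must always resolve to the same subunit set
  for (side in c("ligand", "receptor")) {
    nm <- x[[paste0(side, "_name")]]
    su <- vapply(x[[paste0(side, "_subunits")]], paste, "", collapse = "_")
    if (any(vapply(split(su, nm), function(z) length(unique(z)), 1L) > 1L))
      return(paste(side, "complex name mapped to more than one subunit set"))
  }
  TRUE
})

#' @describeIn LRDatabase number of interactions
#' @param x,object an `LRDatabase`
#' @export
setMethod("length", "LRDatabase", function(x) nrow(x@interactions))

setMethod("show", "LRDatabase", function(object) {
  x <- object@interactions
  cat("LRDatabase with", nrow(x), "interactions in",
      length(unique(x$pathway)), "pathways\n")
  ncx <- sum(vapply(x$ligand_subunits, length, 1L) > 1L |
             vapply(x$receptor_subunits, length, 1L) > 1L)
  ncf <- sum(vapply(seq_len(nrow(x)), function(i)
    sum(lengths(lapply(.lr_list_cols[-(1:2)], function(col) x[[col]][[i]]))), 1L) > 0L)
  cat("  heteromeric complexes:", ncx, " with cofactors:", ncf, "\n")
  cat("  categories:",
      paste(names(table(x$category)), table(x$category), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# CCCExperiment
# ---------------------------------------------------------------------------

#' Annotated expression dataset for communication analysis
#'
#' A [SingleCellExperiment::SingleCellExperiment] carrying a log-normalized
#' genes x cells matrix in the `"logcounts"` assay plus per-cell `cell_type`,
#' `sample` and `condition` labels (and optionally `region`) in `colData`.
#' Values must be non-negative (library-size normalized, log-transformed
#' expression, as in typical single-nucleus downloads); each sample must map
#' to exactly one condition.
#'
#' @export
setClass("CCCExperiment", contains = "SingleCellExperiment")

setValidity("CCCExperiment", function(object) {
  cd <- colData(object)
  need <- c("cell_type", "sample", "condition")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    return(paste("colData must contain:", paste(miss, collapse = ", ")))
  if (!"logcounts" %in% names(assays(object)))
    return("a 'logcounts' assay is required")
  for (f in need)
    if (anyNA(cd[[f]])) return(paste0("NA values in colData$", f))
  m <- tapply(as.character(cd$condition), as.character(cd$sample),
              function(z) length(unique(z)))
  if (any(m > 1L))
    return(paste("sample(s) mapped to more than one condition:",
                 paste(names(m)[m > 1L], collapse = ", ")))
  a <- assay(object, "logcounts")
  mn <- if (methods::is(a, "sparseMatrix")) min(a@x, 0) else suppressWarnings(min(a))
  if (ncol(object) > 0L && nrow(object) > 0L && mn < 0)
    return("expression values must be non-negative (log-normalized scale)")
  TRUE
})

#' Construct a CCCExperiment
#'
#' @param mat genes x cells matrix of non-negative, log-normalized expression
#'   (dense or `Matrix` sparse); rownames are gene symbols, colnames cell ids.
#' @param cellType,sample,condition per-cell labels (condition may also be a
#'   named per-sample vector).
#' @param region optional per-cell (or per-sample, named) region label.
#' @return a validated [CCCExperiment-class] object.
#' @examples
#' m <- matrix(abs(rnorm(20)), 5, 4,
#'             dimnames = list(paste0("G", 1:5), paste0("c", 1:4)))
#' ds <- CCCExperiment(m, cellType = c("A", "A", "B", "B"),
#'                     sample = c("s1", "s1", "s2", "s2"),
#'                     condition = c(s1 = "case", s2 = "control"))
#' @export
CCCExperiment <- function(mat, cellType, sample, condition, region = NULL) {
  sample <- as.character(sample)
  if (!is.null(names(condition)) &&
      all(unique(sample) %in% names(condition))) {
    condition <- unname(condition[sample])
  }
  if (!is.null(region) && !is.null(names(region)) &&
      all(unique(sample) %in% names(region))) {
    region <- unname(region[sample])
  }
  cd <- DataFrame(cell_type = as.character(cellType), sample = sample,
                  condition = as.character(condition),
                  row.names = colnames(mat))
  if (!is.null(region)) cd$region <- as.character(region)
  sce <- SingleCellExperiment(assays = list(logcounts = mat), colData = cd)
  methods::new("CCCExperiment", sce)
}

#' @describeIn CCCExperiment per-cell cell-type labels
#' @param x a `CCCExperiment`
#' @export
cellType <- function(x) as.character(colData(x)$cell_type)

#' @describeIn CCCExperiment per-cell sample ids
#' @export
sampleId <- function(x) as.character(colData(x)$sample)

#' @describeIn CCCExperiment per-cell condition labels
#' @export
condition <- function(x) as.character(colData(x)$condition)

# ---------------------------------------------------------------------------
# CommunicationTensor
# ---------------------------------------------------------------------------

#' Sender x receiver x interaction communication strengths
#'
#' Mass-action interaction strengths ("communication probabilities", in
#' `[0, 1)` without cofactors) and label-permutation p-values for every
#' (sender cell type, receiver cell type, interaction) triple. A zero
#' strength carries p = 1 by convention; the significance mask is
#' `pval < alpha`.
#'
#' @slot strength,pval 3-d arrays (sender x receiver x interaction).
#' @slot alpha numeric significance level.
#' @slot anno data.frame with one row per interaction (id, ligand, receptor,
#'   pathway, category).
#' @export
setClass("CommunicationTensor",
         representation(strength = "array", pval = "array",
                        alpha = "numeric", anno = "data.frame"))

setValidity("CommunicationTensor", function(object) {
  if (!identical(dim(object@strength), dim(object@pval)))
    return("strength and pval dimensions differ")
  if (length(dim(object@strength)) != 3L)
    return("strength must be a 3-d array")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be in (0, 1)")
  if (nrow(object@anno) != dim(object@strength)[3L])
    return("annotation rows must match the interaction dimension")
  if (any(object@strength < 0)) return("negative strengths")
  if (any(object@pval < 0 | object@pval > 1)) return("p-values outside [0, 1]")
  if (any(object@strength == 0 & object@pval < 1))
    return("zero strengths must carry p = 1")
  TRUE
})

#' @describeIn CommunicationTensor strength array accessor
#' @param object,x a `CommunicationTensor`
#' @export
setGeneric("strengths", function(object) standardGeneric("strengths"))
#' @rdname CommunicationTensor-class
#' @export
setMethod("strengths", "CommunicationTensor", function(object) object@strength)

#' @describeIn CommunicationTensor permutation p-value array accessor
#' @export
setGeneric("pvalues", function(object) standardGeneric("pvalues"))
#' @rdname CommunicationTensor-class
#' @export
setMethod("pvalues", "CommunicationTensor", function(object) object@pval)

#' @describeIn CommunicationTensor logical mask of significant triples
#' @export
setGeneric("significantMask", function(object) standardGeneric("significantMask"))
#' @rdname CommunicationTensor-class
#' @export
setMethod("significantMask", "CommunicationTensor",
          function(object) object@pval < object@alpha)

setMethod("show", "CommunicationTensor", function(object) {
  d <- dim(object@strength)
  sig <- sum(significantMask(object))
  cat("CommunicationTensor:", d[1L], "senders x", d[2L], "receivers x",
      d[3L], "interactions\n")
  cat("  significant triples (p <", object@alpha, "):", sig, "\n")
  cat("  total significant strength:",
      signif(sum(object@strength[significantMask(object)]), 4L), "\n")
})

# ---------------------------------------------------------------------------
# PathwayScores
# ---------------------------------------------------------------------------

#' Pathway-level communication scores
#'
#' Per (sender, receiver, pathway) sums of significant interaction strengths.
#'
#' @slot score 3-d array sender x receiver x pathway.
#' @slot detected named logical: pathway has any non-zero score.
#' @export
setClass("PathwayScores",
         representation(score = "array", detected = "logical"))

setValidity("PathwayScores", function(object) {
  if (length(dim(object@score)) != 3L) return("score must be a 3-d array")
  if (length(object@detected) != dim(object@score)[3L])
    return("detected flag length must match pathway dimension")
  if (any(object@score < 0)) return("negative pathway scores")
  TRUE
})

#' @describeIn PathwayScores score array accessor
#' @param object a `PathwayScores`
#' @export
setGeneric("pathwayScores", function(object) standardGeneric("pathwayScores"))
#' @rdname PathwayScores-class
#' @export
setMethod("pathwayScores", "PathwayScores", function(object) object@score)

setMethod("show", "PathwayScores", function(object) {
  d <- dim(object@score)
  cat("PathwayScores:", d[1L], "senders x", d[2L], "receivers x",
      d[3L], "pathways (", sum(object@detected), "detected )\n")
})

# ---------------------------------------------------------------------------
# SampleLevelScores
# ---------------------------------------------------------------------------

#' Per-sample pseudo-bulk communication scores
#'
#' Sample-indexed pathway and ligand-receptor score matrices from running the
#' inference independently within each sample, the unit of between-group
#' pseudo-bulk testing.
#'
#' @slot pathway_scores samples x pathways matrix of total significant
#'   strength per pathway.
#' @slot lr_scores samples x units matrix, units being
#'   `sender|receiver|interaction` triples.
#' @slot detected logical samples x pathways (score > 0).
#' @slot condition named per-sample condition labels.
#' @slot lr_anno data.frame mapping lr unit columns to sender, receiver,
#'   interaction and pathway.
#' @slot flagged character: samples with fewer than two populated cell types.
#' @export
setClass("SampleLevelScores",
         representation(pathway_scores = "matrix", lr_scores = "matrix",
                        detected = "matrix", condition = "character",
                        lr_anno = "data.frame", flagged = "character"))

setValidity("SampleLevelScores", function(object) {
  if (!identical(dim(object@pathway_scores), dim(object@detected)))
    return("pathway_scores and detected dimensions differ")
  if (length(object@condition) != nrow(object@pathway_scores))
    return("one condition label per sample row required")
  if (!identical(object@detected, object@pathway_scores > 0))
    return("detected must equal pathway_scores > 0")
  if (nrow(object@lr_anno) != ncol(object@lr_scores))
    return("lr annotation must match lr_scores columns")
  TRUE
})

setMethod("show", "SampleLevelScores", function(object) {
  cat("SampleLevelScores:", nrow(object@pathway_scores), "samples x",
      ncol(object@pathway_scores), "pathways;",
      ncol(object@lr_scores), "L-R units\n")
  cat("  conditions:", paste(names(table(object@condition)),
                             table(object@condition), collapse = ", "), "\n")
  if (length(object@flagged))
    cat("  flagged samples:", paste(object@flagged, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# CommunicationPatterns
# ---------------------------------------------------------------------------

#' Latent communication patterns (NMF)
#'
#' Non-negative factorization of a cell-type x pathway signaling matrix into
#' `k` latent patterns linking groups of cell types to groups of pathways.
#'
#' @slot direction `"outgoing"` or `"incoming"`.
#' @slot k number of patterns.
#' @slot cell_loadings cell_type x k matrix, rows sum to one.
#' @slot pathway_loadings k x pathway non-negative matrix.
#' @slot diagnostics data.frame of per-candidate-k consensus diagnostics
#'   (cophenetic coefficient, mean silhouette), possibly empty.
#' @slot converged logical: multiplicative updates converged.
#' @export
setClass("CommunicationPatterns",
         representation(direction = "character", k = "integer",
                        cell_loadings = "matrix", pathway_loadings = "matrix",
                        diagnostics = "data.frame", converged = "logical"))

setValidity("CommunicationPatterns", function(object) {
  if (!object@direction %in% c("outgoing", "incoming"))
    return("direction must be 'outgoing' or 'incoming'")
  if (object@k < 2L) return("k must be at least 2")
  if (any(object@cell_loadings < 0) || any(object@pathway_loadings < 0))
    return("loadings must be non-negative")
  rs <- rowSums(object@cell_loadings)
  if (any(abs(rs - 1) > 1e-9))
    return("cell loading rows must sum to 1")
  TRUE
})

setMethod("show", "CommunicationPatterns", function(object) {
  cat("CommunicationPatterns (", object@direction, "): k =", object@k, "\n")
  top <- apply(object@cell_loadings, 2L, function(z)
    rownames(object@cell_loadings)[which.max(z)])
  cat("  top cell type per pattern:", paste(top, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SpatialDataset
# ---------------------------------------------------------------------------

#' Spatial expression dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a non-negative
#' genes x spots `"logcounts"` assay and a per-spot `layer` label (cortical
#' layer or white matter; the literal label `"NA"` is allowed).
#'
#' @export
setClass("SpatialDataset", contains = "SummarizedExperiment")

setValidity("SpatialDataset", function(object) {
  if (!"layer" %in% names(colData(object)))
    return("colData must contain a 'layer' column")
  if (anyNA(colData(object)$layer))
    return("layer labels must not be missing (use the string 'NA')")
  a <- assay(object)
  mn <- if (methods::is(a, "sparseMatrix")) min(a@x, 0) else suppressWarnings(min(a))
  if (ncol(object) > 0L && nrow(object) > 0L && mn < 0)
    return("expression values must be non-negative")
  TRUE
})

#' Construct a SpatialDataset
#'
#' @param mat genes x spots non-negative expression matrix.
#' @param layer per-spot layer labels.
#' @return a validated [SpatialDataset-class].
#' @export
SpatialDataset <- function(mat, layer) {
  se <- SummarizedExperiment(assays = list(logcounts = mat),
                             colData = DataFrame(layer = as.character(layer),
                                                 row.names = colnames(mat)))
  methods::new("SpatialDataset", se)
}

#' @describeIn SpatialDataset per-spot layer labels
#' @param x a `SpatialDataset`
#' @export
spotLayer <- function(x) as.character(colData(x)$layer)
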