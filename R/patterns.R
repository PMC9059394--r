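#' @importFrom stats hclust cophenetic as.dist cutree runif
#' @importFrom cluster silhouette
NULL

#' Build the cell-type x pathway signaling matrix
#'
#' Outgoing signaling sums pathway scores over receivers, incoming over
#' senders. Each detected pathway column is divided by its maximum
#' (column maxima become 1); undetected pathways are dropped.
#'
#' @param ps a [PathwayScores-class].
#' @param direction `"outgoing"` or `"incoming"`.
#' @return cell_type x pathway matrix.
#' @export
buildSignalingMatrix <- function(ps, direction = c("outgoing", "incoming")) {
  direction <- match.arg(direction)
  m <- celltypeContributions(ps, direction)
  m <- m[, ps@detected, drop = FALSE]
  if (ncol(m) == 0L) stop("no detected pathway")
  sweep(m, 2L, apply(m, 2L, max), "/")
}

# multiplicative-update NMF (Frobenius objective); returns W, H and the
# error trace (non-increasing up to machine precision)
.nmf <- function(M, k, maxIter = 200L, tol = 1e-6) {
  nr <- nrow(M); nc <- ncol(M)
  scale <- sqrt(mean(M) / k)
  W <- matrix(runif(nr * k), nr, k) * scale + 1e-9
  H <- matrix(runif(k * nc), k, nc) * scale + 1e-9
  eps <- .Machine$double.eps
  errs <- numeric(0)
  prev <- Inf
  conv <- FALSE
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, M) / (crossprod(W, W %*% H) + eps))
    W <- W * (M %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    e <- sqrt(sum((M - W %*% H)^2))
    errs <- c(errs, e)
    if (is.finite(prev) && prev - e < tol * max(prev, 1)) { conv <- TRUE; break }
    prev <- e
  }
  list(W = W, H = H, errors = errs, converged = conv)
}

#' Select the number of communication patterns
#'
#' For each candidate k, repeated seeded NMF runs build a consensus
#' co-clustering matrix of the cell types (rows assigned to their dominant
#' pattern). The cophenetic correlation of the consensus distance with its
#' average-linkage dendrogram and the mean silhouette width of the consensus
#' partition are recorded. The chosen k is the largest candidate with both
#' metrics at >= 95% of their value at the smallest k, falling back to the
#' k maximizing the cophenetic coefficient; both metrics are always
#' returned so the choice can be overridden.
#'
#' @param M cell_type x pathway matrix from [buildSignalingMatrix()].
#' @param kRange candidate pattern counts (default `2:10`, truncated to the
#'   matrix dimensions).
#' @param runsPerK NMF runs per candidate (default 30).
#' @param seed optional integer seed.
#' @return list with `k` and `diagnostics` (data.frame: k, cophenetic,
#'   silhouette).
#' @export
selectK <- function(M, kRange = 2:10, runsPerK = 30L, seed = NULL) {
  if (sd(as.vector(M)) == 0) stop("degenerate constant matrix")
  if (!is.null(seed)) set.seed(seed)
  kRange <- kRange[kRange >= 2L & kRange < nrow(M) & kRange <= ncol(M)]
  if (!length(kRange)) stop("no feasible k in range for this matrix")
  diag_rows <- lapply(kRange, function(k) {
    C <- matrix(0, nrow(M), nrow(M))
    for (r in seq_len(runsPerK)) {
      fit <- .nmf(M, k)
      assign <- apply(fit$W, 1L, which.max)
      C <- C + outer(assign, assign, "==")
    }
    C <- C / runsPerK
    d <- as.dist(1 - C)
    hc <- hclust(d, method = "average")
    coph <- if (sd(d) == 0) 1 else suppressWarnings(cor(d, cophenetic(hc)))
    if (is.na(coph)) coph <- 1
    cl <- cutree(hc, k)
    sil <- if (length(unique(cl)) > 1L)
      mean(silhouette(cl, dmatrix = as.matrix(d))[, 3L]) else 0
    data.frame(k = k, cophenetic = coph, silhouette = sil)
  })
  diagnostics <- do.call(rbind, diag_rows)
  ref <- diagnostics[1L, ]
  ok <- diagnostics$cophenetic >= 0.95 * ref$cophenetic &
    diagnostics$silhouette >= 0.95 * ref$silhouette
  k <- if (any(ok)) max(diagnostics$k[ok])
       else diagnostics$k[which.max(diagnostics$cophenetic)]
  list(k = k, diagnostics = diagnostics)
}

#' Detect latent communication patterns
#'
#' Single seeded NMF fit `M ~ W H` by multiplicative updates with uniform
#' non-negative initialization; W rows are normalized to sum 1 so each cell
#' type's loadings distribute over patterns.
#'
#' @param M cell_type x pathway matrix from [buildSignalingMatrix()].
#' @param k number of patterns (from [selectK()] or user-set).
#' @param direction direction label carried into the result.
#' @param seed optional integer seed.
#' @param maxIter maximum multiplicative updates (default 200); if not
#'   converged the result is returned with `converged = FALSE` and a
#'   warning.
#' @param diagnostics optional data.frame from [selectK()].
#' @return a [CommunicationPatterns-class].
#' @export
detectPatterns <- function(M, k, direction = c("outgoing", "incoming"),
                           seed = NULL, maxIter = 200L,
                           diagnostics = data.frame()) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  fit <- .nmf(M, k, maxIter = maxIter)
  if (!fit$converged)
    warning("NMF did not converge within ", maxIter, " iterations")
  W <- fit$W
  rs <- rowSums(W)
  zero <- rs == 0
  if (any(zero)) W[zero, ] <- 1 / k
  W <- W / rowSums(W)
  dimnames(W) <- list(rownames(M), paste0("pattern", seq_len(k)))
  H <- fit$H
  dimnames(H) <- list(paste0("pattern", seq_len(k)), colnames(M))
  methods::new("CommunicationPatterns", direction = direction,
               k = as.integer(k), cell_loadings = W, pathway_loadings = H,
               diagnostics = diagnostics, converged = fit$converged)
}

#' Write pattern tables
#'
#' Writes `patterns_<direction>.tsv` (cell loadings),
#' `pattern_pathways_<direction>.tsv` (pathway loadings) and, when
#' diagnostics are present, `pattern_diagnostics.tsv`.
#'
#' @param patterns a [CommunicationPatterns-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePatterns <- function(patterns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- patterns@direction
  w <- data.frame(cell_type = rownames(patterns@cell_loadings),
                  patterns@cell_loadings, check.names = FALSE)
  write.table(w, file.path(dir, paste0("patterns_", d, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  h <- data.frame(pattern = rownames(patterns@pathway_loadings),
                  patterns@pathway_loadings, check.names = FALSE)
  write.table(h, file.path(dir, paste0("pattern_pathways_", d, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(patterns@diagnostics))
    write.table(patterns@diagnostics,
                file.path(dir, "pattern_diagnostics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
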