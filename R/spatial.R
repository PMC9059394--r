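#' @importFrom stats ks.test
NULL

.spatial_scope <- function(sp, layer) {
  if (identical(layer, "all")) return(seq_len(ncol(sp)))
  idx <- which(spotLayer(sp) == layer)
  if (length(idx) < 10L) {
    warning("layer ", layer, " has fewer than 10 spots; skipped")
    return(integer(0))
  }
  idx
}

#' Spatial correlation of ligand-receptor pairs
#'
#' Pearson correlation of each ligand-receptor gene pair across spots, using
#' all spots or only those of one layer. Complexes (subunits joined by
#' `"_"`) are expanded into every ligand-subunit x receptor-subunit gene
#' pair and flagged `expanded`. Pairs with a missing or spot-constant gene
#' are emitted with a missing correlation and a flag.
#'
#' @param sp a [SpatialDataset-class].
#' @param pairs data.frame with `ligand` and `receptor` columns (gene
#'   symbols or `"_"`-joined complexes).
#' @param layer `"all"` or a layer label (layers with < 10 spots are skipped
#'   with a warning).
#' @return data.frame with `ligand`, `receptor`, `pair`, `r`, `n_spots`,
#'   `flag`.
#' @export
lrSpatialCorrelation <- function(sp, pairs, layer = "all") {
  idx <- .spatial_scope(sp, layer)
  empty <- data.frame(ligand = character(0), receptor = character(0),
                      pair = character(0), r = numeric(0),
                      n_spots = integer(0), flag = character(0),
                      stringsAsFactors = FALSE)
  if (length(idx) < 3L) {
    if (length(idx)) warning("fewer than 3 spots in scope")
    return(empty)
  }
  X <- as.matrix(assay(sp))[, idx, drop = FALSE]
  rn <- toupper(rownames(X))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ls <- toupper(strsplit(as.character(pairs$ligand[i]), "_")[[1L]])
    rs <- toupper(strsplit(as.character(pairs$receptor[i]), "_")[[1L]])
    expanded <- length(ls) > 1L || length(rs) > 1L
    grid <- expand.grid(lg = ls, rg = rs, stringsAsFactors = FALSE)
    do.call(rbind, lapply(seq_len(nrow(grid)), function(j) {
      lg <- grid$lg[j]; rg <- grid$rg[j]
      flag <- if (expanded) "expanded" else ""
      if (!lg %in% rn || !rg %in% rn) {
        return(data.frame(ligand = lg, receptor = rg,
                          pair = paste(pairs$ligand[i], pairs$receptor[i],
                                       sep = "-"),
                          r = NA_real_, n_spots = ncol(X),
                          flag = paste0(flag, ifelse(nzchar(flag), ";", ""),
                                        "missing_gene"),
                          stringsAsFactors = FALSE))
      }
      x <- X[match(lg, rn), ]; y <- X[match(rg, rn), ]
      if (sd(x) == 0 || sd(y) == 0) {
        r <- NA_real_
        flag <- paste0(flag, ifelse(nzchar(flag), ";", ""), "constant")
      } else r <- cor(x, y)
      data.frame(ligand = lg, receptor = rg,
                 pair = paste(pairs$ligand[i], pairs$receptor[i], sep = "-"),
                 r = r, n_spots = ncol(X), flag = flag,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Random-pair null for spatial co-expression
#'
#' Pearson correlations of uniformly drawn gene pairs (true L-R pairs
#' excluded), the null the observed L-R correlations are compared against.
#' When the pool of admissible pairs is smaller than `nPairs`, pairs are
#' drawn with replacement with a message.
#'
#' @param sp a [SpatialDataset-class].
#' @param nPairs number of random pairs (>= 100).
#' @param seed optional integer seed.
#' @param exclude optional data.frame of true pairs (`ligand`, `receptor`)
#'   excluded (in either orientation).
#' @param trueR optional vector of observed true-pair correlations; when
#'   given, a two-sample Kolmogorov-Smirnov comparison against the null is
#'   reported.
#' @param layer `"all"` or a layer label.
#' @return list with `null_r` and, when `trueR` is supplied, `ks_stat` and
#'   `ks_p`.
#' @export
randomPairNull <- function(sp, nPairs = 1000L, seed = NULL, exclude = NULL,
                           trueR = NULL, layer = "all") {
  if (nPairs < 100L) stop("nPairs must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  idx <- .spatial_scope(sp, layer)
  if (length(idx) < 3L) stop("fewer than 3 spots in scope")
  X <- as.matrix(assay(sp))[, idx, drop = FALSE]
  rn <- toupper(rownames(X))
  banned <- character(0)
  if (!is.null(exclude))
    banned <- c(paste(toupper(exclude$ligand), toupper(exclude$receptor)),
                paste(toupper(exclude$receptor), toupper(exclude$ligand)))
  G <- length(rn)
  if (G * (G - 1) < nPairs)
    message("fewer available gene pairs than requested; ",
            "sampling with replacement")
  null_r <- numeric(0)
  guard <- 0L
  while (length(null_r) < nPairs && guard < 50L) {
    need <- nPairs - length(null_r)
    i <- sample.int(G, need, replace = TRUE)
    j <- sample.int(G, need, replace = TRUE)
    ok <- i != j & !(paste(rn[i], rn[j]) %in% banned)
    i <- i[ok]; j <- j[ok]
    if (length(i)) {
      r <- vapply(seq_along(i), function(q) {
        x <- X[i[q], ]; y <- X[j[q], ]
        if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
      }, 1)
      null_r <- c(null_r, r[!is.na(r)])
    }
    guard <- guard + 1L
  }
  null_r <- null_r[seq_len(min(nPairs, length(null_r)))]
  out <- list(null_r = null_r)
  if (!is.null(trueR)) {
    trueR <- trueR[!is.na(trueR)]
    ks <- suppressWarnings(ks.test(trueR, null_r))
    out$ks_stat <- unname(ks$statistic)
    out$ks_p <- ks$p.value
  }
  out
}
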