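#' @importFrom stats phyper fisher.test
NULL

#' Gene set collection
#'
#' Named gene sets plus the gene universe they are tested against. Set genes
#' need not all lie in the universe; they are intersected at test time.
#'
#' @slot sets named list of character vectors (non-empty).
#' @slot universe character vector of gene symbols.
#' @export
setClass("GeneSetCollection2",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection2", function(object) {
  if (!length(object@sets)) return("at least one gene set required")
  if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
    return("gene sets must be named")
  if (any(lengths(object@sets) == 0L)) return("empty gene set")
  TRUE
})

setMethod("show", "GeneSetCollection2", function(object) {
  cat("GeneSetCollection2:", length(object@sets), "sets, universe of",
      length(object@universe), "genes\n")
})

#' Build a gene set collection
#'
#' @param sets named list of gene symbol vectors.
#' @param universe gene universe (by default, e.g., the genes present in the
#'   expression matrix).
#' @return a [GeneSetCollection2-class].
#' @export
geneSetCollection <- function(sets, universe) {
  methods::new("GeneSetCollection2",
               sets = lapply(sets, function(z) unique(toupper(z))),
               universe = unique(toupper(universe)))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @param universe gene universe for the collection.
#' @return a [GeneSetCollection2-class].
#' @export
readGMT <- function(path, universe) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  sets <- lapply(lines, function(z) z[-(1:2)])
  names(sets) <- vapply(lines, `[`, "", 1L)
  geneSetCollection(sets, universe)
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file with one gene symbol per line.
#' @return character vector.
#' @export
readGeneList <- function(path) {
  z <- trimws(readLines(path))
  unique(toupper(z[nzchar(z)]))
}

#' Overrepresentation analysis
#'
#' Hypergeometric upper-tail test of a query gene list against each set:
#' `p = P(X >= k)` with universe size N, set size K (after intersection with
#' the universe) and query size n; BH-adjusted across sets.
#'
#' @param query gene list (intersected with the universe; must leave at
#'   least one gene).
#' @param gsc a [GeneSetCollection2-class].
#' @param fdrCut FDR threshold for the `significant` flag (default 0.05).
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `fdr`,
#'   `significant`.
#' @export
ora <- function(query, gsc, fdrCut = 0.05) {
  uni <- gsc@universe
  if (!length(uni)) stop("empty universe")
  query <- unique(toupper(query))
  dropped <- setdiff(query, uni)
  if (length(dropped))
    message(length(dropped), " query gene(s) outside the universe dropped")
  query <- intersect(query, uni)
  if (!length(query)) stop("no query genes left after universe intersection")
  N <- length(uni); n <- length(query)
  res <- lapply(names(gsc@sets), function(s) {
    set <- intersect(gsc@sets[[s]], uni)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdrCut
  out
}

#' Fisher exact test of overlap between two gene lists
#'
#' Builds the 2x2 table `[[a, b], [c, d]]` with `a` the overlap, `b` and `c`
#' the list-specific genes and `d` the remaining universe, and reports the
#' sample odds ratio `(a d)/(b c)` (with Haldane 0.5 correction when any
#' cell is zero) and the two-sided Fisher exact p-value.
#'
#' @param listA,listB gene lists (intersected with the universe).
#' @param universe gene universe.
#' @return one-row data.frame with `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `flag` (`""`, `"empty_list"` or `"degenerate"`).
#' @export
overlapTest <- function(listA, listB, universe) {
  universe <- unique(toupper(universe))
  A <- intersect(unique(toupper(listA)), universe)
  B <- intersect(unique(toupper(listB)), universe)
  if (length(universe) < length(union(A, B)))
    stop("universe smaller than the union of the lists")
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  cc <- length(setdiff(B, A))
  d <- length(universe) - a - b - cc
  if (!length(A) || !length(B))
    return(data.frame(a = a, b = b, c = cc, d = d, odds_ratio = NA_real_,
                      p = 1, flag = "empty_list", stringsAsFactors = FALSE))
  flag <- if (d == 0L && b == 0L && cc == 0L) "degenerate" else ""
  or <- if (any(c(a, b, cc, d) == 0L))
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * d) / (b * cc)
  p <- fisher.test(matrix(c(a, b, cc, d), 2L, byrow = TRUE))$p.value
  data.frame(a = a, b = b, c = cc, d = d, odds_ratio = or, p = p,
             flag = flag, stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
.gsea_es <- function(scores, hit, weight) {
  N <- length(scores)
  nh <- sum(hit)
  w <- abs(scores)^weight
  sw <- sum(w[hit])
  if (sw == 0 || nh == 0L || nh == N) return(NA_real_)
  inc <- ifelse(hit, w / sw, -1 / (N - nh))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a preranked gene list
#' (e.g. genes ranked by expression fold change between conditions), with a
#' gene-label permutation null: set positions are redrawn uniformly `nPerm`
#' times. NES divides ES by the mean magnitude of same-sign null ES values;
#' FDR uses the standard positive/negative pooled-null procedure.
#'
#' @param ranking named numeric vector of per-gene scores (unique names).
#' @param gsc a [GeneSetCollection2-class] (universe ignored; the ranking is
#'   the universe).
#' @param weight running-sum weight (default 1).
#' @param nPerm permutations (default 1000).
#' @param seed optional integer seed.
#' @param fdrCut FDR threshold for the `significant` flag (default 0.25).
#' @param minSize minimum overlap of a set with the ranking (default 5;
#'   set to 1 for tiny examples). Sets with no genes in the ranking are
#'   skipped with a message.
#' @return data.frame with `set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `significant`.
#' @export
prerankedGSEA <- function(ranking, gsc, weight = 1, nPerm = 1000L,
                          seed = NULL, fdrCut = 0.25, minSize = 5L) {
  if (anyDuplicated(names(ranking))) stop("ranking genes must be unique")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(ranking, decreasing = TRUE)
  scores <- as.numeric(ranking)[ord]
  genes <- toupper(names(ranking))[ord]
  N <- length(genes)
  keep <- character(0)
  sizes <- integer(0)
  for (s in names(gsc@sets)) {
    sz <- sum(genes %in% gsc@sets[[s]])
    if (sz == 0L) { message("set ", s, " has no genes in the ranking; skipped") }
    else if (sz >= minSize && sz < N) { keep <- c(keep, s); sizes <- c(sizes, sz) }
  }
  if (!length(keep)) stop("no testable gene set")
  es <- vapply(keep, function(s)
    .gsea_es(scores, genes %in% gsc@sets[[s]], weight), 1)
  nullES <- lapply(seq_along(keep), function(i) {
    vapply(seq_len(nPerm), function(b) {
      hit <- logical(N)
      hit[sample.int(N, sizes[i])] <- TRUE
      .gsea_es(scores, hit, weight)
    }, 1)
  })
  norm1 <- function(e, nul) {
    m <- mean(abs(nul[sign(nul) == sign(e)]))
    if (!is.finite(m) || m == 0) return(NA_real_)
    e / m
  }
  nes <- vapply(seq_along(keep), function(i) norm1(es[i], nullES[[i]]), 1)
  pv <- vapply(seq_along(keep), function(i) {
    nul <- nullES[[i]]
    same <- nul[sign(nul) == sign(es[i])]
    (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }, 1)
  nullNES <- unlist(lapply(seq_along(keep), function(i)
    vapply(nullES[[i]], norm1, 1, nul = nullES[[i]])))
  nullNES <- nullNES[is.finite(nullNES)]
  fdr <- vapply(seq_along(keep), function(i) {
    z <- nes[i]
    if (!is.finite(z)) return(NA_real_)
    if (z >= 0) {
      num <- mean(nullNES[nullNES >= 0] >= z)
      den <- mean(nes[is.finite(nes) & nes >= 0] >= z)
    } else {
      num <- mean(nullNES[nullNES < 0] <= z)
      den <- mean(nes[is.finite(nes) & nes < 0] <= z)
    }
    if (!is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, 1)
  data.frame(set = keep, size = sizes, es = unname(es), nes = nes, p = pv,
             fdr = fdr, significant = !is.na(fdr) & fdr < fdrCut,
             stringsAsFactors = FALSE)
}
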