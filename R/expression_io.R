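#' @importFrom Matrix readMM writeMM colSums
NULL

#' Load an annotated expression dataset
#'
#' Reads a genes x cells matrix either from Matrix-Market sparse triplet form
#' (`matrixPath` ending in `.mtx`, accompanied by a one-symbol-per-line
#' `genesPath`) or from a dense TSV with gene rownames and cell-id column
#' names, together with a cell metadata TSV keyed by cell id with `cell_type`,
#' `sample` and `condition` columns (optional `region`).
#'
#' Values are assumed to be already library-normalized and log-transformed;
#' no normalization is performed, but a warning is emitted when per-cell
#' column sums vary by more than 100x (a heuristic for raw counts).
#'
#' @param matrixPath matrix file (`.mtx` or dense TSV).
#' @param metadataPath cell metadata TSV; the first column (or a `cell`
#'   column) holds cell ids matching the matrix columns.
#' @param genesPath gene symbols file, required for MTX input.
#' @return a validated [CCCExperiment-class]; per-cell-type counts are
#'   reported via `message()`.
#' @export
loadDataset <- function(matrixPath, metadataPath, genesPath = NULL) {
  if (grepl("\\.mtx$", matrixPath)) {
    if (is.null(genesPath))
      stop("MTX input requires 'genesPath' with one gene symbol per line")
    mat <- as(readMM(matrixPath), "CsparseMatrix")
    genes <- readLines(genesPath)
    if (length(genes) != nrow(mat))
      stop("gene list length (", length(genes),
           ") does not match matrix rows (", nrow(mat), ")")
    rownames(mat) <- genes
  } else {
    df <- read.delim(matrixPath, row.names = 1L, check.names = FALSE)
    mat <- as.matrix(df)
  }
  meta <- read.delim(metadataPath, stringsAsFactors = FALSE,
                     check.names = FALSE)
  idcol <- if ("cell" %in% names(meta)) "cell" else names(meta)[1L]
  cells <- as.character(meta[[idcol]])
  if (is.null(colnames(mat))) {
    if (ncol(mat) != length(cells))
      stop("matrix has ", ncol(mat), " cells but metadata ", length(cells))
    colnames(mat) <- cells
  }
  missing <- setdiff(colnames(mat), cells)
  if (length(missing))
    stop("cell(s) present in matrix but absent from metadata: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  meta <- meta[match(colnames(mat), cells), , drop = FALSE]
  need <- c("cell_type", "sample", "condition")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (min(mat) < 0) stop("negative expression values")
  cs <- Matrix::colSums(mat)
  if (any(cs > 0) && max(cs) / max(min(cs[cs > 0]), .Machine$double.eps) > 100)
    warning("per-cell totals vary by more than 100x; ",
            "input may be raw counts rather than normalized expression")
  ds <- CCCExperiment(mat, cellType = meta$cell_type, sample = meta$sample,
                      condition = meta$condition, region = meta$region)
  tab <- table(cellType(ds))
  message("loaded ", ncol(ds), " cells, ", nrow(ds), " genes; cells per type: ",
          paste(names(tab), tab, sep = "=", collapse = ", "))
  ds
}

#' Write a dataset in the pipeline's input formats
#'
#' @param ds a [CCCExperiment-class].
#' @param dir output directory (created if needed).
#' @param format `"mtx"` (matrix.mtx + genes.tsv + metadata.tsv) or `"tsv"`
#'   (matrix.tsv + metadata.tsv).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(ds, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(cell = colnames(ds), cell_type = cellType(ds),
                     sample = sampleId(ds), condition = condition(ds),
                     stringsAsFactors = FALSE)
  if ("region" %in% names(colData(ds)))
    meta$region <- as.character(colData(ds)$region)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  a <- assay(ds, "logcounts")
  if (format == "mtx") {
    writeMM(as(as(a, "CsparseMatrix"), "generalMatrix"),
            file.path(dir, "matrix.mtx"))
    writeLines(rownames(ds), file.path(dir, "genes.tsv"))
  } else {
    out <- data.frame(gene = rownames(ds), as.matrix(a),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(out, file.path(dir, "matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Check balance of per-sample cell counts between conditions
#'
#' For each cell type, a two-sided Wilcoxon rank-sum test compares the
#' per-sample cell counts between the two conditions (samples without cells
#' of the type count as zero). The report is advisory: a high p-value
#' supports treating cell-number composition as comparable across groups.
#'
#' @param ds a [CCCExperiment-class] with two conditions.
#' @return data.frame with `cell_type`, `p` and a `note` column flagging
#'   `"underpowered"` cell types when a condition has fewer than two samples.
#' @export
checkGroupBalance <- function(ds) {
  cond <- condition(ds)
  lev <- unique(cond)
  if (length(lev) != 2L)
    stop("exactly two conditions required, found: ",
         paste(lev, collapse = ", "))
  samp <- sampleId(ds)
  samples <- unique(samp)
  scond <- vapply(samples, function(s) cond[match(s, samp)], "")
  underpowered <- any(table(scond) < 2L)
  types <- sort(unique(cellType(ds)))
  res <- lapply(types, function(tp) {
    cnt <- vapply(samples, function(s)
      sum(samp == s & cellType(ds) == tp), 1L)
    a <- cnt[scond == lev[1L]]
    b <- cnt[scond == lev[2L]]
    p <- if (!length(a) || !length(b)) NA_real_
    else if (stats::sd(c(a, b)) == 0) 1
    else suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
    data.frame(cell_type = tp, p = p,
               note = if (underpowered) "underpowered" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
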