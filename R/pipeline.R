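#' @importFrom jsonlite write_json
NULL

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tensor_table <- function(tensor) {
  d <- dim(tensor@strength)
  dn <- dimnames(tensor@strength)
  grid <- expand.grid(sender = dn[[1L]], receiver = dn[[2L]],
                      interaction = dn[[3L]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  i <- match(grid$interaction, tensor@anno$id)
  data.frame(grid[, c("sender", "receiver", "interaction")],
             ligand = tensor@anno$ligand[i],
             receptor = tensor@anno$receptor[i],
             pathway = tensor@anno$pathway[i],
             strength = as.vector(tensor@strength),
             pval = as.vector(tensor@pval),
             significant = as.vector(significantMask(tensor)),
             stringsAsFactors = FALSE)
}

.pathway_table <- function(ps) {
  dn <- dimnames(ps@score)
  grid <- expand.grid(sender = dn[[1L]], receiver = dn[[2L]],
                      pathway = dn[[3L]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  data.frame(grid, score = as.vector(ps@score),
             detected = ps@detected[grid$pathway],
             stringsAsFactors = FALSE)
}

#' Run the full two-group comparison pipeline
#'
#' Executes either the merged "global" design or the per-sample pseudo-bulk
#' design and writes deterministic TSV result tables plus a JSON run
#' manifest into `outDir`.
#'
#' Global mode writes `interactions.tsv` (both conditions),
#' `pathway_scores.tsv`, `information_flow.tsv` and
#' `differential_pathways.tsv`. Per-sample mode writes
#' `sample_pathway_scores.tsv`, `differential_pathways.tsv`,
#' `differential_lr.tsv` and `pca_samples.tsv`.
#'
#' @param ds a [CCCExperiment-class] with two conditions.
#' @param db an [LRDatabase-class].
#' @param params a [cccParams()] list.
#' @param mode `"global"` or `"per-sample"`.
#' @param outDir output directory (created); `NULL` skips writing.
#' @param seed integer seed recorded in the manifest.
#' @param minSamples pathway detection filter for per-sample mode.
#' @param groupMap optional named vector reassigning samples to groups
#'   (e.g. a balanced 4-vs-4 regrouping); names are sample ids, values the
#'   two group labels.
#' @param conditionA which condition plays "A".
#' @return invisibly, a list of the computed result objects.
#' @export
runPipeline <- function(ds, db, params = cccParams(),
                        mode = c("global", "per-sample"), outDir = NULL,
                        seed = 1L, minSamples = 5L, groupMap = NULL,
                        conditionA = NULL) {
  mode <- match.arg(mode)
  if (!is.null(groupMap)) {
    cd <- colData(ds)
    cd$condition <- unname(groupMap[as.character(cd$sample)])
    ds <- ds[, !is.na(cd$condition)]
    colData(ds)$condition <-
      unname(groupMap[as.character(colData(ds)$sample)])
    methods::validObject(ds)
  }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE,
                                   recursive = TRUE)
  res <- list(mode = mode, seed = seed)
  if (mode == "global") {
    gc <- globalCompare(ds, db, params, seed = seed,
                        conditionA = conditionA)
    rf <- relativeFlow(gc$scoresA, gc$scoresB)
    res$global <- gc
    res$relative_flow <- rf
    if (!is.null(outDir)) {
      ta <- cbind(condition = gc$conditionA, .tensor_table(gc$tensorA))
      tb <- cbind(condition = gc$conditionB, .tensor_table(gc$tensorB))
      .write_tsv(rbind(ta, tb), file.path(outDir, "interactions.tsv"))
      pa <- cbind(condition = gc$conditionA, .pathway_table(gc$scoresA))
      pb <- cbind(condition = gc$conditionB, .pathway_table(gc$scoresB))
      .write_tsv(rbind(pa, pb), file.path(outDir, "pathway_scores.tsv"))
      .write_tsv(rf, file.path(outDir, "information_flow.tsv"))
      .write_tsv(gc$pathway, file.path(outDir, "differential_pathways.tsv"))
    }
  } else {
    sls <- perSampleScores(ds, db, params, seed = seed)
    sls <- filterPathways(sls, minSamples = minSamples)
    dp <- sampleWilcoxon(sls, what = "pathway", alpha = params$alpha,
                         conditionA = conditionA)
    dl <- sampleWilcoxon(sls, what = "lr", alpha = params$alpha,
                         conditionA = conditionA)
    dl <- cbind(sls@lr_anno[match(dl$unit, sls@lr_anno$unit),
                            c("sender", "receiver", "interaction",
                              "pathway")],
                dl)
    res$scores <- sls
    res$differential_pathways <- dp
    res$differential_lr <- dl
    if (ncol(sls@pathway_scores) >= 2L && nrow(sls@pathway_scores) >= 3L) {
      res$pca <- tryCatch(pcaSamples(sls), error = function(e) {
        message("PCA skipped: ", conditionMessage(e))
        NULL
      })
    }
    if (!is.null(outDir)) {
      sp <- data.frame(sample = rownames(sls@pathway_scores),
                       condition = unname(sls@condition),
                       sls@pathway_scores, check.names = FALSE)
      .write_tsv(sp, file.path(outDir, "sample_pathway_scores.tsv"))
      .write_tsv(dp, file.path(outDir, "differential_pathways.tsv"))
      .write_tsv(dl[dl$mean_A + dl$mean_B > 0, ],
                 file.path(outDir, "differential_lr.tsv"))
      if (!is.null(res$pca))
        .write_tsv(res$pca$coordinates_df,
                   file.path(outDir, "pca_samples.tsv"))
    }
  }
  if (!is.null(outDir)) {
    manifest <- list(mode = mode, seed = seed,
                     parameters = unclass(params),
                     n_cells = ncol(ds), n_genes = nrow(ds),
                     n_interactions = length(db),
                     package_version =
                       as.character(utils::packageVersion("cccdiff")),
                     r_version = R.version.string)
    write_json(manifest, file.path(outDir, "run_manifest.json"),
               auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}
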