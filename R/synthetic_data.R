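#' @importFrom stats rnbinom rlnorm rnorm median quantile
NULL

.default_cell_types <- c("ExN-L2/3", "ExN-L4", "ExN-L5/6", "ExN-L5/6-CC",
                         "IN-PV", "IN-SST", "IN-SV2C", "IN-VIP", "Neu-mat",
                         "Neu-NRGN-I", "Neu-NRGN-II", "AST-FB", "AST-PP",
                         "OPC", "Oligodendrocyte", "Microglia",
                         "Endothelial")

#' Simulation configuration
#'
#' Study-scale defaults: 17 cortical cell types, 13 case versus 10 control
#' samples, ~50 cells per type per sample, negative-binomial counts that are
#' library-normalized and log2(1+x)-transformed, and multiplicative
#' log-normal sample-level noise (SD 0.25) so pseudo-bulk tests are
#' non-trivial.
#'
#' @param nGenes total genes including background (>= database genes).
#' @param cellTypes cell-type labels (default 17 cortical types).
#' @param samplesPerCondition named counts, conditions are the names
#'   (default 13 `case`, 10 `control`).
#' @param cellsPerSampleType range the per-sample per-type cell count is
#'   drawn from (default 40-60).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of background
#'   per-gene NB means.
#' @param nbDispersion NB size parameter (default 4, moderate overdispersion
#'   as seen for reasonably expressed genes in UMI-based snRNA-seq).
#' @param plantedSignals data.frame with `pathway`, `sender`, `receiver`,
#'   `fold_change` (> 0), `condition`: the ligands of the pathway's
#'   interactions are scaled by `fold_change` in the sender type of that
#'   condition's samples.
#' @param sampleEffectSd SD of multiplicative log-normal sample x gene noise
#'   (default 0.25).
#' @param elevation fold elevation of a ligand (receptor) gene in its home
#'   sender (receiver) cell type over baseline (default 64, putting home
#'   types clearly above the 20% detection threshold).
#' @param dbGeneMean baseline NB mean of database genes outside their home
#'   type (default 0.05, clearly below the 20% detection threshold at these
#'   depths so off-home cell types do not flicker across the filter).
#' @param seed integer seed stored in the config.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nGenes = 300L, cellTypes = .default_cell_types,
                      samplesPerCondition = c(case = 13L, control = 10L),
                      cellsPerSampleType = c(40L, 60L),
                      baselineMeanlog = log(0.5), baselineSdlog = 1,
                      nbDispersion = 4, plantedSignals = NULL,
                      sampleEffectSd = 0.25, elevation = 64,
                      dbGeneMean = 0.05, seed = 1L) {
  if (length(samplesPerCondition) != 2L || is.null(names(samplesPerCondition)))
    stop("exactly two named conditions required")
  if (any(samplesPerCondition < 1L) || any(cellsPerSampleType < 1L))
    stop("all counts must be at least 1")
  if (!is.null(plantedSignals)) {
    need <- c("pathway", "sender", "receiver", "fold_change", "condition")
    if (!all(need %in% names(plantedSignals)))
      stop("plantedSignals needs columns: ", paste(need, collapse = ", "))
    if (any(plantedSignals$fold_change <= 0))
      stop("fold changes must be positive")
    if (!all(plantedSignals$sender %in% cellTypes) ||
        !all(plantedSignals$receiver %in% cellTypes))
      stop("planted sender/receiver must be among the cell types")
    if (!all(plantedSignals$condition %in% names(samplesPerCondition)))
      stop("planted condition must be one of the two conditions")
  }
  structure(list(nGenes = as.integer(nGenes), cellTypes = cellTypes,
                 samplesPerCondition = samplesPerCondition,
                 cellsPerSampleType = as.integer(cellsPerSampleType),
                 baselineMeanlog = baselineMeanlog,
                 baselineSdlog = baselineSdlog,
                 nbDispersion = nbDispersion,
                 plantedSignals = plantedSignals,
                 sampleEffectSd = sampleEffectSd,
                 elevation = elevation, dbGeneMean = dbGeneMean,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Generate a toy ligand-receptor database
#'
#' Pathway-partitioned interactions over a synthetic gene universe; each
#' interaction gets its own ligand and receptor genes, with optional
#' two-subunit receptor complexes and cofactor annotations drawn from a
#' shared cofactor pool.
#'
#' @param nPathways number of pathways (>= 1).
#' @param interactionsPerPathway interactions per pathway.
#' @param withComplexes make every second receptor a two-subunit complex.
#' @param withCofactors attach agonist/antagonist genes to every second
#'   interaction.
#' @param seed optional integer seed.
#' @return an [LRDatabase-class].
#' @export
generateToyDB <- function(nPathways = 3L, interactionsPerPathway = 2L,
                          withComplexes = TRUE, withCofactors = TRUE,
                          seed = NULL) {
  if (nPathways < 1L) stop("nPathways must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  nI <- nPathways * interactionsPerPathway
  rows <- lapply(seq_len(nI), function(i) {
    pw <- sprintf("PW%02d", (i - 1L) %/% interactionsPerPathway + 1L)
    lig <- sprintf("LG%03d", i)
    rec <- if (withComplexes && i %% 2L == 0L)
      sprintf(c("RCA%03d", "RCB%03d"), i) else sprintf("RCA%03d", i)
    ago <- if (withCofactors && i %% 2L == 1L)
      sprintf("AG%02d", (i %% 5L) + 1L) else character(0)
    ant <- if (withCofactors && i %% 4L == 0L)
      sprintf("AN%02d", (i %% 3L) + 1L) else character(0)
    data.frame(id = sprintf("%s_I%d", pw,
                            (i - 1L) %% interactionsPerPathway + 1L),
               ligand_name = lig,
               ligand_subunits = I(list(lig)),
               receptor_name = paste(rec, collapse = "_"),
               receptor_subunits = I(list(rec)),
               pathway = pw,
               agonists = I(list(ago)), antagonists = I(list(ant)),
               co_stimulatory = I(list(character(0))),
               co_inhibitory = I(list(character(0))),
               category = c("secreted", "ecm_receptor",
                            "cell_contact")[(i %% 3L) + 1L],
               stringsAsFactors = FALSE)
  })
  makeLRDatabase(do.call(rbind, rows))
}

#' Generate an annotated expression dataset with planted communication
#'
#' Draws negative-binomial counts per gene and cell, library-normalizes per
#' cell and log2(1+x)-transforms them, mirroring normalized single-nucleus
#' downloads. Each database interaction is assigned a home (sender,
#' receiver) cell-type pair (taken from `plantedSignals` for planted
#' pathways, seeded otherwise): its ligand genes are elevated in the home
#' sender and its receptor genes in the home receiver, in both conditions.
#' Planted ligands are additionally scaled by the planted fold change in the
#' designated condition's samples. Sample x gene multiplicative log-normal
#' effects add pseudo-bulk noise.
#'
#' @param cfg a [simConfig()] list (its `seed` drives all randomness; the
#'   same config yields a bit-identical dataset).
#' @param db an [LRDatabase-class] whose genes are embedded in the gene
#'   universe.
#' @return list with `dataset` (a [CCCExperiment-class]), `truth`
#'   (data.frame of planted differentials: pathway, sender, receiver,
#'   condition, fold_change; empty when nothing is planted) and `homes`
#'   (per-interaction home assignment).
#' @export
generateDataset <- function(cfg, db) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  dbg <- .db_genes(db)
  if (length(dbg) > cfg$nGenes)
    stop("config error: database needs ", length(dbg),
         " genes but nGenes = ", cfg$nGenes)
  nBg <- cfg$nGenes - length(dbg)
  genes <- c(dbg, sprintf("BG%04d", seq_len(nBg)))
  types <- cfg$cellTypes
  conds <- names(cfg$samplesPerCondition)
  planted <- cfg$plantedSignals
  if (!is.null(planted) &&
      !all(planted$pathway %in% db@interactions$pathway))
    stop("config error: planted pathway absent from the database")

  # home (sender, receiver) per interaction
  x <- db@interactions
  homes <- data.frame(id = x$id, pathway = x$pathway,
                      sender = sample(types, nrow(x), replace = TRUE),
                      receiver = sample(types, nrow(x), replace = TRUE),
                      stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      sel <- homes$pathway == planted$pathway[i]
      homes$sender[sel] <- planted$sender[i]
      homes$receiver[sel] <- planted$receiver[i]
    }
  }

  # per-gene NB mean by cell type
  mu <- matrix(rep(rlnorm(length(genes), cfg$baselineMeanlog,
                          cfg$baselineSdlog), length(types)),
               nrow = length(genes),
               dimnames = list(genes, types))
  mu[seq_along(dbg), ] <- cfg$dbGeneMean
  for (i in seq_len(nrow(x))) {
    lg <- x$ligand_subunits[[i]]
    rg <- x$receptor_subunits[[i]]
    mu[lg, homes$sender[i]] <- cfg$dbGeneMean * cfg$elevation
    mu[rg, homes$receiver[i]] <- cfg$dbGeneMean * cfg$elevation
  }
  cof <- setdiff(dbg, unlist(c(x$ligand_subunits, x$receptor_subunits)))
  mu[cof, ] <- cfg$dbGeneMean * cfg$elevation  # cofactors broadly present

  # planted condition-specific ligand scaling
  scaleFor <- function(cond) {
    s <- matrix(1, length(genes), length(types),
                dimnames = dimnames(mu))
    if (!is.null(planted)) {
      for (i in seq_len(nrow(planted))) {
        if (planted$condition[i] != cond) next
        sel <- which(x$pathway == planted$pathway[i])
        lg <- unique(unlist(x$ligand_subunits[sel]))
        s[lg, planted$sender[i]] <- planted$fold_change[i]
      }
    }
    s
  }

  sampleIds <- unlist(lapply(conds, function(cn)
    sprintf("%s_%02d", cn, seq_len(cfg$samplesPerCondition[[cn]]))))
  sampleCond <- rep(conds, cfg$samplesPerCondition)
  names(sampleCond) <- sampleIds

  mats <- list(); ctv <- list(); spv <- list()
  sdlog <- cfg$sampleEffectSd
  for (s in sampleIds) {
    cond <- sampleCond[[s]]
    sf <- rlnorm(length(genes), -sdlog^2 / 2, sdlog)  # sample x gene effect
    musc <- mu * scaleFor(cond) * sf
    ncell <- sample(seq(cfg$cellsPerSampleType[1L],
                        cfg$cellsPerSampleType[2L]),
                    length(types), replace = TRUE)
    cnt <- do.call(cbind, lapply(seq_along(types), function(t)
      matrix(rnbinom(length(genes) * ncell[t], mu = musc[, t],
                     size = cfg$nbDispersion),
             nrow = length(genes))))
    mats[[s]] <- cnt
    ctv[[s]] <- rep(types, ncell)
    spv[[s]] <- rep(s, sum(ncell))
  }
  counts <- do.call(cbind, mats)
  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%06d", seq_len(ncol(counts)))
  # library normalization to the median depth, then log2(1 + x)
  tot <- pmax(colSums(counts), 1)
  lognorm <- log2(1 + sweep(counts, 2L, median(tot) / tot, "*"))
  ds <- CCCExperiment(lognorm, cellType = unlist(ctv, use.names = FALSE),
                      sample = unlist(spv, use.names = FALSE),
                      condition = sampleCond)
  truth <- if (is.null(planted))
    data.frame(pathway = character(0), sender = character(0),
               receiver = character(0), condition = character(0),
               fold_change = numeric(0), stringsAsFactors = FALSE)
  else planted[, c("pathway", "sender", "receiver", "condition",
                   "fold_change")]
  list(dataset = ds, truth = truth, homes = homes)
}

#' Default planted-truth simulation
#'
#' The package's reference study-scale scenario: a 30-pathway toy database
#' (3 interactions each), 5 planted pathways with ligand fold change 2 in
#' the case group, 13 case vs 10 control samples, ~50 cells per type per
#' sample.
#'
#' @param seed integer seed.
#' @param nPathways,nPlanted,foldChange,cellTypes scenario knobs.
#' @param ... passed to [simConfig()].
#' @return list with `db`, `config`, `dataset`, `truth`, `homes`.
#' @export
defaultSimulation <- function(seed = 1L, nPathways = 30L, nPlanted = 5L,
                              foldChange = 2,
                              cellTypes = .default_cell_types, ...) {
  db <- generateToyDB(nPathways = nPathways, interactionsPerPathway = 3L,
                      seed = seed)
  set.seed(seed + 1L)
  pws <- sort(sample(unique(db@interactions$pathway), nPlanted))
  planted <- data.frame(pathway = pws,
                        sender = sample(cellTypes, nPlanted, replace = TRUE),
                        receiver = sample(cellTypes, nPlanted,
                                          replace = TRUE),
                        fold_change = foldChange, condition = "case",
                        stringsAsFactors = FALSE)
  cfg <- simConfig(nGenes = max(300L, length(.db_genes(db)) + 100L),
                   cellTypes = cellTypes, plantedSignals = planted,
                   seed = seed, ...)
  sim <- generateDataset(cfg, db)
  c(list(db = db, config = cfg), sim)
}

#' Generate a spatial dataset with planted L-R correlation
#'
#' Spots are assigned to layers; background genes are independent draws on
#' the log scale, planted ligand-receptor pairs come from a correlated
#' bivariate normal with the requested correlation (values truncated at 0).
#'
#' @param nGenes background gene count.
#' @param nSpots number of spots.
#' @param layers layer labels (default six layers plus white matter).
#' @param plantedPairs data.frame with `ligand`, `receptor`, `rho`
#'   (each rho in (-1, 1)); pair genes are appended to the gene universe.
#' @param meanExpr,sdExpr log-scale mean and SD.
#' @param seed optional integer seed.
#' @return list with `dataset` (a [SpatialDataset-class]) and `pairs`.
#' @export
generateSpatial <- function(nGenes = 200L, nSpots = 500L,
                            layers = c(paste0("L", 1:6), "WM"),
                            plantedPairs = NULL, meanExpr = 4, sdExpr = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(plantedPairs) &&
      any(abs(plantedPairs$rho) >= 1))
    stop("config error: rho must lie in (-1, 1)")
  bg <- sprintf("SPG%04d", seq_len(nGenes))
  X <- matrix(pmax(rnorm(nGenes * nSpots, meanExpr, sdExpr), 0),
              nrow = nGenes, dimnames = list(bg, NULL))
  if (!is.null(plantedPairs)) {
    for (i in seq_len(nrow(plantedPairs))) {
      rho <- plantedPairs$rho[i]
      z1 <- rnorm(nSpots)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(nSpots)
      P <- rbind(pmax(meanExpr + sdExpr * z1, 0),
                 pmax(meanExpr + sdExpr * z2, 0))
      rownames(P) <- toupper(c(plantedPairs$ligand[i],
                               plantedPairs$receptor[i]))
      X <- rbind(X, P)
    }
  }
  colnames(X) <- sprintf("spot%05d", seq_len(ncol(X)))
  layer <- sample(layers, nSpots, replace = TRUE)
  list(dataset = SpatialDataset(X, layer),
       pairs = plantedPairs)
}
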