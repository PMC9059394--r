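#' @importFrom utils read.delim write.table
NULL

.lr_schema <- c("id", "ligand_name", "ligand_subunits", "receptor_name",
                "receptor_subunits", "pathway", "agonists", "antagonists",
                "co_stimulatory", "co_inhibitory", "category")
.lr_mandatory <- c("id", "ligand_name", "ligand_subunits", "receptor_name",
                   "receptor_subunits", "pathway")

.split_genes <- function(x, delim) {
  lapply(as.character(x), function(z) {
    if (is.na(z) || !nzchar(z)) character(0)
    else toupper(strsplit(z, delim, fixed = TRUE)[[1L]])
  })
}

#' Build a ligand-receptor database from a data.frame
#'
#' @param interactions data.frame following the tabular schema of
#'   [readLRDatabase()] with subunit/cofactor fields either delimited strings
#'   or list columns.
#' @param delim delimiter separating complex subunits and cofactor genes in
#'   string fields (default `"_"`, the common L-R resource convention).
#' @return a validated [LRDatabase-class].
#' @export
makeLRDatabase <- function(interactions, delim = "_") {
  x <- interactions
  miss <- setdiff(.lr_mandatory, names(x))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in .lr_list_cols) {
    if (!col %in% names(x)) x[[col]] <- replicate(nrow(x), character(0),
                                                  simplify = FALSE)
    else if (!is.list(x[[col]])) x[[col]] <- .split_genes(x[[col]], delim)
    else x[[col]] <- lapply(x[[col]], toupper)
  }
  if (!"category" %in% names(x)) x$category <- "secreted"
  out <- data.frame(id = as.character(x$id),
                    ligand_name = as.character(x$ligand_name),
                    receptor_name = as.character(x$receptor_name),
                    pathway = as.character(x$pathway),
                    category = as.character(x$category),
                    stringsAsFactors = FALSE)
  for (col in .lr_list_cols) out[[col]] <- x[[col]]
  out <- out[, .lr_schema]
  methods::new("LRDatabase", interactions = out)
}

#' Read a ligand-receptor database from a TSV file
#'
#' The file must carry the columns `id`, `ligand_name`, `ligand_subunits`,
#' `receptor_name`, `receptor_subunits`, `pathway` and may carry `agonists`,
#' `antagonists`, `co_stimulatory`, `co_inhibitory` and `category`
#' (`secreted` / `ecm_receptor` / `cell_contact`, default `secreted`).
#' Subunit and cofactor fields are `delim`-delimited gene symbol lists
#' (empty allowed for cofactors). Unknown columns are ignored with a warning.
#'
#' CellChatDB or CellPhoneDB content can be exported into this schema by
#' flattening each interaction to one row, writing complex subunits as
#' `"_"`-joined symbols (e.g. `NRXN1_NLGN2`) and the curated pathway family
#' into `pathway`; no third-party database content ships with the package.
#'
#' @param path TSV file path.
#' @param delim subunit delimiter (default `"_"`).
#' @return a validated [LRDatabase-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tligand_name\tligand_subunits\treceptor_name\treceptor_subunits\tpathway",
#'              "I1\tFGF1\tFGF1\tFGFR1\tFGFR1\tFGF"), f)
#' db <- readLRDatabase(f)
#' @export
readLRDatabase <- function(path, delim = "_") {
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  unknown <- setdiff(names(x), .lr_schema)
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  makeLRDatabase(x[, intersect(.lr_schema, names(x)), drop = FALSE],
                 delim = delim)
}

#' Write a ligand-receptor database to canonical TSV form
#'
#' @param db an [LRDatabase-class].
#' @param path output TSV path.
#' @param delim subunit delimiter used when joining list fields.
#' @return `path`, invisibly.
#' @export
writeLRDatabase <- function(db, path, delim = "_") {
  x <- db@interactions
  out <- x[, c("id", "ligand_name", "receptor_name", "pathway", "category")]
  for (col in .lr_list_cols)
    out[[col]] <- vapply(x[[col]], paste, "", collapse = delim)
  out <- out[, .lr_schema]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pathway membership of a database
#'
#' @param db an [LRDatabase-class].
#' @return named list mapping each pathway label to its interaction ids; the
#'   lists partition the interaction set.
#' @export
pathways <- function(db) {
  split(db@interactions$id, db@interactions$pathway)
}

#' Gene set of a signaling pathway
#'
#' Deduplicated union of all ligand and receptor subunit genes and (always)
#' all cofactor genes of the pathway's interactions.
#'
#' @param db an [LRDatabase-class].
#' @param pathway pathway label present in `db`.
#' @return character vector of gene symbols.
#' @export
pathwayGeneSet <- function(db, pathway) {
  x <- db@interactions
  if (!pathway %in% x$pathway)
    stop("unknown pathway: ", pathway)
  rows <- which(x$pathway == pathway)
  genes <- unlist(lapply(rows, function(i)
    c(x$ligand_subunits[[i]], x$receptor_subunits[[i]], x$agonists[[i]],
      x$antagonists[[i]], x$co_stimulatory[[i]], x$co_inhibitory[[i]])),
    use.names = FALSE)
  unique(genes)
}

# all gene symbols referenced anywhere in the database, in stable order
.db_genes <- function(db) {
  x <- db@interactions
  unique(unlist(c(x$ligand_subunits, x$receptor_subunits, x$agonists,
                  x$antagonists, x$co_stimulatory, x$co_inhibitory),
                use.names = FALSE))
}
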