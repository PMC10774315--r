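# Plain-text readers/writers for the pipeline's interchange formats: TSV for
# expression and metadata, MatrixMarket or dense TSV for single-cell counts,
# JSON for reports and simulation truth, YAML for configuration.

required_meta_cols <- function() {
  c("sample_id", "dataset", "met_event", "gleason", "age", "psa", "stage",
    "pfs_months", "pfs_event")
}

#' Validate a clinical metadata table
#'
#' @param meta data.frame of per-sample clinical metadata.
#' @param required columns that must be present.
#' @return Invisibly, `meta`; errors name the first missing column.
#' @export
validate_meta <- function(meta, required = required_meta_cols()) {
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(meta)
}

#' Read a bulk cohort from TSV files
#'
#' @param expr_path TSV of samples x genes expression; first column or
#'   rownames hold sample ids, header holds gene ids.
#' @param meta_path TSV of clinical metadata with the columns `sample_id`,
#'   `dataset`, `met_event`, `gleason`, `age`, `psa`, `stage`, `pfs_months`,
#'   `pfs_event`.
#' @return A [bulk_cohort()].
#' @export
read_bulk_cohort <- function(expr_path, meta_path) {
  expr <- utils::read.delim(expr_path, row.names = 1, check.names = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            check.names = FALSE,
                            colClasses = c(gleason = "character"))
  validate_meta(meta)
  meta <- meta[match(rownames(expr), meta$sample_id), , drop = FALSE]
  bulk_cohort(as.matrix(expr), meta)
}

#' Write a bulk cohort to TSV files
#'
#' @param cohort a [bulk_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the two paths written.
#' @export
write_bulk_cohort <- function(cohort, dir, prefix = "bulk") {
  stopifnot(inherits(cohort, "bulk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, paste0(prefix, "_expr.tsv"))
  mp <- file.path(dir, paste0(prefix, "_meta.tsv"))
  utils::write.table(cohort$expr, ep, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.table(cohort$meta, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr = ep, meta = mp))
}

#' Write a single-cell matrix
#'
#' Either a dense TSV (genes x cells) or MatrixMarket sparse format with
#' gene/cell index files; cluster labels go to a cells TSV either way.
#'
#' @param sc an [sc_matrix()].
#' @param dir output directory.
#' @param format `"tsv"` (dense) or `"mtx"` (sparse; needs the Matrix
#'   package).
#' @return Invisibly, the paths written.
#' @export
write_sc_matrix <- function(sc, dir, format = c("tsv", "mtx")) {
  stopifnot(inherits(sc, "sc_matrix"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(cell_id = sc$cell_ids, cluster = sc$cluster_labels,
                      stringsAsFactors = FALSE)
  cp <- file.path(dir, "cells.tsv")
  utils::write.table(cells, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (format == "tsv") {
    xp <- file.path(dir, "counts.tsv")
    utils::write.table(sc$counts, xp, sep = "\t", quote = FALSE,
                       col.names = NA)
    return(invisible(c(counts = xp, cells = cp)))
  }
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MTX output")
  }
  xp <- file.path(dir, "counts.mtx")
  gp <- file.path(dir, "genes.tsv")
  Matrix::writeMM(Matrix::Matrix(sc$counts, sparse = TRUE), xp)
  utils::write.table(data.frame(gene_id = sc$gene_ids), gp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(counts = xp, genes = gp, cells = cp))
}

#' Read a single-cell matrix
#'
#' @param counts_path dense TSV (genes x cells) or `.mtx` MatrixMarket file.
#' @param cells_path TSV with `cell_id` and `cluster` columns.
#' @param genes_path TSV with a `gene_id` column (required for MTX input).
#' @return An [sc_matrix()].
#' @export
read_sc_matrix <- function(counts_path, cells_path, genes_path = NULL) {
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(cells))) {
    stop("cells file needs cell_id and cluster columns")
  }
  if (grepl("\\.mtx$", counts_path)) {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("the Matrix package is required for MTX input")
    }
    if (is.null(genes_path)) stop("genes_path is required with MTX input")
    counts <- as.matrix(Matrix::readMM(counts_path))
    genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)$gene_id
    dimnames(counts) <- list(genes, cells$cell_id)
  } else {
    counts <- as.matrix(utils::read.delim(counts_path, row.names = 1,
                                          check.names = FALSE))
  }
  sc_matrix(counts, cluster_labels = cells$cluster[
    match(colnames(counts), cells$cell_id)])
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] arguments; a `sim:` section is passed
#' to [sim_config()] (with `planted_pairs` / `planted_markers` given as lists
#' of records).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    sim <- raw$sim
    for (fld in c("planted_pairs", "planted_markers")) {
      if (!is.null(sim[[fld]])) {
        sim[[fld]] <- do.call(rbind, lapply(sim[[fld]], function(r) {
          as.data.frame(r, stringsAsFactors = FALSE)
        }))
      }
    }
    if (!is.null(sim$clusters)) sim$clusters <- unlist(sim$clusters)
    raw$sim <- do.call(sim_config, sim)
  }
  do.call(pipeline_config, raw)
}
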