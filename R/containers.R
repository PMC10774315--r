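#' Single-cell count matrix with cluster labels
#'
#' Lightweight container for a genes x cells matrix of non-negative integer
#' counts together with the per-cell cluster assignment. Cluster labels are an
#' input here: clustering itself happens upstream.
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param cell_ids character vector of unique cell identifiers (columns).
#' @param cluster_labels vector of cluster labels, one per cell.
#'
#' @return An object of class `sc_matrix`: a list with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cluster_labels`.
#' @export
sc_matrix <- function(counts, gene_ids = rownames(counts),
                      cell_ids = colnames(counts), cluster_labels) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  cluster_labels <- as.character(cluster_labels)
  if (length(gene_ids) != nrow(counts)) stop("gene_ids length != nrow(counts)")
  if (length(cell_ids) != ncol(counts)) stop("cell_ids length != ncol(counts)")
  if (length(cluster_labels) != ncol(counts)) {
    stop("cluster_labels must have one label per cell")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyNA(cluster_labels)) stop("every cell needs a cluster label")
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         cluster_labels = cluster_labels),
    class = "sc_matrix"
  )
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("<sc_matrix> %d genes x %d cells, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cluster_labels))))
  invisible(x)
}

#' Bulk expression cohort
#'
#' Samples x genes expression matrix (log scale) with a clinical metadata
#' table. Metadata carries dataset of origin, the binary metastasis label,
#' Gleason grade, age, PSA, stage, and (optionally, after
#' [simulate_survival()] or loading) progression-free-survival follow-up.
#'
#' @param expr samples x genes numeric matrix with sample ids as rownames and
#'   gene ids as colnames.
#' @param meta data.frame with one row per sample; must contain `sample_id`
#'   and `dataset` columns, in the same order as `expr` rows.
#'
#' @return An object of class `bulk_cohort`: list with `expr`, `meta`,
#'   `genes`.
#' @export
bulk_cohort <- function(expr, meta) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expr must be numeric")
  if (anyNA(expr)) stop("expr must not contain missing values")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "dataset") %in% names(meta))) {
    stop("meta needs 'sample_id' and 'dataset' columns")
  }
  if (nrow(meta) != nrow(expr)) stop("meta rows must match expr rows")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids")
  if (is.null(rownames(expr))) rownames(expr) <- meta$sample_id
  if (!identical(rownames(expr), as.character(meta$sample_id))) {
    stop("expr rownames must equal meta$sample_id (same order)")
  }
  if (is.null(colnames(expr))) stop("expr needs gene ids as colnames")
  if (anyDuplicated(colnames(expr))) stop("duplicate gene ids")
  structure(list(expr = expr, meta = meta, genes = colnames(expr)),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d samples x %d genes, %d dataset(s)\n",
              nrow(x$expr), ncol(x$expr), length(unique(x$meta$dataset))))
  if ("met_event" %in% names(x$meta)) {
    cat(sprintf("  metastatic: %d / %d\n",
                sum(x$meta$met_event == 1), nrow(x$meta)))
  }
  invisible(x)
}

#' Subset a bulk cohort by sample
#'
#' @param cohort a [bulk_cohort()].
#' @param idx integer, logical or character (sample id) index.
#' @return A `bulk_cohort` restricted to the selected samples.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (is.character(idx)) idx <- match(idx, cohort$meta$sample_id)
  bulk_cohort(cohort$expr[idx, , drop = FALSE],
              cohort$meta[idx, , drop = FALSE])
}

#' Split a multi-dataset cohort into one cohort per dataset
#'
#' @param cohort a [bulk_cohort()] whose `meta$dataset` has >= 1 level.
#' @return Named list of `bulk_cohort` objects, one per dataset.
#' @export
split_by_dataset <- function(cohort) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  ds <- unique(cohort$meta$dataset)
  out <- lapply(ds, function(d) subset_cohort(cohort, cohort$meta$dataset == d))
  names(out) <- ds
  out
}
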