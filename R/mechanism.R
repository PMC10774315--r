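#' Build the mechanism pair set from cluster marker tables
#'
#' For each cluster, significant markers (`fdr < fdr_max`) are divided by the
#' sign of their average log fold change; the top `n_top` positive markers
#' (descending `avg_logfc`) are paired with the top `n_top` negative markers
#' (ascending `avg_logfc`) in all positive x negative ordered combinations.
#' Each pair is oriented: the up gene is expected to out-rank the down gene in
#' samples resembling the marker-bearing clusters. Ties in `avg_logfc` at the
#' `n_top` boundary break lexicographically by gene id for reproducibility.
#'
#' With three clusters each contributing 100 positive and 100 negative
#' markers, the cluster-tagged total is 3 x 100 x 100 = 30,000 pairs. Training
#' uses the deduplicated pooled view; the cluster-tagged multiset is kept for
#' audit.
#'
#' @param marker_tables named list of [rank_markers()] tables, one per cluster.
#' @param n_top number of markers of each sign taken per cluster.
#' @param fdr_max significance gate applied to markers before pairing.
#' @return An object of class `mechanism_pairs`: list with `pairs`
#'   (cluster-tagged data.frame `cluster`, `up_gene`, `down_gene`), `pooled`
#'   (deduplicated `up_gene`, `down_gene`), and `counts` per cluster.
#' @export
build_mechanism <- function(marker_tables, n_top = 100, fdr_max = 0.05) {
  if (n_top < 1) stop("n_top must be >= 1")
  if (is.data.frame(marker_tables)) marker_tables <- list(marker_tables)
  if (is.null(names(marker_tables)) || any(names(marker_tables) == "")) {
    names(marker_tables) <- vapply(seq_along(marker_tables), function(i) {
      cl <- unique(marker_tables[[i]]$cluster)
      if (length(cl) == 1) as.character(cl) else paste0("cluster", i)
    }, character(1))
  }
  per_cluster <- lapply(names(marker_tables), function(cn) {
    tab <- marker_tables[[cn]]
    tab <- tab[!is.na(tab$fdr) & tab$fdr < fdr_max, , drop = FALSE]
    pos <- tab[tab$avg_logfc > 0, , drop = FALSE]
    neg <- tab[tab$avg_logfc < 0, , drop = FALSE]
    pos <- pos[order(-pos$avg_logfc, pos$gene), , drop = FALSE]
    neg <- neg[order(neg$avg_logfc, neg$gene), , drop = FALSE]
    pos <- utils::head(pos$gene, n_top)
    neg <- utils::head(neg$gene, n_top)
    if (length(pos) == 0 || length(neg) == 0) {
      warning("cluster '", cn, "' has no ",
              if (length(pos) == 0) "positive" else "negative",
              " markers; it contributes 0 pairs")
      return(data.frame(cluster = character(), up_gene = character(),
                        down_gene = character(), stringsAsFactors = FALSE))
    }
    grid <- expand.grid(up_gene = pos, down_gene = neg,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(cluster = cn, grid, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, per_cluster)
  rownames(pairs) <- NULL
  pooled <- unique(pairs[, c("up_gene", "down_gene"), drop = FALSE])
  rownames(pooled) <- NULL
  counts <- vapply(per_cluster, nrow, integer(1))
  names(counts) <- names(marker_tables)
  structure(list(pairs = pairs, pooled = pooled, counts = counts),
            class = "mechanism_pairs")
}

#' @export
print.mechanism_pairs <- function(x, ...) {
  cat(sprintf("<mechanism_pairs> %d cluster-tagged pairs (%d pooled unique)\n",
              nrow(x$pairs), nrow(x$pooled)))
  for (cn in names(x$counts)) {
    cat(sprintf("  %s: %d pairs\n", cn, x$counts[[cn]]))
  }
  invisible(x)
}
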