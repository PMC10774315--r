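# Two-part (hurdle) differential expression for zero-inflated log expression.
#
# Detection part: logistic model of P(expr > 0) on a binary group; continuous
# part: equal-variance Gaussian model of expr among detected cells. With a
# single binary covariate both parts have closed-form MLEs, so the joint
# likelihood-ratio statistic is computed exactly rather than by IWLS.

# Vectorized closed-form two-part LRT over the rows of a genes x cells matrix
# of log expression (zeros = undetected). Returns one row per gene.
hurdle_stats <- function(x, in_group) {
  x <- matrix(x, nrow = if (is.matrix(x)) nrow(x) else 1)
  in_group <- as.logical(in_group)
  n1 <- sum(in_group); n0 <- sum(!in_group)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  if (any(x < 0)) stop("log expression must be non-negative")

  det <- x > 0
  k1 <- rowSums(det[, in_group, drop = FALSE])
  k0 <- rowSums(det[, !in_group, drop = FALSE])

  # binomial log likelihood with 0*log(0) = 0
  bll <- function(k, n) {
    p <- k / n
    out <- numeric(length(k))
    pos <- k > 0
    out[pos] <- out[pos] + k[pos] * log(p[pos])
    q <- n - k
    neg <- q > 0
    out[neg] <- out[neg] + q[neg] * log(1 - p[neg])
    out
  }
  lrt_det <- 2 * (bll(k1, n1) + bll(k0, n0) - bll(k1 + k0, n1 + n0))
  detect_coef <- stats::qlogis(k1 / n1) - stats::qlogis(k0 / n0)

  # continuous part on detected cells only (undetected entries are exactly 0,
  # so sums over detected cells are plain row sums)
  s1 <- rowSums(x[, in_group, drop = FALSE])
  s0 <- rowSums(x[, !in_group, drop = FALSE])
  q1 <- rowSums(x[, in_group, drop = FALSE]^2)
  q0 <- rowSums(x[, !in_group, drop = FALSE]^2)
  m1 <- ifelse(k1 > 0, s1 / k1, NA_real_)
  m0 <- ifelse(k0 > 0, s0 / k0, NA_real_)
  kd <- k1 + k0
  mg <- ifelse(kd > 0, (s1 + s0) / kd, NA_real_)
  ss_full <- (q1 - k1 * ifelse(k1 > 0, m1^2, 0)) +
    (q0 - k0 * ifelse(k0 > 0, m0^2, 0))
  ss_null <- (q1 + q0) - kd * ifelse(kd > 0, mg^2, 0)
  both <- k1 > 0 & k0 > 0
  lrt_cont <- numeric(nrow(x))
  eps <- 1e-12
  ok <- both & ss_full > eps * pmax(1, q1 + q0)
  lrt_cont[ok] <- kd[ok] * log(ss_null[ok] / ss_full[ok])
  degen <- both & !ok
  lrt_cont[degen] <- ifelse(ss_null[degen] > eps * pmax(1, q1 + q0)[degen],
                            Inf, 0)
  lrt_cont[!both] <- 0
  lrt_cont <- pmax(lrt_cont, 0)

  df <- ifelse(both, 2L, 1L)
  lrt <- pmax(lrt_det, 0) + lrt_cont
  data.frame(
    detect_coef = detect_coef,
    cont_coef = m1 - m0,
    lrt_stat = lrt,
    df = df,
    p_value = stats::pchisq(lrt, df = df, lower.tail = FALSE),
    cont_dropped = !both
  )
}

#' Fit the two-part hurdle model to one gene
#'
#' @param expr non-negative log-expression vector; zeros mean undetected.
#' @param group binary labels (logical, 0/1, or two-level factor); `TRUE`/1 is
#'   the group of interest.
#' @return An object of class `hurdle_fit`: list with `detect_coef` (log-odds
#'   difference of detection), `cont_coef` (mean log-expression difference
#'   among detected cells), `lrt_stat`, `df` (2, or 1 when a group has no
#'   detected cells and the continuous part is dropped — flagged by
#'   `cont_dropped`), and `p_value` from the chi-square reference.
#' @export
fit_hurdle <- function(expr, group) {
  if (is.factor(group) || is.character(group)) {
    lev <- unique(as.character(group))
    if (length(lev) != 2) stop("group must be binary")
    group <- as.character(group) == lev[1]
  }
  group <- as.logical(group)
  if (anyNA(group)) stop("group labels must not be missing")
  if (length(expr) != length(group)) stop("expr and group lengths differ")
  st <- hurdle_stats(matrix(expr, nrow = 1), group)
  structure(as.list(st[1, ]), class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf(
    "<hurdle_fit> LRT = %.4g on %d df, p = %.3g\n  detection log-odds diff = %.4g, continuous mean diff = %.4g%s\n",
    x$lrt_stat, x$df, x$p_value, x$detect_coef, x$cont_coef,
    if (x$cont_dropped) " (continuous part dropped)" else ""))
  invisible(x)
}

# Library-size normalization to a fixed scale followed by log1p, the
# transformation the hurdle test expects as input.
lognormalize_counts <- function(counts, scale_factor = 1e4) {
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("cells with zero total counts")
  log1p(sweep(counts, 2, libsize / scale_factor, `/`))
}

#' Rank cluster markers with the hurdle model
#'
#' Compares one cluster against all other cells pooled. Genes are prefiltered
#' before any testing: the average natural-log fold change
#' `ln(mean(expm1(x_in)) + 1) - ln(mean(expm1(x_out)) + 1)` must reach
#' `logfc_min` in absolute value and the gene must be detected in at least
#' `min_pct` of cells in either group. Surviving genes get the two-part hurdle
#' LRT and Benjamini-Hochberg FDR across exactly the tested genes.
#'
#' @param sc an [sc_matrix()] of raw counts.
#' @param cluster cluster label to contrast against the rest.
#' @param logfc_min minimum absolute average log fold change (natural log);
#'   default 0.25.
#' @param min_pct minimum detection fraction required in at least one of the
#'   two groups; default 0.10.
#' @param scale_factor library-size normalization target before log1p.
#' @return A `marker_table` data.frame with columns `gene`, `cluster`,
#'   `avg_logfc`, `pct_in`, `pct_out`, `lrt_stat`, `p_value`, `fdr`, sorted by
#'   decreasing signed `avg_logfc`.
#' @export
rank_markers <- function(sc, cluster, logfc_min = 0.25, min_pct = 0.10,
                         scale_factor = 1e4) {
  stopifnot(inherits(sc, "sc_matrix"))
  if (!cluster %in% sc$cluster_labels) {
    stop("cluster '", cluster, "' not present in cluster labels")
  }
  if (length(unique(sc$cluster_labels)) < 2) stop("need >= 2 clusters")
  in_group <- sc$cluster_labels == cluster
  x <- lognormalize_counts(sc$counts, scale_factor)

  pct_in <- rowMeans(x[, in_group, drop = FALSE] > 0)
  pct_out <- rowMeans(x[, !in_group, drop = FALSE] > 0)
  mean_in <- rowMeans(expm1(x[, in_group, drop = FALSE]))
  mean_out <- rowMeans(expm1(x[, !in_group, drop = FALSE]))
  avg_logfc <- log(mean_in + 1) - log(mean_out + 1)

  keep <- abs(avg_logfc) >= logfc_min & pmax(pct_in, pct_out) >= min_pct
  if (!any(keep)) {
    warning("all genes removed by the prefilters; empty marker table")
    return(empty_marker_table(cluster))
  }
  st <- hurdle_stats(x[keep, , drop = FALSE], in_group)
  out <- data.frame(
    gene = sc$gene_ids[keep], cluster = cluster,
    avg_logfc = avg_logfc[keep], pct_in = pct_in[keep],
    pct_out = pct_out[keep], lrt_stat = st$lrt_stat, p_value = st$p_value,
    fdr = stats::p.adjust(st$p_value, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$avg_logfc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

empty_marker_table <- function(cluster) {
  out <- data.frame(gene = character(), cluster = character(),
                    avg_logfc = numeric(), pct_in = numeric(),
                    pct_out = numeric(), lrt_stat = numeric(),
                    p_value = numeric(), fdr = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_table", "data.frame")
  out
}
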