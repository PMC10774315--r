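#' Harmonize multiple bulk expression datasets
#'
#' Each dataset is (optionally) log2-transformed and then z-scored gene-wise,
#' so per-dataset location/scale batch effects are removed; gene sets are then
#' intersected and samples concatenated. Genes constant within any dataset
#' cannot be z-scored and are dropped everywhere with a warning.
#'
#' @param datasets list of [bulk_cohort()] objects (or a single cohort).
#' @param log2_transform logical scalar or vector (one per dataset): apply
#'   `log2(x + 1)` first for datasets still on a linear scale.
#' @return A single harmonized [bulk_cohort()]; within it, every dataset has
#'   per-gene mean 0 and sd 1.
#' @export
harmonize <- function(datasets, log2_transform = FALSE) {
  if (inherits(datasets, "bulk_cohort")) datasets <- list(datasets)
  if (length(datasets) < 1) stop("need at least one dataset")
  log2_transform <- rep_len(log2_transform, length(datasets))
  for (d in datasets) {
    stopifnot(inherits(d, "bulk_cohort"))
    if (nrow(d$expr) < 2) stop("each dataset needs >= 2 samples")
  }
  scaled <- vector("list", length(datasets))
  constant <- character()
  for (i in seq_along(datasets)) {
    x <- datasets[[i]]$expr
    if (log2_transform[i]) x <- log2(x + 1)
    sds <- apply(x, 2, stats::sd)
    constant <- union(constant, colnames(x)[!is.finite(sds) | sds == 0])
    scaled[[i]] <- scale(x)
  }
  genes <- Reduce(intersect, lapply(scaled, colnames))
  genes <- setdiff(genes, constant)
  if (length(constant)) {
    warning("dropped ", length(constant),
            " gene(s) constant within a dataset: ",
            paste(utils::head(constant, 5), collapse = ", "),
            if (length(constant) > 5) ", ..." else "")
  }
  if (length(genes) == 0) stop("empty gene intersection across datasets")
  expr <- do.call(rbind, lapply(scaled, function(x) {
    y <- x[, genes, drop = FALSE]
    attr(y, "scaled:center") <- NULL
    attr(y, "scaled:scale") <- NULL
    y
  }))
  meta_cols <- Reduce(intersect, lapply(datasets, function(d) names(d$meta)))
  meta <- do.call(rbind, lapply(datasets, function(d) {
    d$meta[, meta_cols, drop = FALSE]
  }))
  rownames(meta) <- NULL
  bulk_cohort(expr, meta)
}

# Cut a numeric clinical variable into tertiles computed on the full cohort;
# missing values become their own "unknown" level so the partition stays
# exhaustive.
tertile_bin <- function(x) {
  out <- rep("unknown", length(x))
  ok <- !is.na(x)
  if (sum(ok) >= 3) {
    q <- stats::quantile(x[ok], probs = c(1 / 3, 2 / 3), names = FALSE)
    out[ok] <- c("t1", "t2", "t3")[1L + (x[ok] > q[1]) + (x[ok] > q[2])]
  } else if (any(ok)) {
    out[ok] <- "t1"
  }
  out
}

#' Stratified train/test split with largest-remainder allocation
#'
#' Strata are the cross of dataset, Gleason grade, age tertile, PSA tertile
#' and stage (continuous variables are binned into tertiles on the full
#' cohort; missing values form an "unknown" level). Each stratum contributes
#' `floor(train_frac * n_s)` training samples plus largest-remainder top-ups
#' so that the global training count is exactly `ceiling(train_frac * n)`.
#' Strata of size 1 go wholly to training (with a warning). A cohort of 1,239
#' samples at `train_frac = 0.75` therefore splits into 930 training and 309
#' testing samples.
#'
#' @param cohort a [bulk_cohort()].
#' @param train_frac training fraction in (0, 1).
#' @param strata_vars metadata columns to stratify on; numeric ones are
#'   binned into tertiles.
#' @param seed integer seed for the within-stratum draw.
#' @return list with `train` and `test` cohorts (disjoint, exhaustive).
#' @export
stratified_split <- function(cohort, train_frac = 0.75,
                             strata_vars = c("dataset", "gleason", "age",
                                             "psa", "stage"),
                             seed = 1L) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  missing_vars <- setdiff(strata_vars, names(cohort$meta))
  if (length(missing_vars)) {
    stop("strata variable(s) absent from metadata: ",
         paste(missing_vars, collapse = ", "))
  }
  parts <- lapply(strata_vars, function(v) {
    x <- cohort$meta[[v]]
    if (is.numeric(x)) tertile_bin(x) else {
      x <- as.character(x)
      x[is.na(x)] <- "unknown"
      x
    }
  })
  strata <- do.call(paste, c(parts, sep = "|"))
  n <- nrow(cohort$meta)
  target <- ceiling(train_frac * n)

  sizes <- table(strata)
  nm <- names(sizes)
  ns <- as.integer(sizes)
  quota <- ns * train_frac
  alloc <- floor(quota)
  singleton <- ns == 1L
  if (any(singleton)) {
    alloc[singleton] <- 1L
    warning(sum(singleton),
            " stratum/strata of size 1 assigned wholly to training")
  }
  remainder <- quota - floor(quota)
  diff <- target - sum(alloc)
  if (diff > 0) {
    elig <- which(alloc < ns)
    ord <- elig[order(-remainder[elig], -ns[elig], nm[elig])]
    take <- utils::head(ord, diff)
    alloc[take] <- alloc[take] + 1L
    diff <- target - sum(alloc)
  }
  if (diff < 0) {
    elig <- which(alloc > 0 & !singleton)
    ord <- elig[order(remainder[elig], ns[elig], nm[elig])]
    take <- utils::head(ord, -diff)
    alloc[take] <- alloc[take] - 1L
  }
  if (sum(alloc) != target) {
    stop("internal allocation failure: ", sum(alloc), " != ", target)
  }

  set.seed(seed)
  train_idx <- integer(0)
  for (i in seq_along(nm)) {
    members <- which(strata == nm[i])
    a <- alloc[i]
    if (a >= length(members)) {
      chosen <- members
    } else if (a == 0L) {
      chosen <- integer(0)
    } else {
      chosen <- sample(members, a)
    }
    train_idx <- c(train_idx, chosen)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = subset_cohort(cohort, train_idx),
       test = subset_cohort(cohort, test_idx))
}

#' Quantile normalization across samples
#'
#' Each sample's values are replaced by the mean order-statistic profile of
#' all samples; afterwards every sample shares the same value multiset. Ties
#' within a sample receive the average of their target quantiles. Delegates to
#' `limma::normalizeQuantiles(..., ties = TRUE)`, which implements exactly
#' this convention. Rank-based pair votes are unaffected (the map is
#' monotone within sample); only magnitude-based models see the change.
#'
#' @param x samples x genes matrix, or a [bulk_cohort()].
#' @return Object of the same kind with normalized expression.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "bulk_cohort")) {
    x$expr <- quantile_normalize(x$expr)
    return(x)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) {
    warning("single sample: quantile normalization is a no-op")
    return(x)
  }
  out <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(out) <- dimnames(x)
  out
}
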