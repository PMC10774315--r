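# Harmonization, stratified splitting and quantile normalization.

test_that("harmonizing an already z-scored dataset is the identity", {
  set.seed(8)
  x <- scale(matrix(rnorm(200), nrow = 20,
                    dimnames = list(sprintf("s%02d", 1:20),
                                    paste0("g", 1:10))))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  co <- tiny_cohort(x, met = rep(0:1, 10))
  h <- harmonize(co)
  expect_equal(h$expr, x, tolerance = 1e-12)
})

test_that("gene sets intersect and per-dataset moments are exactly normalized", {
  set.seed(9)
  x1 <- matrix(rnorm(60, 5, 2), nrow = 20,
               dimnames = list(sprintf("a%02d", 1:20), c("g1", "g2", "g3")))
  x2 <- matrix(rnorm(45, -3, 5), nrow = 15,
               dimnames = list(sprintf("b%02d", 1:15), c("g2", "g3", "g4")))
  h <- harmonize(list(tiny_cohort(x1, met = 0, dataset = "d1"),
                      tiny_cohort(x2, met = 1, dataset = "d2")))
  expect_identical(colnames(h$expr), c("g2", "g3"))
  for (d in c("d1", "d2")) {
    sub <- h$expr[h$meta$dataset == d, ]
    expect_equal(unname(colMeans(sub)), c(0, 0), tolerance = 1e-8)
    expect_equal(unname(apply(sub, 2, sd)), c(1, 1), tolerance = 1e-8)
    # direct recomputation from the raw input
    raw <- if (d == "d1") x1 else x2
    expect_equal(sub, scale(raw)[, c("g2", "g3")], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("constant genes are dropped everywhere and empty intersections fail", {
  x1 <- matrix(rnorm(40), nrow = 10,
               dimnames = list(sprintf("a%02d", 1:10),
                               c("g1", "g2", "g3", "g4")))
  x1[, "g2"] <- 7
  x2 <- matrix(rnorm(40), nrow = 10,
               dimnames = list(sprintf("b%02d", 1:10),
                               c("g1", "g2", "g3", "g4")))
  expect_warning(
    h <- harmonize(list(tiny_cohort(x1, 0, "d1"), tiny_cohort(x2, 1, "d2"))),
    "constant")
  expect_false("g2" %in% colnames(h$expr))
  x3 <- x2
  colnames(x3) <- paste0("h", 1:4)
  expect_error(
    suppressWarnings(harmonize(list(tiny_cohort(x1, 0, "d1"),
                                    tiny_cohort(x3, 1, "d2")))),
    "intersection")
})

test_that("per-dataset z-scoring removes planted batch shifts", {
  cfg <- sim_config(n_genes = 80, bulk_n_samples = 200, bulk_n_datasets = 2,
                    planted_pairs = NULL, n_decoy_markers = 0,
                    batch_shift_sd = 1.5, batch_scale_sd = 0.3, seed = 17L)
  co <- simulate_bulk_cohort(cfg)$cohort
  ds <- as.integer(co$meta$dataset == "ds2")
  gap <- function(x) mean(abs(colMeans(x[ds == 1, ]) - colMeans(x[ds == 0, ])))
  h <- harmonize(split_by_dataset(co))
  hx <- h$expr[match(co$meta$sample_id, h$meta$sample_id), ]
  # per-gene dataset shifts are large before z-scoring and gone after
  expect_gt(gap(co$expr), 0.5)
  expect_lt(gap(hx), 1e-8)
  post <- auroc(rowMeans(hx), ds)
  expect_lt(abs(post - 0.5), 0.1)
})

test_that("the stratified split reproduces the published cohort arithmetic", {
  cfg <- sim_config(n_genes = 20, planted_pairs = NULL, n_decoy_markers = 0,
                    bulk_n_samples = 1239, bulk_n_datasets = 7, seed = 3L)
  co <- simulate_bulk_cohort(cfg)$cohort
  sp <- suppressWarnings(stratified_split(co, train_frac = 0.75, seed = 5L))
  expect_identical(nrow(sp$train$expr), 930L)
  expect_identical(nrow(sp$test$expr), 309L)
  # disjoint and exhaustive
  expect_length(intersect(sp$train$meta$sample_id, sp$test$meta$sample_id), 0)
  expect_setequal(c(sp$train$meta$sample_id, sp$test$meta$sample_id),
                  co$meta$sample_id)
})

test_that("largest-remainder allocation is balanced within strata", {
  # two strata of 2 at fraction 1/2: one sample each side per stratum
  x <- matrix(rnorm(8), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("g1", "g2")))
  co <- tiny_cohort(x, met = c(0, 1, 0, 1), dataset = c("d1", "d1", "d2", "d2"))
  sp <- stratified_split(co, train_frac = 0.5, strata_vars = "dataset",
                         seed = 1L)
  for (d in c("d1", "d2")) {
    expect_identical(sum(sp$train$meta$dataset == d), 1L)
    expect_identical(sum(sp$test$meta$dataset == d), 1L)
  }
  # strata of 60 and 40 at 0.75 contribute exactly 45 and 30
  x2 <- matrix(rnorm(200), nrow = 100,
               dimnames = list(sprintf("s%03d", 1:100), c("g1", "g2")))
  co2 <- tiny_cohort(x2, met = rep(0:1, 50),
                     dataset = rep(c("d1", "d2"), c(60, 40)))
  sp2 <- stratified_split(co2, train_frac = 0.75, strata_vars = "dataset",
                          seed = 2L)
  expect_identical(sum(sp2$train$meta$dataset == "d1"), 45L)
  expect_identical(sum(sp2$train$meta$dataset == "d2"), 30L)
  # per-stratum training fraction within one sample of the target
  tab <- table(co2$meta$dataset)
  for (d in names(tab)) {
    expect_lte(abs(sum(sp2$train$meta$dataset == d) - 0.75 * tab[[d]]), 1)
  }
})

test_that("singleton strata go to training with a warning", {
  x <- matrix(rnorm(10), nrow = 5,
              dimnames = list(paste0("s", 1:5), c("g1", "g2")))
  co <- tiny_cohort(x, met = c(0, 1, 0, 1, 0),
                    dataset = c("d1", "d1", "d1", "d1", "lonely"))
  expect_warning(
    sp <- stratified_split(co, train_frac = 0.6, strata_vars = "dataset",
                           seed = 1L),
    "size 1")
  expect_true("s5" %in% sp$train$meta$sample_id)
})

test_that("quantile normalization has its defining fixed points and properties", {
  # permuted columns of one multiset: already a fixed point
  x <- rbind(s1 = c(3, 1, 2), s2 = c(2, 3, 1))
  colnames(x) <- paste0("g", 1:3)
  expect_equal(quantile_normalize(x), x)
  # hand-computed mean order statistics
  y <- rbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  colnames(y) <- paste0("g", 1:3)
  qn <- quantile_normalize(y)
  expect_equal(unname(qn["s1", ]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn["s2", ]), c(2.5, 3.5, 4.5))
  # all samples share one multiset afterwards, and the map is idempotent
  set.seed(10)
  z <- matrix(rnorm(300), nrow = 6,
              dimnames = list(paste0("s", 1:6), paste0("g", 1:50)))
  qz <- quantile_normalize(z)
  sorted <- t(apply(qz, 1, sort))
  for (i in 2:6) expect_equal(sorted[i, ], sorted[1, ], tolerance = 1e-12,
                              ignore_attr = TRUE)
  expect_equal(quantile_normalize(qz), qz, tolerance = 1e-12)
  # ties within a sample receive the average of their target quantiles
  w <- rbind(s1 = c(1, 1, 5), s2 = c(10, 20, 30))
  colnames(w) <- paste0("g", 1:3)
  qw <- quantile_normalize(w)
  m <- c(mean(c(1, 10)), mean(c(1, 20)), mean(c(5, 30)))
  expect_equal(unname(qw["s1", ]), c(mean(m[1:2]), mean(m[1:2]), m[3]))
  expect_warning(one <- quantile_normalize(y[1, , drop = FALSE]), "single")
  expect_equal(one, y[1, , drop = FALSE])
})
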