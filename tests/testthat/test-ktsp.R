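# k-TSP scoring, disjoint selection, k selection and voting.

test_that("perfect and null pairs get delta 1 and 0", {
  expr <- cbind(up = c(5, 6, 7, 1, 2, 3), dn = c(1, 2, 3, 5, 6, 7),
                n1 = c(2, 1, 2, 2, 1, 2), n2 = c(1, 2, 1, 1, 2, 1))
  co <- tiny_cohort(expr, met = rep(1:0, each = 3))
  scored <- score_pairs(co, data.frame(up_gene = c("up", "n1"),
                                       down_gene = c("dn", "n2")))
  expect_equal(scored$delta[scored$up_gene == "up"], 1)
  expect_equal(scored$delta[scored$up_gene == "n1"], 0)
})

test_that("delta and gamma match brute-force counting on a 5+5 fixture", {
  set.seed(14)
  expr <- matrix(round(rnorm(10 * 8), 2), nrow = 10,
                 dimnames = list(sprintf("s%02d", 1:10), paste0("g", 1:8)))
  expr[3, "g1"] <- expr[3, "g2"]  # exact expression tie inside a pair
  y <- rep(c(1, 0), each = 5)
  mech <- data.frame(up_gene = c("g1", "g3", "g5"),
                     down_gene = c("g2", "g4", "g6"))
  co <- tiny_cohort(expr, met = y)
  scored <- score_pairs(co, mech)
  for (i in seq_len(nrow(mech))) {
    o <- brute_delta_gamma(expr, y, mech$up_gene[i], mech$down_gene[i])
    row <- scored[scored$up_gene == mech$up_gene[i], ]
    expect_equal(row$delta, o$delta, tolerance = 1e-12)
    expect_equal(row$gamma, o$gamma, tolerance = 1e-12)
  }
  expect_true(all(scored$delta >= -1 & scored$delta <= 1))
})

test_that("swapping class labels negates delta", {
  set.seed(15)
  expr <- matrix(rnorm(60), nrow = 10,
                 dimnames = list(sprintf("s%02d", 1:10), paste0("g", 1:6)))
  y <- rep(c(1, 0), each = 5)
  mech <- data.frame(up_gene = c("g1", "g3"), down_gene = c("g2", "g4"))
  d1 <- score_pairs(tiny_cohort(expr, met = y), mech)
  d2 <- score_pairs(tiny_cohort(expr, met = 1 - y), mech)
  d2 <- d2[match(paste(d1$up_gene, d1$down_gene),
                 paste(d2$up_gene, d2$down_gene)), ]
  expect_equal(d1$delta, -d2$delta, tolerance = 1e-12)
})

test_that("scores, votes and predictions are rank-invariant per sample", {
  set.seed(16)
  expr <- matrix(rnorm(12 * 10), nrow = 12,
                 dimnames = list(sprintf("s%02d", 1:12), paste0("g", 1:10)))
  y <- rep(c(1, 0), each = 6)
  mech <- data.frame(up_gene = paste0("g", c(1, 3, 5)),
                     down_gene = paste0("g", c(2, 4, 6)))
  co <- tiny_cohort(expr, met = y)
  # per-sample strictly increasing transforms: affine and nonlinear
  tr <- expr
  for (i in seq_len(nrow(expr))) {
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    tr[i, ] <- a * exp(expr[i, ] / 2) + b
  }
  co_tr <- tiny_cohort(tr, met = y)
  s1 <- score_pairs(co, mech)
  s2 <- score_pairs(co_tr, mech)
  expect_equal(s1, s2, tolerance = 1e-12)
  m <- suppressWarnings(select_pairs(s1, 3))
  expect_equal(predict(m, co), predict(m, co_tr), tolerance = 1e-12)
})

test_that("greedy disjoint selection handles overlap, exhaustion and ordering", {
  scored <- data.frame(
    up_gene = c("a", "a", "a"), down_gene = c("x", "y", "z"),
    delta = c(0.9, 0.8, 0.7), gamma = c(1, 1, 1), stringsAsFactors = FALSE)
  class(scored) <- c("scored_pairs", "data.frame")
  expect_warning(m <- select_pairs(scored, 5), "disjoint")
  expect_identical(m$k, 1L)
  expect_identical(m$pairs$down_gene, "x")
  # pairs with delta <= 0 are never selected
  scored2 <- rbind(scored,
                   data.frame(up_gene = "b", down_gene = "c", delta = -0.5,
                              gamma = 9))
  m2 <- suppressWarnings(select_pairs(scored2, 5))
  expect_false("b" %in% m2$pairs$up_gene)
})

test_that("greedy selection equals exhaustive enumeration on small instances", {
  set.seed(17)
  for (rep in 1:8) {
    n_samp <- sample(6:12, 1)
    n_gene <- sample(8:12, 1)
    expr <- matrix(rnorm(n_samp * n_gene), nrow = n_samp,
                   dimnames = list(sprintf("s%02d", seq_len(n_samp)),
                                   sprintf("g%02d", seq_len(n_gene))))
    y <- sample(rep(c(1, 0), length.out = n_samp))
    if (length(unique(y)) < 2) next
    pairs <- t(combn(sprintf("g%02d", seq_len(n_gene)), 2))
    pairs <- pairs[sample(nrow(pairs), min(25, nrow(pairs))), , drop = FALSE]
    mech <- data.frame(up_gene = pairs[, 1], down_gene = pairs[, 2],
                       stringsAsFactors = FALSE)
    co <- tiny_cohort(expr, met = y)
    scored <- score_pairs(co, mech)
    # scoring vs brute force for every candidate
    for (i in seq_len(nrow(mech))) {
      o <- brute_delta_gamma(expr, y, mech$up_gene[i], mech$down_gene[i])
      row <- scored[scored$up_gene == mech$up_gene[i] &
                      scored$down_gene == mech$down_gene[i], ]
      expect_equal(row$delta, o$delta, tolerance = 1e-12)
      expect_equal(row$gamma, o$gamma, tolerance = 1e-12)
    }
    # greedy vs exhaustive disjoint search
    k <- sample(2:3, 1)
    m <- suppressWarnings(select_pairs(scored, k))
    oracle <- exhaustive_ktsp(scored, k)
    expect_equal(m$pairs[, c("up_gene", "down_gene", "delta", "gamma")],
                 oracle[, c("up_gene", "down_gene", "delta", "gamma")],
                 ignore_attr = TRUE)
  }
})

test_that("majority voting follows the documented tie policies", {
  expr <- matrix(c(2, 1,   # pair 1 votes 1
                   1.5, 1.5,  # pair 2 ties -> half vote
                   1, 2),  # pair 3 votes 0
                 nrow = 1, dimnames = list("s1", paste0("g", 1:6)))
  model <- structure(list(
    pairs = data.frame(up_gene = paste0("g", c(1, 3, 5)),
                       down_gene = paste0("g", c(2, 4, 6)),
                       delta = c(0.9, 0.8, 0.7), gamma = 1:3),
    k = 3L, tie_policy = "met"), class = "ktsp_model")
  co <- tiny_cohort(expr, met = 1)
  p <- predict(model, co)
  expect_equal(p$vote_fraction, 0.5)
  expect_identical(p$pred_class, 1L)
  model$tie_policy <- "nonmet"
  expect_identical(predict(model, co)$pred_class, 0L)
  # unanimity and simple majority
  expr2 <- rbind(s1 = c(2, 1, 3, 1, 4, 1), s2 = c(2, 1, 1, 3, 1, 4))
  colnames(expr2) <- paste0("g", 1:6)
  co2 <- tiny_cohort(expr2, met = c(1, 0))
  model$tie_policy <- "met"
  p2 <- predict(model, co2)
  expect_equal(p2$vote_fraction, c(1, 1 / 3))
  expect_identical(p2$pred_class, c(1L, 0L))
  # a missing model gene is a named error
  co3 <- tiny_cohort(expr2[, 1:5], met = c(1, 0))
  expect_error(predict(model, co3), "g6")
})

test_that("cross-validated k selection is sane on forced and planted cases", {
  cfg <- sim_config(n_genes = 60, bulk_n_samples = 200, bulk_n_datasets = 1,
                    planted_pairs = default_planted_pairs(60, 2),
                    inversion_prob_met = 0.9, inversion_prob_nonmet = 0.1,
                    batch_shift_sd = 0, batch_scale_sd = 0, seed = 19L)
  co <- simulate_bulk_cohort(cfg)$cohort
  # single candidate: forced choice regardless of the grid
  expect_identical(
    suppressWarnings(choose_k(co, cfg$planted_pairs[1, ], k_grid = c(3L, 5L),
                              folds = 3L, seed = 1L)), 1L)
  # singleton grid with enough strongly scoring supply
  cfg4 <- sim_config(n_genes = 60, bulk_n_samples = 200, bulk_n_datasets = 1,
                     planted_pairs = default_planted_pairs(60, 4),
                     inversion_prob_met = 0.9, inversion_prob_nonmet = 0.1,
                     batch_shift_sd = 0, batch_scale_sd = 0, seed = 20L)
  co4 <- simulate_bulk_cohort(cfg4)$cohort
  expect_identical(choose_k(co4, cfg4$planted_pairs, k_grid = 3L, folds = 3L,
                            seed = 1L), 3L)
})

test_that("thirteen strongly planted pairs steer CV towards k near 13", {
  hits <- 0L
  for (s in 1:20) {
    cfg <- sim_config(n_genes = 60, bulk_n_samples = 600, bulk_n_datasets = 1,
                      planted_pairs = default_planted_pairs(60, 13),
                      n_decoy_markers = 0,
                      inversion_prob_met = 0.85, inversion_prob_nonmet = 0.15,
                      batch_shift_sd = 0, batch_scale_sd = 0, seed = 100L + s)
    co <- simulate_bulk_cohort(cfg)$cohort
    free <- setdiff(co$genes, unlist(cfg$planted_pairs))
    mech <- rbind(cfg$planted_pairs,
                  data.frame(up_gene = free[seq(1, 20, 2)],
                             down_gene = free[seq(2, 20, 2)]))
    k <- choose_k(co, mech, seed = s)
    if (k >= 9 && k <= 17) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("planted pairs dominate the top disjoint selections across seeds", {
  ok <- 0L
  for (s in 1:50) {
    cfg <- sim_config(n_genes = 60, bulk_n_samples = 600, bulk_n_datasets = 1,
                      planted_pairs = default_planted_pairs(60, 13),
                      n_decoy_markers = 0, batch_shift_sd = 0, batch_scale_sd = 0, seed = 200L + s)
    co <- simulate_bulk_cohort(cfg)$cohort
    pm <- expand.grid(up_gene = cfg$planted_pairs$up_gene,
                      down_gene = cfg$planted_pairs$down_gene,
                      stringsAsFactors = FALSE)  # planted plus all cross pairs
    m <- suppressWarnings(select_pairs(score_pairs(co, pm), 13))
    if (count_recovered(m$pairs, cfg$planted_pairs) >= 10) ok <- ok + 1L
  }
  expect_gte(ok, 45L)
})
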