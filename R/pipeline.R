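#' Pipeline configuration
#'
#' Validates every knob of the end-to-end analysis before any computation.
#' Two input modes: `sim` (a [sim_config()]; the generator supplies single
#' cells, bulk cohort and survival) or `files` (paths to a single-cell matrix
#' and one or more bulk dataset TSV pairs).
#'
#' @param sim a [sim_config()] (simulate mode) or `NULL`.
#' @param files list for file mode: `sc_counts`, `sc_cells`, optional
#'   `sc_genes`, and `datasets` = list of `list(expr =, meta =, log2 =)`.
#' @param marker_clusters clusters whose markers seed the mechanism; `NULL`
#'   (simulate mode) uses the clusters carrying planted markers.
#' @param n_top markers of each sign per cluster for the mechanism.
#' @param fdr_max marker significance gate.
#' @param logfc_min,min_pct hurdle prefilter thresholds.
#' @param train_frac training fraction of the stratified split.
#' @param strata_vars stratification variables.
#' @param k signature size; `NULL` selects k by cross-validation.
#' @param k_grid,folds grid of odd k and fold count for [choose_k()].
#' @param tie_policy prediction tie rule (see [select_pairs()]).
#' @param logistic_penalty L2 penalty of the probability-scoring model.
#' @param out_dir output directory, or `NULL` for no files.
#' @param seed master seed; derives the simulation, split and CV seeds.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), files = NULL,
                            marker_clusters = NULL, n_top = 100,
                            fdr_max = 0.05, logfc_min = 0.25, min_pct = 0.10,
                            train_frac = 0.75,
                            strata_vars = c("dataset", "gleason", "age",
                                            "psa", "stage"),
                            k = 13L, k_grid = seq(3L, 25L, by = 2L),
                            folds = 5L, tie_policy = "met",
                            logistic_penalty = 0, out_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(files)) stop("provide either sim or files")
  if (!is.null(files)) {
    needed <- c("sc_counts", "sc_cells", "datasets")
    miss <- setdiff(needed, names(files))
    if (length(miss)) stop("files mode needs: ", paste(miss, collapse = ", "))
    if (is.null(marker_clusters)) {
      stop("files mode requires explicit marker_clusters")
    }
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  if (n_top < 1) stop("n_top must be >= 1")
  if (!is.null(k) && k < 1) stop("k must be >= 1")
  if (fdr_max <= 0 || fdr_max > 1) stop("fdr_max must be in (0, 1]")
  if (logistic_penalty < 0) stop("logistic_penalty must be >= 0")
  structure(list(sim = sim, files = files, marker_clusters = marker_clusters,
                 n_top = n_top, fdr_max = fdr_max, logfc_min = logfc_min,
                 min_pct = min_pct, train_frac = train_frac,
                 strata_vars = strata_vars, k = k, k_grid = k_grid,
                 folds = folds, tie_policy = tie_policy,
                 logistic_penalty = logistic_penalty, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full signature pipeline
#'
#' Simulate (or load) the inputs, rank hurdle markers per mechanism cluster,
#' build the up x down pair mechanism, harmonize the bulk datasets, split
#' stratified 75/25, quantile-normalize the partitions separately, train the
#' mechanism-constrained k-TSP classifier, and evaluate: AUROC on training and
#' held-out samples, a logistic probability score over the signature genes,
#' Kaplan-Meier curves, a log-rank test, and a Gleason-adjusted Cox model on
#' the held-out partition. Writes the signature, per-sample predictions, a
#' JSON report and a run log when `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return An `evaluation_report` list; notable elements: `auroc_train`,
#'   `auroc_test`, `model` (the `ktsp_model`), `signature` (pair table),
#'   `mechanism`, `markers`, `split` (sample ids), `logistic`, `km`,
#'   `logrank`, `cox`, `predictions`, `k`, `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }
  say("pairmet %s, R %s, seed %d",
      as.character(utils::packageVersion("pairmet")),
      paste(R.version$major, R.version$minor, sep = "."), config$seed)

  inputs <- stage("load", pipeline_inputs(config))
  sc <- inputs$sc
  cohort <- inputs$cohort
  marker_clusters <- inputs$marker_clusters
  say("inputs: %d genes x %d cells; bulk %d samples x %d genes, %d datasets",
      nrow(sc$counts), ncol(sc$counts), nrow(cohort$expr), ncol(cohort$expr),
      length(unique(cohort$meta$dataset)))

  markers <- stage("markers", {
    tabs <- lapply(marker_clusters, function(cl) {
      rank_markers(sc, cl, logfc_min = config$logfc_min,
                   min_pct = config$min_pct)
    })
    names(tabs) <- marker_clusters
    tabs
  })
  say("markers: %s",
      paste(sprintf("%s=%d", names(markers),
                    vapply(markers, nrow, integer(1))), collapse = ", "))

  mechanism <- stage("mechanism",
                     build_mechanism(markers, n_top = config$n_top,
                                     fdr_max = config$fdr_max))
  say("mechanism: %d cluster-tagged pairs, %d pooled",
      nrow(mechanism$pairs), nrow(mechanism$pooled))

  harmonized <- stage("harmonize", {
    h <- harmonize(split_by_dataset(cohort), log2_transform = inputs$log2)
    validate_meta(h$meta, required = c("sample_id", "dataset", "met_event",
                                       "gleason"))
    h
  })

  split <- stage("split",
                 stratified_split(harmonized, train_frac = config$train_frac,
                                  strata_vars = config$strata_vars,
                                  seed = config$seed + 10L))
  say("split: %d training / %d testing", nrow(split$train$expr),
      nrow(split$test$expr))

  train <- stage("quantile_normalize", quantile_normalize(split$train))
  test <- stage("quantile_normalize", quantile_normalize(split$test))

  k <- config$k
  if (is.null(k)) {
    k <- stage("choose_k",
               choose_k(train, mechanism, k_grid = config$k_grid,
                        folds = config$folds, seed = config$seed + 11L))
    say("choose_k: selected k = %d by %d-fold CV", k, config$folds)
  }

  model <- stage("train", {
    scored <- score_pairs(train, mechanism)
    select_pairs(scored, k, tie_policy = config$tie_policy)
  })
  say("model: %d pair(s)", model$k)

  pred_train <- stage("predict", predict(model, train))
  pred_test <- stage("predict", predict(model, test))
  auroc_train <- stage("evaluate",
                       auroc(pred_train$vote_fraction,
                             train$meta$met_event))
  auroc_test <- stage("evaluate",
                      auroc(pred_test$vote_fraction, test$meta$met_event))
  say("AUROC: train %.3f, test %.3f", auroc_train, auroc_test)

  genes <- signature_genes(model)
  logistic <- stage("logistic",
                    fit_logistic(train$expr[, genes, drop = FALSE],
                                 train$meta$met_event,
                                 penalty = config$logistic_penalty))
  prob_test <- logistic$predict(test$expr[, genes, drop = FALSE])
  prob_class <- as.integer(prob_test >= 0.5)

  # survival evaluation is reported when estimable; degenerate predicted
  # classes, no events, or a monotone Cox likelihood (e.g. a sparse Gleason
  # level with all-or-no events in a small partition) are logged, not fatal
  km <- NULL; lr <- NULL; cox <- NULL
  if (all(c("pfs_months", "pfs_event") %in% names(test$meta))) {
    tm <- test$meta
    if (length(unique(prob_class)) == 2 && sum(tm$pfs_event) > 0) {
      km <- kaplan_meier(tm$pfs_months, tm$pfs_event, prob_class)
      lr <- logrank(tm$pfs_months, tm$pfs_event, prob_class)
      gl <- factor(tm$gleason, levels = gleason_levels())
      cox <- tryCatch(
        cox_ph(data.frame(signature = prob_class, gleason = droplevels(gl)),
               tm$pfs_months, tm$pfs_event),
        error = function(e) {
          say("Cox model not estimable: %s", conditionMessage(e))
          NULL
        })
      if (!is.null(cox)) {
        say("log-rank chi-square %.3f (p = %.3g); signature HR %.3f",
            lr$statistic, lr$p_value,
            cox$terms$hr[cox$terms$term == "signature"])
      }
    } else {
      say("survival evaluation skipped: degenerate predicted classes or no events")
    }
  }

  predictions <- data.frame(
    sample_id = c(pred_train$sample_id, pred_test$sample_id),
    partition = rep(c("train", "test"),
                    c(nrow(pred_train), nrow(pred_test))),
    vote_fraction = c(pred_train$vote_fraction, pred_test$vote_fraction),
    pred_class = c(pred_train$pred_class, pred_test$pred_class),
    met_event = c(train$meta$met_event, test$meta$met_event),
    stringsAsFactors = FALSE
  )
  predictions$prob_score <- NA_real_
  predictions$prob_score[predictions$partition == "test"] <- prob_test

  report <- structure(list(
    schema_version = "1.0", seed = config$seed, k = model$k,
    signature = model$pairs, model = model, mechanism = mechanism,
    markers = markers, truth = inputs$truth,
    split = list(train = split$train$meta$sample_id,
                 test = split$test$meta$sample_id),
    auroc_train = auroc_train, auroc_test = auroc_test,
    logistic = list(coefficients = logistic$coefficients),
    km = km, logrank = lr, cox = cox, predictions = predictions,
    log = log_lines
  ), class = "evaluation_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

pipeline_inputs <- function(config) {
  if (!is.null(config$files)) {
    f <- config$files
    sc <- read_sc_matrix(f$sc_counts, f$sc_cells, f$sc_genes)
    datasets <- lapply(f$datasets, function(d) {
      read_bulk_cohort(d$expr, d$meta)
    })
    log2 <- vapply(f$datasets, function(d) isTRUE(d$log2), logical(1))
    cohort <- if (length(datasets) == 1) datasets[[1]] else {
      # concatenate; harmonize() re-splits by the dataset column
      expr <- do.call(rbind, lapply(datasets, `[[`, "expr"))
      meta <- do.call(rbind, lapply(datasets, `[[`, "meta"))
      bulk_cohort(expr, meta)
    }
    # per-dataset log2 flags are applied dataset-wise downstream
    names(log2) <- vapply(datasets, function(d) d$meta$dataset[1], character(1))
    return(list(sc = sc, cohort = cohort, truth = NULL,
                marker_clusters = config$marker_clusters,
                log2 = log2[unique(cohort$meta$dataset)]))
  }
  scfg <- config$sim
  scfg$seed <- config$seed
  sc_out <- simulate_single_cell(scfg)
  bulk <- simulate_bulk_cohort(scfg)
  cohort <- simulate_survival(bulk$cohort, scfg)
  marker_clusters <- config$marker_clusters
  if (is.null(marker_clusters)) {
    marker_clusters <- unique(scfg$planted_markers$cluster)
  }
  if (length(marker_clusters) == 0) stop("no marker clusters configured")
  list(sc = sc_out$sc, cohort = cohort,
       truth = list(sc = sc_out$truth, bulk = bulk$truth),
       marker_clusters = marker_clusters, log2 = FALSE)
}

#' Write pipeline outputs
#'
#' @param report an `evaluation_report` from [run_pipeline()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(dir, "signature.tsv")
  utils::write.table(report$signature, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pp <- file.path(dir, "predictions.tsv")
  utils::write.table(report$predictions, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rp <- file.path(dir, "report.json")
  json <- list(
    schema_version = report$schema_version, seed = report$seed, k = report$k,
    signature = report$signature, auroc_train = report$auroc_train,
    auroc_test = report$auroc_test,
    logistic_coefficients = as.list(report$logistic$coefficients),
    logrank = report$logrank,
    cox = if (!is.null(report$cox)) report$cox$terms,
    n_train = length(report$split$train), n_test = length(report$split$test)
  )
  jsonlite::write_json(json, rp, auto_unbox = TRUE, digits = NA, null = "null")
  lp <- file.path(dir, "run.log")
  writeLines(report$log, lp)
  invisible(c(signature = sp, predictions = pp, report = rp, log = lp))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> k = %d pairs (%d genes)\n", x$k,
              length(unique(c(x$signature$up_gene, x$signature$down_gene)))))
  cat(sprintf("  AUROC train %.3f / test %.3f\n", x$auroc_train,
              x$auroc_test))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank chi-square %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
  }
  if (!is.null(x$cox)) {
    hr <- x$cox$terms[x$cox$terms$term == "signature", ]
    cat(sprintf("  Gleason-adjusted signature HR %.3f [%.3f, %.3f]\n",
                hr$hr, hr$ci_lower, hr$ci_upper))
  }
  invisible(x)
}
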