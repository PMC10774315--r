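#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: a single-cell
#' negative-binomial/dropout matrix with planted cluster markers, a
#' multi-dataset bulk cohort with planted rank-inverting gene pairs, batch
#' location/scale effects and clinical covariates, and exponential
#' progression-free-survival with independent censoring.
#'
#' Defaults describe the study conditions used throughout the package's tests:
#' 2,000 genes, three marker-bearing mesenchymal clusters plus a background
#' cluster, 13 planted pairs with per-class inversion probabilities 0.65/0.35,
#' a 600-sample three-dataset bulk cohort with balanced metastasis prevalence,
#' and months-scale exponential survival.
#'
#' Planted pairs carry correlated within-pair noise (`pair_noise_cor`): each
#' pair models a tightly co-regulated gene pair, so the inversion signal is a
#' property of the pair rather than of either gene's marginal class
#' difference. The pair offset that achieves a target inversion probability
#' `t` is `delta = sqrt(2 * (1 - pair_noise_cor)) * bulk_noise_sd * qnorm(t)`
#' (probit closed form; `pair_noise_cor = 0` gives the familiar
#' `sqrt(2) * sigma * qnorm(t)`).
#'
#' @param n_genes number of genes in both the single-cell and bulk universes.
#' @param clusters named integer vector of cells per cluster (>= 2 clusters,
#'   >= 20 cells each).
#' @param planted_pairs data.frame with columns `up_gene`, `down_gene`; or
#'   `NULL` for no planted pairs.
#' @param planted_markers data.frame with columns `cluster`, `gene`, `logfc`
#'   (natural-log fold effect on the NB mean in that cluster). `NULL` wires a
#'   default: each planted pair's up/down genes become +/-`marker_logfc`
#'   markers of one of the first three clusters (round-robin), plus
#'   `n_decoy_markers` positive and negative decoy markers per cluster with no
#'   bulk signal.
#' @param marker_logfc,n_decoy_markers defaults used by the wiring above.
#' @param nb_dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2), shared across genes.
#' @param dropout_rate probability that a count is zeroed by dropout.
#' @param sc_mean_meanlog,sc_mean_sdlog lognormal hyper-parameters of gene
#'   base means; `sc_marker_mean` fixes marker-gene base means so markers are
#'   detectable.
#' @param bulk_n_samples,bulk_n_datasets bulk cohort size and number of
#'   batches (datasets).
#' @param met_prevalence probability of a metastatic event label, in (0, 1).
#' @param inversion_prob_met,inversion_prob_nonmet target per-pair
#'   P(up > down) in metastatic / non-metastatic samples.
#' @param pair_noise_cor within-pair noise correlation in [0, 1).
#' @param bulk_noise_sd Gaussian noise sd of log-scale bulk expression.
#' @param batch_shift_sd sd of the per-dataset per-gene additive shift.
#' @param batch_scale_sd sdlog of the per-dataset per-gene lognormal scale.
#' @param gleason_probs base probabilities of Gleason categories
#'   `<=6, 7, 8, 9, 10`.
#' @param gleason_met_lor log-odds tilt per Gleason step applied to metastatic
#'   samples, inducing the Gleason-metastasis correlation.
#' @param surv_baseline_rate baseline hazard, events per month.
#' @param surv_log_hr_signature,surv_log_hr_gleason log hazard ratios of the
#'   metastasis label and of one Gleason step.
#' @param censor_rate rate of the independent exponential censoring process
#'   (0 means no censoring).
#' @param seed integer seed; fixed seed gives bitwise-identical output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       clusters = c(prn1 = 250, prn2 = 250, prn3 = 250,
                                    other = 750),
                       planted_pairs = default_planted_pairs(n_genes),
                       planted_markers = NULL,
                       marker_logfc = 1.2,
                       n_decoy_markers = 6,
                       nb_dispersion = 0.5,
                       dropout_rate = 0.3,
                       sc_mean_meanlog = -0.5,
                       sc_mean_sdlog = 1.2,
                       sc_marker_mean = 3,
                       bulk_n_samples = 600,
                       bulk_n_datasets = 3,
                       met_prevalence = 0.5,
                       inversion_prob_met = 0.65,
                       inversion_prob_nonmet = 0.35,
                       pair_noise_cor = 0.9,
                       bulk_noise_sd = 1,
                       batch_shift_sd = 0.4,
                       batch_scale_sd = 0.2,
                       gleason_probs = c(0.25, 0.40, 0.20, 0.10, 0.05),
                       gleason_met_lor = 0.5,
                       surv_baseline_rate = 0.02,
                       surv_log_hr_signature = log(2),
                       surv_log_hr_gleason = 0.3,
                       censor_rate = 0.015,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), clusters = clusters,
    planted_pairs = planted_pairs, planted_markers = planted_markers,
    marker_logfc = marker_logfc, n_decoy_markers = as.integer(n_decoy_markers),
    nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
    sc_mean_meanlog = sc_mean_meanlog, sc_mean_sdlog = sc_mean_sdlog,
    sc_marker_mean = sc_marker_mean,
    bulk_n_samples = as.integer(bulk_n_samples),
    bulk_n_datasets = as.integer(bulk_n_datasets),
    met_prevalence = met_prevalence,
    inversion_prob_met = inversion_prob_met,
    inversion_prob_nonmet = inversion_prob_nonmet,
    pair_noise_cor = pair_noise_cor, bulk_noise_sd = bulk_noise_sd,
    batch_shift_sd = batch_shift_sd, batch_scale_sd = batch_scale_sd,
    gleason_probs = gleason_probs, gleason_met_lor = gleason_met_lor,
    surv_baseline_rate = surv_baseline_rate,
    surv_log_hr_signature = surv_log_hr_signature,
    surv_log_hr_gleason = surv_log_hr_gleason,
    censor_rate = censor_rate, seed = as.integer(seed)
  )
  if (is.null(cfg$planted_markers)) {
    cfg$planted_markers <- default_planted_markers(cfg)
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Gene identifiers of the simulated universe
#' @param n_genes number of genes.
#' @return Character vector `g0001`, `g0002`, ...
#' @export
sim_gene_ids <- function(n_genes) {
  sprintf(paste0("g%0", max(4L, nchar(as.character(n_genes))), "d"),
          seq_len(n_genes))
}

#' Default set of 13 planted rank-inverting pairs
#' @param n_genes number of genes available (needs >= 26).
#' @param n_pairs number of pairs to plant.
#' @return data.frame with `up_gene`, `down_gene`.
#' @export
default_planted_pairs <- function(n_genes, n_pairs = 13) {
  ids <- sim_gene_ids(n_genes)
  if (n_genes < 2 * n_pairs) stop("need at least ", 2 * n_pairs, " genes")
  data.frame(up_gene = ids[seq_len(n_pairs)],
             down_gene = ids[n_pairs + seq_len(n_pairs)],
             stringsAsFactors = FALSE)
}

# Wire planted pairs into cluster markers: up genes as positive and down genes
# as negative markers of the first three clusters (round-robin), plus decoy
# markers that carry no bulk signal so the mechanism contains null pairs too.
default_planted_markers <- function(cfg) {
  ids <- sim_gene_ids(cfg$n_genes)
  mcl <- names(cfg$clusters)[seq_len(min(3L, length(cfg$clusters)))]
  out <- list()
  if (!is.null(cfg$planted_pairs) && nrow(cfg$planted_pairs) > 0) {
    np <- nrow(cfg$planted_pairs)
    cl <- mcl[((seq_len(np) - 1L) %% length(mcl)) + 1L]
    out$pairs_up <- data.frame(cluster = cl, gene = cfg$planted_pairs$up_gene,
                               logfc = cfg$marker_logfc,
                               stringsAsFactors = FALSE)
    out$pairs_dn <- data.frame(cluster = cl, gene = cfg$planted_pairs$down_gene,
                               logfc = -cfg$marker_logfc,
                               stringsAsFactors = FALSE)
  }
  used <- unique(c(cfg$planted_pairs$up_gene, cfg$planted_pairs$down_gene))
  free <- setdiff(ids, used)
  nd <- cfg$n_decoy_markers
  if (nd > 0) {
    need <- 2L * nd * length(mcl)
    if (length(free) < need) stop("not enough genes for decoy markers")
    dg <- free[seq_len(need)]
    out$decoys <- data.frame(
      cluster = rep(mcl, each = 2L * nd),
      gene = dg,
      logfc = rep(rep(c(cfg$marker_logfc, -cfg$marker_logfc), each = nd),
                  times = length(mcl)),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(cluster = character(), gene = character(),
                      logfc = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, unname(out))
}

validate_sim_config <- function(cfg) {
  probs <- c(dropout = cfg$dropout_rate, met = cfg$met_prevalence,
             inv_met = cfg$inversion_prob_met,
             inv_non = cfg$inversion_prob_nonmet)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$inversion_prob_met < cfg$inversion_prob_nonmet) {
    stop("inversion_prob_met must be >= inversion_prob_nonmet")
  }
  if (cfg$pair_noise_cor < 0 || cfg$pair_noise_cor >= 1) {
    stop("pair_noise_cor must lie in [0, 1)")
  }
  if (cfg$n_genes < 1 || cfg$nb_dispersion <= 0 || cfg$bulk_noise_sd <= 0) {
    stop("n_genes, nb_dispersion and bulk_noise_sd must be positive")
  }
  if (cfg$batch_shift_sd < 0 || cfg$batch_scale_sd < 0) {
    stop("batch sds must be non-negative")
  }
  if (cfg$bulk_n_datasets < 1) stop("need at least one bulk dataset")
  if (length(cfg$gleason_probs) != 5 || any(cfg$gleason_probs < 0)) {
    stop("gleason_probs must be 5 non-negative weights")
  }
  ids <- sim_gene_ids(cfg$n_genes)
  planted <- c(cfg$planted_markers$gene,
               cfg$planted_pairs$up_gene, cfg$planted_pairs$down_gene)
  if (length(planted) && !all(planted %in% ids)) {
    stop("configuration error: planted gene outside the simulated universe")
  }
  if (!is.null(cfg$planted_pairs) && nrow(cfg$planted_pairs) > 0 &&
      any(cfg$planted_pairs$up_gene == cfg$planted_pairs$down_gene)) {
    stop("planted pair genes must be distinct")
  }
  invisible(cfg)
}

gleason_levels <- function() c("<=6", "7", "8", "9", "10")

#' Simulate a single-cell count matrix with planted cluster markers
#'
#' Counts are negative-binomial with a shared dispersion and multiplicative
#' Bernoulli dropout, the simplest generative law exhibiting the zero
#' inflation and bimodality the hurdle model assumes. A planted marker shifts
#' the NB log-mean of its gene in its cluster by `logfc`.
#'
#' @param config a [sim_config()].
#' @return list with `sc` (an [sc_matrix()]) and `truth` (planted markers,
#'   planted pairs, realized gene base means, seed).
#' @export
simulate_single_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$clusters
  if (length(cl) < 2) stop("need >= 2 clusters")
  if (any(cl < 20)) stop("each cluster needs >= 20 cells")
  set.seed(config$seed)
  ids <- sim_gene_ids(config$n_genes)
  mu <- stats::rlnorm(config$n_genes, config$sc_mean_meanlog,
                      config$sc_mean_sdlog)
  names(mu) <- ids
  pm <- config$planted_markers
  if (nrow(pm) > 0) mu[unique(pm$gene)] <- config$sc_marker_mean
  size <- 1 / config$nb_dispersion
  blocks <- lapply(names(cl), function(cn) {
    m <- mu
    sel <- pm$cluster == cn
    if (any(sel)) m[pm$gene[sel]] <- m[pm$gene[sel]] * exp(pm$logfc[sel])
    nc <- cl[[cn]]
    x <- matrix(stats::rnbinom(config$n_genes * nc, mu = m, size = size),
                nrow = config$n_genes)
    keep <- matrix(stats::rbinom(config$n_genes * nc, 1L,
                                 1 - config$dropout_rate),
                   nrow = config$n_genes)
    x * keep
  })
  counts <- do.call(cbind, blocks)
  labels <- rep(names(cl), times = cl)
  sc <- sc_matrix(counts, gene_ids = ids,
                  cell_ids = sprintf("c%05d", seq_len(ncol(counts))),
                  cluster_labels = labels)
  truth <- list(markers = pm, pairs = config$planted_pairs,
                base_means = mu, seed = config$seed)
  list(sc = sc, truth = truth)
}

#' Simulate a harmonizable multi-dataset bulk cohort
#'
#' Log-scale Gaussian expression with per-dataset per-gene location/scale
#' batch effects (removable by per-dataset gene-wise z-scoring) and clinical
#' metadata: dataset, metastasis label, Gleason grade (correlated with
#' metastasis through `gleason_met_lor`), age, PSA and stage. Each planted
#' pair receives a class-dependent offset calibrated on the probit scale so
#' that P(up > down) equals `inversion_prob_met` in metastatic and
#' `inversion_prob_nonmet` in non-metastatic samples.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (a [bulk_cohort()]) and `truth` (planted pairs
#'   with realized per-class offsets, seed).
#' @export
simulate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$met_prevalence <= 0 || config$met_prevalence >= 1) {
    stop("degenerate cohort: met_prevalence must lie strictly in (0, 1)")
  }
  set.seed(config$seed + 1L)
  n <- config$bulk_n_samples
  g <- config$n_genes
  ids <- sim_gene_ids(g)
  sigma <- config$bulk_noise_sd

  met <- stats::rbinom(n, 1L, config$met_prevalence)
  glev <- gleason_levels()
  gleason <- vapply(met, function(m) {
    w <- config$gleason_probs * exp(config$gleason_met_lor * (0:4) * m)
    sample(glev, 1L, prob = w / sum(w))
  }, character(1))
  age <- round(stats::rnorm(n, 65, 8))
  psa <- round(stats::rlnorm(n, log(8), 0.7), 1)
  stage <- sample(c("T2", "T3", "T4"), n, replace = TRUE,
                  prob = c(0.5, 0.4, 0.1))
  dataset <- paste0("ds", ((seq_len(n) - 1L) %% config$bulk_n_datasets) + 1L)

  base <- stats::rnorm(g, 0, 1)
  expr <- matrix(stats::rnorm(n * g, 0, sigma), nrow = n) +
    matrix(base, nrow = n, ncol = g, byrow = TRUE)
  colnames(expr) <- ids

  pp <- config$planted_pairs
  truth_pairs <- NULL
  if (!is.null(pp) && nrow(pp) > 0) {
    rho <- config$pair_noise_cor
    d_met <- sqrt(2 * (1 - rho)) * sigma * stats::qnorm(config$inversion_prob_met)
    d_non <- sqrt(2 * (1 - rho)) * sigma *
      stats::qnorm(config$inversion_prob_nonmet)
    delta <- ifelse(met == 1L, d_met, d_non)
    for (i in seq_len(nrow(pp))) {
      z <- stats::rnorm(n)
      eu <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      ed <- sqrt(rho) * z + sqrt(1 - rho) * stats::rnorm(n)
      # a pair models two co-regulated genes: shared baseline, so the class
      # offset delta alone sets P(up > down)
      bshare <- mean(base[match(c(pp$up_gene[i], pp$down_gene[i]), ids)])
      expr[, pp$up_gene[i]] <- bshare + delta / 2 + sigma * eu
      expr[, pp$down_gene[i]] <- bshare - delta / 2 + sigma * ed
    }
    truth_pairs <- cbind(pp, delta_met = d_met, delta_nonmet = d_non)
  }

  for (d in unique(dataset)) {
    rows <- dataset == d
    shift <- stats::rnorm(g, 0, config$batch_shift_sd)
    scale <- exp(stats::rnorm(g, 0, config$batch_scale_sd))
    expr[rows, ] <- sweep(sweep(expr[rows, , drop = FALSE], 2, scale, `*`),
                          2, shift, `+`)
  }

  meta <- data.frame(
    sample_id = sprintf("s%05d", seq_len(n)), dataset = dataset,
    met_event = met, gleason = gleason, age = age, psa = psa, stage = stage,
    stringsAsFactors = FALSE
  )
  rownames(expr) <- meta$sample_id
  truth <- list(pairs = truth_pairs, markers = config$planted_markers,
                seed = config$seed)
  list(cohort = bulk_cohort(expr, meta), truth = truth)
}

#' Attach exponential progression-free survival to a cohort
#'
#' Event times are exponential with hazard
#' `surv_baseline_rate * exp(beta * met + gamma * gleason_step)` (months);
#' censoring is an independent exponential with rate `censor_rate`.
#'
#' @param cohort a [bulk_cohort()] with `met_event` and `gleason` metadata.
#' @param config a [sim_config()].
#' @return The cohort with `pfs_months` and `pfs_event` metadata columns.
#' @export
simulate_survival <- function(cohort, config) {
  stopifnot(inherits(cohort, "bulk_cohort"), inherits(config, "sim_config"))
  if (config$surv_baseline_rate <= 0) {
    stop("configuration error: surv_baseline_rate must be positive")
  }
  if (!all(c("met_event", "gleason") %in% names(cohort$meta))) {
    stop("cohort needs met_event and gleason metadata")
  }
  set.seed(config$seed + 2L)
  n <- nrow(cohort$meta)
  gscore <- match(cohort$meta$gleason, gleason_levels()) - 1L
  rate <- config$surv_baseline_rate *
    exp(config$surv_log_hr_signature * cohort$meta$met_event +
        config$surv_log_hr_gleason * gscore)
  tt <- stats::rexp(n, rate)
  cc <- if (config$censor_rate <= 0) rep(Inf, n) else
    stats::rexp(n, config$censor_rate)
  cohort$meta$pfs_months <- pmin(tt, cc)
  cohort$meta$pfs_event <- as.integer(tt <= cc)
  cohort
}
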