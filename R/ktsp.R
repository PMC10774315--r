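# Mechanism-constrained k-top-scoring-pairs classifier. Every statistic here
# depends on the data only through within-sample orderings, so any strictly
# increasing per-sample transform of expression leaves scores, votes and
# predictions unchanged.

pair_votes <- function(expr, up, down) {
  u <- expr[, up, drop = FALSE]
  d <- expr[, down, drop = FALSE]
  (u > d) + 0.5 * (u == d)
}

#' Score candidate pairs on a training cohort
#'
#' For each mechanism pair, the primary score is
#' `delta = P(up > down | metastatic) - P(up > down | non-metastatic)`
#' from empirical within-class frequencies (exact expression ties count one
#' half). The secondary tie-break score `gamma` is the absolute difference
#' between classes of the mean within-sample rank difference
#' `rank(up) - rank(down)` (ranks taken across all genes in the cohort,
#' midranks for ties). Pairs outside the mechanism are never scored.
#'
#' @param train a [bulk_cohort()] with both outcome classes present.
#' @param mechanism a [build_mechanism()] result, or a data.frame with
#'   `up_gene`, `down_gene` columns.
#' @param class_var metadata column holding the binary outcome (1 = positive
#'   class).
#' @return data.frame of class `scored_pairs` with `up_gene`, `down_gene`,
#'   `delta`, `gamma`, sorted by `delta` desc, `gamma` desc, then gene ids.
#' @export
score_pairs <- function(train, mechanism, class_var = "met_event") {
  stopifnot(inherits(train, "bulk_cohort"))
  pairs <- if (inherits(mechanism, "mechanism_pairs")) mechanism$pooled
           else as.data.frame(mechanism, stringsAsFactors = FALSE)
  if (!all(c("up_gene", "down_gene") %in% names(pairs))) {
    stop("mechanism must provide up_gene and down_gene")
  }
  y <- train$meta[[class_var]]
  if (is.null(y)) stop("class column '", class_var, "' absent from metadata")
  y <- as.integer(y)
  if (length(unique(y)) != 2 || !all(y %in% 0:1)) {
    stop("both outcome classes (0/1) must be present")
  }
  present <- pairs$up_gene %in% train$genes & pairs$down_gene %in% train$genes
  if (!all(present)) {
    warning(sum(!present), " pair(s) dropped: gene(s) absent from the cohort")
    pairs <- pairs[present, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no scorable pairs remain")

  votes <- pair_votes(train$expr, pairs$up_gene, pairs$down_gene)
  pos <- y == 1
  p_met <- colMeans(votes[pos, , drop = FALSE])
  p_non <- colMeans(votes[!pos, , drop = FALSE])

  ranks <- t(apply(train$expr, 1, rank))
  colnames(ranks) <- colnames(train$expr)
  rd <- ranks[, pairs$up_gene, drop = FALSE] -
    ranks[, pairs$down_gene, drop = FALSE]
  gamma <- abs(colMeans(rd[pos, , drop = FALSE]) -
                 colMeans(rd[!pos, , drop = FALSE]))

  out <- data.frame(up_gene = pairs$up_gene, down_gene = pairs$down_gene,
                    delta = unname(p_met - p_non), gamma = unname(gamma),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$delta, -out$gamma, out$up_gene, out$down_gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("scored_pairs", "data.frame")
  out
}

#' Select k gene-disjoint top-scoring pairs
#'
#' Greedy scan in order of (`delta` desc, `gamma` desc, lexicographic gene
#' ids), skipping any pair sharing a gene with an already selected pair, until
#' `k` pairs are found or candidates are exhausted. Pairs with `delta <= 0`
#' are discarded first: the mechanism fixes the expected orientation in
#' metastatic samples, so only positively scoring pairs are admissible.
#'
#' @param scored a [score_pairs()] result.
#' @param k requested number of pairs (the classical choice is odd).
#' @param tie_policy prediction tie rule stored in the model: `"met"`
#'   classifies a 0.5 vote fraction as metastatic (sensitivity-favoring
#'   default), `"nonmet"` the opposite.
#' @return An object of class `ktsp_model`: list with `pairs` (ordered
#'   data.frame), `k` (pairs actually selected), `tie_policy`.
#' @export
select_pairs <- function(scored, k, tie_policy = c("met", "nonmet")) {
  tie_policy <- match.arg(tie_policy)
  if (k < 1) stop("k must be >= 1")
  cand <- scored[scored$delta > 0, , drop = FALSE]
  cand <- cand[order(-cand$delta, -cand$gamma, cand$up_gene, cand$down_gene), ,
               drop = FALSE]
  used <- character(0)
  take <- integer(0)
  for (i in seq_len(nrow(cand))) {
    g <- c(cand$up_gene[i], cand$down_gene[i])
    if (any(g %in% used)) next
    take <- c(take, i)
    used <- c(used, g)
    if (length(take) == k) break
  }
  if (length(take) < k) {
    warning("only ", length(take), " gene-disjoint pair(s) available (k = ",
            k, " requested)")
  }
  pairs <- cand[take, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, k = nrow(pairs), tie_policy = tie_policy),
            class = "ktsp_model")
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("<ktsp_model> %d gene pair(s), %d unique genes\n",
              x$k, length(unique(c(x$pairs$up_gene, x$pairs$down_gene)))))
  print(utils::head(x$pairs, 10))
  invisible(x)
}

#' Genes used by a k-TSP model
#' @param model a [select_pairs()] model.
#' @return Character vector of the 2k genes (up genes first).
#' @export
signature_genes <- function(model) {
  stopifnot(inherits(model, "ktsp_model"))
  unique(c(model$pairs$up_gene, model$pairs$down_gene))
}

#' Predict metastasis by majority vote
#'
#' Each pair votes 1 if `expr(up) > expr(down)`, 0 if `<`, and 0.5 on an exact
#' tie; the vote fraction is the mean vote and the predicted class is
#' metastatic iff the vote fraction is `>= 0.5` (or `> 0.5` under the
#' `"nonmet"` tie policy).
#'
#' @param object a `ktsp_model`.
#' @param cohort a [bulk_cohort()] containing every model gene.
#' @param ... unused.
#' @return data.frame with `sample_id`, `vote_fraction` in \[0, 1\], and
#'   `pred_class` (0/1).
#' @export
predict.ktsp_model <- function(object, cohort, ...) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  genes <- unique(c(object$pairs$up_gene, object$pairs$down_gene))
  missing_genes <- setdiff(genes, cohort$genes)
  if (length(missing_genes)) {
    stop("model gene(s) missing from cohort: ",
         paste(missing_genes, collapse = ", "))
  }
  votes <- pair_votes(cohort$expr, object$pairs$up_gene,
                      object$pairs$down_gene)
  vf <- rowMeans(votes)
  cls <- if (object$tie_policy == "met") as.integer(vf >= 0.5)
         else as.integer(vf > 0.5)
  data.frame(sample_id = cohort$meta$sample_id, vote_fraction = unname(vf),
             pred_class = cls, stringsAsFactors = FALSE)
}

make_stratified_folds <- function(y, folds, seed) {
  for (attempt in seq_len(10L)) {
    set.seed(seed + attempt - 1L)
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(y[fold == f])) == 2 && length(unique(y[fold != f])) == 2
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build folds containing both classes in 10 attempts")
}

#' Choose k by stratified cross-validation
#'
#' For each odd `k` in the grid, pairs are scored and greedily selected on
#' each training fold and the vote-fraction score is evaluated by AUROC on the
#' held fold; the smallest `k` attaining the maximal mean AUROC is returned.
#' Fold models for smaller `k` are prefixes of the largest-`k` model, so
#' scoring happens once per fold.
#'
#' @param train a [bulk_cohort()].
#' @param mechanism candidate pair set.
#' @param k_grid odd integers to try.
#' @param folds number of CV folds (>= 2).
#' @param seed integer seed for fold assignment.
#' @param class_var binary outcome column.
#' @return The chosen `k` (integer).
#' @export
choose_k <- function(train, mechanism, k_grid = seq(3L, 25L, by = 2L),
                     folds = 5L, seed = 1L, class_var = "met_event") {
  if (length(k_grid) == 0) stop("k_grid must be non-empty")
  if (any(k_grid %% 2 == 0)) stop("k_grid must contain odd integers only")
  if (folds < 2) stop("folds must be >= 2")
  y <- as.integer(train$meta[[class_var]])
  fold <- make_stratified_folds(y, folds, seed)
  kmax <- max(k_grid)
  auc <- matrix(NA_real_, nrow = folds, ncol = length(k_grid))
  for (f in seq_len(folds)) {
    tr <- subset_cohort(train, fold != f)
    te <- subset_cohort(train, fold == f)
    scored <- score_pairs(tr, mechanism, class_var)
    model <- suppressWarnings(select_pairs(scored, kmax))
    if (model$k == 0) next
    votes <- pair_votes(te$expr, model$pairs$up_gene, model$pairs$down_gene)
    yte <- as.integer(te$meta[[class_var]])
    for (j in seq_along(k_grid)) {
      kk <- min(k_grid[j], model$k)
      vf <- rowMeans(votes[, seq_len(kk), drop = FALSE])
      auc[f, j] <- auroc(vf, yte)
    }
  }
  mean_auc <- colMeans(auc, na.rm = TRUE)
  if (all(is.na(mean_auc))) stop("no fold produced a usable model")
  best <- as.integer(k_grid[which(mean_auc == max(mean_auc, na.rm = TRUE))[1]])
  # forced choice: never return more than the disjoint supply of the full set
  full <- suppressWarnings(select_pairs(score_pairs(train, mechanism,
                                                    class_var), kmax))
  min(best, full$k)
}
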