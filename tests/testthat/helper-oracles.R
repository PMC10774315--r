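# Independent oracles and fixture builders. Every oracle here recomputes the
# target quantity from first principles (explicit loops, stats::glm/lm fits,
# grid search) and never calls the implementation under test.

# Two-part hurdle LRT via independent glm (detection) + lm (continuous) fits.
oracle_two_part <- function(expr, group) {
  det <- as.integer(expr > 0)
  g1 <- stats::glm(det ~ group, family = binomial(),
                   control = glm.control(epsilon = 1e-12))
  g0 <- stats::glm(det ~ 1, family = binomial())
  lrt <- as.numeric(2 * (logLik(g1) - logLik(g0)))
  detect_coef <- unname(coef(g1)[2])
  cont_coef <- NA_real_
  df <- 1L
  sel <- det == 1
  if (length(unique(group[sel])) == 2) {
    y <- expr[sel]; g <- group[sel]
    l1 <- stats::lm(y ~ g)
    l0 <- stats::lm(y ~ 1)
    lrt <- lrt + as.numeric(2 * (logLik(l1) - logLik(l0)))
    cont_coef <- unname(coef(l1)[2])
    df <- 2L
  }
  list(lrt = lrt, detect_coef = detect_coef, cont_coef = cont_coef, df = df,
       p = pchisq(lrt, df, lower.tail = FALSE))
}

# AUROC by explicit pair counting (ties count one half).
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# delta and gamma of one pair by explicit per-sample loops.
brute_delta_gamma <- function(expr, y, up, down) {
  vote <- numeric(nrow(expr))
  rdiff <- numeric(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    u <- expr[i, up]; d <- expr[i, down]
    vote[i] <- if (u > d) 1 else if (u < d) 0 else 0.5
    r <- rank(expr[i, ])
    rdiff[i] <- r[[up]] - r[[down]]
  }
  list(delta = mean(vote[y == 1]) - mean(vote[y == 0]),
       gamma = abs(mean(rdiff[y == 1]) - mean(rdiff[y == 0])))
}

# Exhaustive disjoint-subset search: every gene-disjoint subset of at most k
# pairs that is either of size k or not extendable, compared by the
# lexicographic order of its (delta desc, gamma desc, up, down) sequence.
exhaustive_ktsp <- function(scored, k) {
  scored <- scored[scored$delta > 0, , drop = FALSE]
  scored <- scored[order(-scored$delta, -scored$gamma, scored$up_gene,
                         scored$down_gene), , drop = FALSE]
  n <- nrow(scored)
  best <- NULL
  key <- function(idx) idx  # row order already encodes the sort key
  lex_greater <- function(a, b) {
    # smaller row index = better pair; prefix-longer wins
    la <- length(a); lb <- length(b)
    for (i in seq_len(min(la, lb))) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    la > lb
  }
  compatible <- function(idx, j) {
    g <- c(scored$up_gene[idx], scored$down_gene[idx])
    !(scored$up_gene[j] %in% g || scored$down_gene[j] %in% g)
  }
  recurse <- function(start, chosen) {
    extendable <- FALSE
    if (length(chosen) < k && start <= n) {
      for (j in start:n) {
        if (compatible(chosen, j)) {
          extendable <- TRUE
          recurse(j + 1L, c(chosen, j))
        }
      }
    }
    if (!extendable || length(chosen) == k) {
      if (length(chosen) > 0 &&
          (is.null(best) || lex_greater(chosen, best))) {
        best <<- chosen
      }
    }
    invisible(NULL)
  }
  recurse(1L, integer(0))
  scored[best, , drop = FALSE]
}

# Cox partial log likelihood for a single covariate, no ties (Breslow = Efron
# when event times are unique), maximized by golden-section search.
cox_grid_beta <- function(times, events, x) {
  pl <- function(beta) {
    ll <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(pl, interval = c(-10, 10), maximum = TRUE,
                  tol = 1e-9)$maximum
}

# Two-group log-rank statistic from the observed-minus-expected formula.
logrank_oe <- function(times, events, group) {
  g <- as.integer(factor(group)) - 1L
  ev_times <- sort(unique(times[events == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Marker table with the given numbers of significant positive and negative
# markers (descending magnitude), suitable as build_mechanism() input.
make_marker_table <- function(cluster, n_pos, n_neg, prefix = cluster,
                              fdr = 1e-6) {
  gp <- sprintf("%s_up%03d", prefix, seq_len(n_pos))
  gn <- sprintf("%s_dn%03d", prefix, seq_len(n_neg))
  data.frame(
    gene = c(gp, gn), cluster = cluster,
    avg_logfc = c(seq(2, 0.3, length.out = n_pos),
                  -seq(0.3, 2, length.out = n_neg)),
    pct_in = 0.8, pct_out = 0.2, lrt_stat = 50,
    p_value = fdr / 10, fdr = fdr, stringsAsFactors = FALSE
  )
}

# Minimal bulk cohort around a given expression matrix.
tiny_cohort <- function(expr, met, dataset = "ds1", ...) {
  n <- nrow(expr)
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("s%03d", seq_len(n))
  meta <- data.frame(sample_id = rownames(expr), dataset = dataset,
                     met_event = met, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  bulk_cohort(expr, meta)
}

# Count how many planted pairs appear (same orientation) in a signature.
count_recovered <- function(signature, truth_pairs) {
  sum(paste(signature$up_gene, signature$down_gene) %in%
        paste(truth_pairs$up_gene, truth_pairs$down_gene))
}
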