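# Evaluation statistics: AUROC, logistic probability scoring, Kaplan-Meier,
# log-rank and Gleason-adjusted Cox proportional hazards. The survival
# machinery delegates to the survival package (Efron tie correction for Cox);
# this module owns the interfaces, validation and reporting shape.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half (midrank formulation). Invariant to strictly increasing
#' transforms of the scores.
#'
#' @param scores numeric score vector (higher = more positive).
#' @param labels binary labels (1 = positive class).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# One ridge IWLS step solver for the L2-penalized logistic log-likelihood
# (intercept unpenalized).
ridge_logistic <- function(X, y, penalty, max_iter = 100, tol = 1e-10) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(penalty, p - 1)), nrow = p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    grad <- drop(crossprod(Xd, y - mu)) - pen %*% beta
    hess <- crossprod(Xd * w, Xd) + pen
    step <- solve(hess, grad)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(Xd)
  list(coefficients = beta, probabilities = stats::plogis(drop(Xd %*% beta)),
       iterations = it)
}

#' Logistic regression scoring model
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`); with `penalty > 0` an
#' L2-penalized fit (intercept unpenalized) is used instead, which also
#' resolves separable data. Perfect separation without a penalty is an error.
#'
#' @param X design matrix (samples x covariates) without intercept column;
#'   `NULL` for an intercept-only model.
#' @param y binary outcome (0/1).
#' @param penalty L2 penalty; 0 (default) requests the plain MLE.
#' @return list with `coefficients` (named, intercept first),
#'   `probabilities` in (0, 1), and `predict(newX)` closure.
#' @export
fit_logistic <- function(X, y, penalty = 0) {
  y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("y must be binary 0/1")
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != length(y)) stop("X rows must match y")
    if (nrow(X) <= ncol(X)) stop("need n > p")
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column(s) in X: ",
           paste(colnames(X)[sds == 0], collapse = ", "))
    }
  }
  if (penalty < 0) stop("penalty must be >= 0")
  if (penalty > 0) {
    fit <- ridge_logistic(if (is.null(X)) matrix(0, length(y), 0) else X,
                          y, penalty)
    coefs <- fit$coefficients
    probs <- fit$probabilities
  } else {
    dat <- data.frame(.y = y)
    form <- ".y ~ 1"
    if (!is.null(X) && ncol(X) > 0) {
      dat <- cbind(dat, as.data.frame(X))
      form <- paste(".y ~", paste(sprintf("`%s`", colnames(X)),
                                  collapse = " + "))
    }
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(stats::as.formula(form), data = dat,
                 family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    if (sep || any(abs(stats::coef(fit)) > 1e3, na.rm = TRUE)) {
      stop("perfect separation detected; refit with penalty > 0 (ridge)")
    }
    if (anyNA(stats::coef(fit))) {
      stop("collinear design: ",
           paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                 collapse = ", "))
    }
    coefs <- stats::coef(fit)
    names(coefs) <- c("(Intercept)", colnames(X))[seq_along(coefs)]
    probs <- unname(stats::fitted(fit))
  }
  list(
    coefficients = coefs,
    probabilities = probs,
    predict = function(newX) {
      eta <- coefs[1]
      if (length(coefs) > 1) {
        newX <- as.matrix(newX)[, names(coefs)[-1], drop = FALSE]
        eta <- eta + drop(newX %*% coefs[-1])
      }
      unname(stats::plogis(eta))
    }
  )
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator; censored subjects leave the risk set after their
#' time.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group group labels (one curve per level).
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
kaplan_meier <- function(times, events, group) {
  check_surv_args(times, events)
  group <- as.character(group)
  if (any(table(factor(group)) == 0) || length(group) != length(times)) {
    stop("group must match times")
  }
  levs <- unique(group)
  out <- lapply(levs, function(g) {
    sel <- group == g
    if (!any(sel)) stop("empty group: ", g)
    fit <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

check_surv_args <- function(times, events) {
  if (any(times <= 0)) stop("times must be positive")
  if (!all(events %in% 0:1)) stop("events must be 0/1")
  if (length(times) != length(events)) stop("times/events length mismatch")
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' referred to chi-square with 1 degree of freedom.
#'
#' @inheritParams kaplan_meier
#' @return list with `statistic` and `p_value`.
#' @export
logrank <- function(times, events, group) {
  check_surv_args(times, events)
  group <- factor(group)
  if (nlevels(group) != 2) stop("log-rank test needs exactly 2 groups")
  if (any(table(group) == 0)) stop("each group needs >= 1 subject")
  if (sum(events) == 0) stop("zero events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with Efron tie correction
#'
#' Newton-Raphson maximization of the partial likelihood via
#' `survival::coxph` (Efron ties). Rows with missing covariates are dropped
#' (complete-case) and counted. Monotone partial likelihoods (e.g. all events
#' in one level of a binary covariate) and non-convergence are errors.
#'
#' @param design data.frame of covariates (factors expand to treatment-coded
#'   dummies; code Gleason with `<=6` as the reference level).
#' @param times,events survival outcome.
#' @return Object of class `survival_fit`: per-covariate `coef`, `hr`,
#'   `ci_lower`, `ci_upper` (Wald 95%, log scale), `se`, `p_value`; plus
#'   `loglik`, `n`, `n_events`, `n_missing`.
#' @export
cox_ph <- function(design, times, events) {
  check_surv_args(times, events)
  design <- as.data.frame(design)
  if (nrow(design) != length(times)) stop("design rows must match times")
  complete <- stats::complete.cases(design)
  n_missing <- sum(!complete)
  design <- design[complete, , drop = FALSE]
  times <- times[complete]
  events <- events[complete]
  if (sum(events) < 1) stop("zero-events error: no events to fit")

  dat <- cbind(data.frame(.time = times, .event = events), design)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (any(grepl("infinite|did not converge|out of range", warn))) {
    stop("Cox fit failed (monotone likelihood or non-convergence): ",
         paste(unique(warn), collapse = "; "))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(
    term = names(beta), coef = unname(beta), hr = unname(exp(beta)),
    ci_lower = unname(exp(beta - stats::qnorm(0.975) * se)),
    ci_upper = unname(exp(beta + stats::qnorm(0.975) * se)),
    se = unname(se),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(terms = tab, loglik = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent, n_missing = n_missing),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> n = %d, events = %d%s\n", x$n, x$n_events,
              if (x$n_missing > 0)
                sprintf(" (%d dropped for missing covariates)", x$n_missing)
              else ""))
  tab <- x$terms
  tab$hr <- sprintf("%.3g [%.3g, %.3g]", tab$hr, tab$ci_lower, tab$ci_upper)
  print(tab[, c("term", "coef", "hr", "p_value")], row.names = FALSE)
  invisible(x)
}
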