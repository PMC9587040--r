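# Multiple logistic regression with forced-entry confounders, bidirectional
# p-value stepwise drug selection, adjusted RORs and VIF diagnostics.

#' Design matrix for the signal model
#'
#' Builds the covariate matrix of an analysis table: indicator columns
#' `sex_female`, `age_ge60`, `ebmi_obese`, `ebmi_underweight` (normal eBMI
#' is the reference and carries no column) plus one indicator per requested
#' drug, named by the drug.
#'
#' @param at an `analysis_table`.
#' @param drugs character vector of drug columns to include.
#' @return List with `x` (numeric matrix), `y` (0/1 outcome vector),
#'   `forced_terms`, `candidate_terms`.
#' @export
build_design <- function(at, drugs = character(0)) {
  stopifnot(inherits(at, "analysis_table"))
  cases <- at$cases
  x <- cbind(
    sex_female = as.numeric(cases$sex == "female"),
    age_ge60 = as.numeric(cases$age_ge60),
    ebmi_obese = as.numeric(cases$ebmi_class == "obese"),
    ebmi_underweight = as.numeric(cases$ebmi_class == "underweight")
  )
  drugs <- unique(drugs)
  if (length(drugs)) {
    dm <- vapply(drugs, function(d) {
      ids <- at$exposures$case_id[at$exposures$drug_name == d]
      as.numeric(cases$case_id %in% ids)
    }, numeric(nrow(cases)))
    if (is.null(dim(dm))) dm <- matrix(dm, nrow = nrow(cases),
                                       dimnames = list(NULL, drugs))
    x <- cbind(x, dm)
  }
  list(x = x, y = as.numeric(cases$event),
       forced_terms = c("sex_female", "age_ge60", "ebmi_obese",
                        "ebmi_underweight"),
       candidate_terms = drugs)
}

#' Maximum-likelihood logistic regression
#'
#' Fits a binary logistic model by iteratively reweighted least squares
#' with step-halving (so the log-likelihood never decreases), convergence
#' on the maximum coefficient change (`tol`, default 1e-8) within
#' `max_iter` iterations. Wald standard errors come from the inverse
#' observed information; adjusted reporting odds ratios are
#' `exp(coefficient)` with `exp(coefficient +- z * SE)` intervals and
#' two-sided Wald p-values. Any coefficient walking past `coef_bound` in
#' absolute value aborts with an error naming the separating covariate.
#'
#' @param x numeric matrix of covariates (no intercept column; an
#'   intercept is added internally). May have zero columns for an
#'   intercept-only model.
#' @param y 0/1 outcome vector.
#' @param weights optional non-negative case weights (e.g. aggregated
#'   contingency counts).
#' @param tol,max_iter IRLS convergence controls.
#' @param coef_bound separation guard on |coefficient| (default 30).
#' @param conf_level confidence level for the aROR intervals.
#' @return Object of class `logistic_fit`: `terms`, `coefficients`, `se`,
#'   `z`, `p_values`, `aror`, `aror_ci` (matrix), `loglik`, `deviance`,
#'   `n`, `converged`, `iterations`, `vcov`.
#' @export
fit_logistic <- function(x, y, weights = NULL, tol = 1e-8, max_iter = 100L,
                         coef_bound = 30, conf_level = 0.95) {
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (ncol(x)) {
    cn <- colnames(x)
    if (is.null(cn) || any(!nzchar(cn))) {
      stop("all covariate columns must be named", call. = FALSE)
    }
    const <- apply(x, 2, function(v) diff(range(v)) == 0)
    if (any(const)) {
      stop(sprintf("constant covariate column(s): %s",
                   paste(sQuote(cn[const]), collapse = ", ")),
           call. = FALSE)
    }
  }
  X <- cbind("(Intercept)" = 1, x)
  p <- ncol(X)
  w0 <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  stopifnot(length(w0) == length(y), all(w0 >= 0))
  if (sum(w0) <= p) stop("more model terms than observations", call. = FALSE)

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(w0 * (y * eta - log1p(exp(eta))))
  }

  beta <- rep(0, p)
  pbar <- min(max(stats::weighted.mean(y, w0), 1e-6), 1 - 1e-6)
  beta[1] <- stats::qlogis(pbar)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(w0 * mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    sw <- sqrt(w)
    qrx <- qr(X * sw)
    if (qrx$rank < p) {
      stop("design matrix is rank deficient (exactly collinear terms)",
           call. = FALSE)
    }
    beta_new <- qr.coef(qrx, z * sw)
    # step-halving: Newton can overshoot; back off until the likelihood
    # does not decrease
    step <- beta_new - beta
    ll_new <- loglik(beta_new)
    h <- 0
    while ((!is.finite(ll_new) || ll_new < ll - 1e-12) && h < 25) {
      step <- step / 2
      beta_new <- beta + step
      ll_new <- loglik(beta_new)
      h <- h + 1
    }
    if (any(!is.finite(beta_new)) || any(abs(beta_new) > coef_bound)) {
      off <- which(!is.finite(beta_new) | abs(beta_new) > coef_bound)
      stop(sprintf("apparent complete separation: coefficient for %s diverged",
                   paste(sQuote(colnames(X)[off]), collapse = ", ")),
           call. = FALSE)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- w0 * mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) {
    matrix(NA_real_, p, p)
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vc))
  zstat <- beta / se
  pv <- 2 * stats::pnorm(-abs(zstat))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(low = exp(beta - zq * se), high = exp(beta + zq * se))
  rownames(ci) <- colnames(X)

  structure(list(
    terms = colnames(X),
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(zstat, colnames(X)),
    p_values = stats::setNames(pv, colnames(X)),
    aror = stats::setNames(exp(beta), colnames(X)),
    aror_ci = ci,
    loglik = ll, deviance = -2 * ll,
    n = length(y), converged = converged, iterations = iter,
    vcov = vc), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>\n")
  cat(sprintf("  n = %d, log-likelihood %.2f, converged: %s\n",
              x$n, x$loglik, x$converged))
  tab <- data.frame(
    coef = sprintf("%.4f", x$coefficients),
    aROR = sprintf("%.2f", x$aror),
    ci = sprintf("(%.2f-%.2f)", x$aror_ci[, "low"], x$aror_ci[, "high"]),
    p = sprintf("%.3f", x$p_values),
    row.names = x$terms, check.names = FALSE)
  print(tab)
  invisible(x)
}

fit_cols <- function(x, y, cols, ...) {
  fit_logistic(x[, cols, drop = FALSE], y, ...)
}

#' Forward-backward stepwise selection at a fixed significance level
#'
#' Starting from the forced terms, repeatedly (i) adds the excluded
#' candidate with the smallest likelihood-ratio-test p-value if it is below
#' `alpha_enter`, then (ii) removes the included non-forced term with the
#' largest likelihood-ratio p-value if it is at or above `alpha_remove`,
#' until no change occurs. Forced terms are never removed; ties are broken
#' by lexicographic drug name so the selection is reproducible; candidates
#' whose fit fails (e.g. separation) are skipped in that scan.
#'
#' @param x full covariate matrix containing forced and candidate columns.
#' @param y 0/1 outcome vector.
#' @param forced_terms,candidate_terms disjoint character vectors of
#'   column names of `x`.
#' @param alpha_enter,alpha_remove entry/removal significance levels
#'   (defaults 0.05; `alpha_enter <= alpha_remove` required).
#' @param ... passed to [fit_logistic()].
#' @return The final refit [fit_logistic()] object with extra fields
#'   `selected_drugs`, `forced_terms` and `steps` (data frame logging each
#'   action).
#' @export
stepwise_select <- function(x, y, forced_terms, candidate_terms,
                            alpha_enter = 0.05, alpha_remove = 0.05, ...) {
  stopifnot(alpha_enter > 0, alpha_enter <= alpha_remove, alpha_remove < 1)
  stopifnot(!length(intersect(forced_terms, candidate_terms)))
  candidate_terms <- sort(candidate_terms)

  # candidates constant in this data cannot enter
  usable <- candidate_terms[vapply(candidate_terms, function(d) {
    diff(range(x[, d])) > 0
  }, logical(1))]

  dev_of <- function(cols) fit_cols(x, y, cols, ...)$deviance
  lr_p <- function(dev_small, dev_big) {
    stats::pchisq(max(dev_small - dev_big, 0), df = 1, lower.tail = FALSE)
  }

  current <- character(0)
  steps <- list()
  dev_cur <- dev_of(c(forced_terms, current))
  for (round in seq_len(100L)) {
    changed <- FALSE
    # forward
    pool <- setdiff(usable, current)
    if (length(pool)) {
      pv <- vapply(pool, function(d) {
        dv <- tryCatch(dev_of(c(forced_terms, current, d)),
                       error = function(e) NA_real_)
        if (is.na(dv)) NA_real_ else lr_p(dev_cur, dv)
      }, numeric(1))
      if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < alpha_enter) {
        best <- pool[which.min(pv)]  # pool is sorted: ties -> lexicographic
        current <- sort(c(current, best))
        dev_cur <- dev_of(c(forced_terms, current))
        steps[[length(steps) + 1L]] <- data.frame(
          action = "add", term = best, p_value = min(pv, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # backward
    if (length(current)) {
      pv <- vapply(current, function(d) {
        dv <- tryCatch(dev_of(c(forced_terms, setdiff(current, d))),
                       error = function(e) NA_real_)
        if (is.na(dv)) NA_real_ else lr_p(dv, dev_cur)
      }, numeric(1))
      if (any(!is.na(pv)) && max(pv, na.rm = TRUE) >= alpha_remove) {
        worst <- current[which.max(pv)]  # sorted: ties -> lexicographic
        current <- setdiff(current, worst)
        dev_cur <- dev_of(c(forced_terms, current))
        steps[[length(steps) + 1L]] <- data.frame(
          action = "remove", term = worst, p_value = max(pv, na.rm = TRUE))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- fit_cols(x, y, c(forced_terms, current), ...)
  fit$selected_drugs <- current
  fit$forced_terms <- forced_terms
  fit$steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(0), term = character(0),
               p_value = numeric(0))
  fit
}

#' Variance inflation factors of a linear design
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the ordinary linear
#' regression of column `j` on all other columns plus an intercept —
#' computed on the plain design matrix, not a weighted logistic variant.
#' Exact collinearity is reported as `Inf`.
#'
#' @param x numeric matrix with at least two named columns, none constant.
#' @return Named numeric vector of VIFs.
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("VIF needs at least two model terms", call. = FALSE)
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop(sprintf("constant column(s): %s",
                 paste(sQuote(colnames(x)[const]), collapse = ", ")),
         call. = FALSE)
  }
  vif <- vapply(seq_len(ncol(x)), function(j) {
    yj <- x[, j]
    Xj <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xj, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(vif, colnames(x))
}

#' Fit the full signal model on an analysis table
#'
#' Convenience wrapper tying the pieces together: builds the design with
#' forced demographic terms and the candidate drug indicators (drugs used
#' to treat the target condition are excluded from candidacy by default,
#' since their association is protopathic), runs the stepwise selection and
#' attaches VIFs for the final model terms.
#'
#' @param at an `analysis_table`.
#' @param candidates character vector of candidate drugs (defaults to the
#'   [drugs_of_interest()] list).
#' @param excluded_candidates drugs never eligible for selection (default
#'   albumin tannate, prednisolone, loperamide).
#' @param alpha_enter,alpha_remove stepwise significance levels.
#' @param ... passed to [fit_logistic()].
#' @return A `logistic_fit` (see [stepwise_select()]) with a `vif` field.
#' @export
fit_signal_model <- function(at, candidates = NULL,
                             excluded_candidates = c("albumin tannate",
                                                     "prednisolone",
                                                     "loperamide"),
                             alpha_enter = 0.05, alpha_remove = 0.05, ...) {
  stopifnot(inherits(at, "analysis_table"))
  if (is.null(candidates)) candidates <- drugs_of_interest(at)$drug
  candidates <- setdiff(candidates, excluded_candidates)
  des <- build_design(at, candidates)
  fit <- stepwise_select(des$x, des$y, des$forced_terms, candidates,
                         alpha_enter = alpha_enter,
                         alpha_remove = alpha_remove, ...)
  final_terms <- c(des$forced_terms, fit$selected_drugs)
  fit$vif <- if (length(final_terms) >= 2L) {
    compute_vif(des$x[, final_terms, drop = FALSE])
  } else stats::setNames(numeric(0), character(0))
  fit
}

#' By-sex subset models with fixed terms
#'
#' Fits, separately in female and male cases, a logistic model with fixed
#' explanatory variables — age >= 60, eBMI class (obese and underweight
#' against normal) and the supplied drugs — with no stepwise selection.
#'
#' @param at an `analysis_table`.
#' @param drugs drug indicator terms (default lansoprazole and aspirin).
#' @param ... passed to [fit_logistic()].
#' @return Named list `female`, `male` of `logistic_fit` objects.
#' @export
subset_by_sex <- function(at, drugs = c("lansoprazole", "aspirin"), ...) {
  stopifnot(inherits(at, "analysis_table"))
  des <- build_design(at, drugs)
  keep_cols <- setdiff(colnames(des$x), "sex_female")
  out <- lapply(c(female = "female", male = "male"), function(s) {
    rows <- at$cases$sex == s
    fit_logistic(des$x[rows, keep_cols, drop = FALSE], des$y[rows], ...)
  })
  out
}

#' Tidy one or two regression fits into the report layout
#'
#' @param fit a `logistic_fit`.
#' @param at the `analysis_table` it was fitted on (for per-term case
#'   counts); for subset fits pass the subset rows via `subset_sex`.
#' @param population label for the `population` column.
#' @param subset_sex optional `"female"`/`"male"` restriction used when
#'   counting cases with each term.
#' @return Tibble in the `regression_all.tsv` column layout.
#' @export
regression_table <- function(fit, at, population = "all",
                             subset_sex = NULL) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(at, "analysis_table"))
  cases <- at$cases
  if (!is.null(subset_sex)) cases <- cases[cases$sex == subset_sex, ]
  terms <- setdiff(fit$terms, "(Intercept)")
  forced <- c("sex_female", "age_ge60", "ebmi_obese", "ebmi_underweight")
  has_term <- function(term) {
    if (term == "sex_female") return(cases$sex == "female")
    if (term == "age_ge60") return(cases$age_ge60)
    if (term == "ebmi_obese") return(cases$ebmi_class == "obese")
    if (term == "ebmi_underweight") return(cases$ebmi_class == "underweight")
    ids <- at$exposures$case_id[at$exposures$drug_name == term]
    cases$case_id %in% ids
  }
  vifs <- fit$vif %||% stats::setNames(numeric(0), character(0))
  rows <- lapply(terms, function(tm) {
    flag <- has_term(tm)
    tibble::tibble(
      population = population, term = tm,
      cases_with_term = sum(flag & cases$event),
      noncases_with_term = sum(flag & !cases$event),
      coefficient = fit$coefficients[[tm]], se = fit$se[[tm]],
      aror = fit$aror[[tm]],
      ci_low = fit$aror_ci[tm, "low"], ci_high = fit$aror_ci[tm, "high"],
      p_value = fit$p_values[[tm]],
      vif = if (tm %in% names(vifs)) vifs[[tm]] else NA_real_,
      forced = tm %in% forced,
      selected = tm %in% (fit$selected_drugs %||% character(0)))
  })
  do.call(rbind, rows)
}
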