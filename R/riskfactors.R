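# Risk-factor analysis: multivariate logistic regression of
# dermatologic-AE occurrence on hospitalization, age band and weight band
# within one drug's deduplicated report universe.

#' Build the regression design for one drug's report universe
#'
#' One row per deduplicated report mentioning the drug, with binary
#' covariates banded as in the descriptive table: `outcome` (1 if the
#' report is a dermatologic-AE case), `hospitalized` (HO among its outcome
#' codes), `age_ge65` (age >= 65 years; reference < 65) and
#' `weight_extreme` (weight < 50 or > 100 kg; reference 50-100 kg).
#' Reports with missing age or weight are incomplete and excluded, with
#' the dropped count logged.
#'
#' @param bundle Deduplicated `faers_bundle`.
#' @param drug_ids Primaryids of the drug's reports ([match_drug()]).
#' @param derm_ids Primaryids of dermatologic cases ([filter_soc()]).
#' @return Tibble: `primaryid`, `outcome`, `hospitalized`, `age_ge65`,
#'   `weight_extreme` (all 0/1).
#' @export
build_design <- function(bundle, drug_ids, derm_ids) {
  stopifnot(inherits(bundle, "faers_bundle"))
  ho <- unique(bundle$outc$primaryid[bundle$outc$outc_cod == "HO"])
  rows <- bundle$demo %>%
    filter(.data$primaryid %in% drug_ids) %>%
    mutate(age_years = age_to_years(.data$age, .data$age_cod),
           weight_kg = weight_to_kg(.data$wt, .data$wt_cod))
  complete <- !is.na(rows$age_years) & !is.na(rows$weight_kg)
  if (any(!complete)) {
    inform(sprintf("%d incomplete report(s) excluded from the regression design",
                   sum(!complete)))
  }
  rows %>%
    filter(complete) %>%
    transmute(.data$primaryid,
              outcome = as.integer(.data$primaryid %in% derm_ids),
              hospitalized = as.integer(.data$primaryid %in% ho),
              age_ge65 = as.integer(.data$age_years >= 65),
              weight_extreme = as.integer(.data$weight_kg < 50 |
                                            .data$weight_kg > 100))
}

#' Multivariate logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression with intercept, fitted by
#' iteratively reweighted least squares with step-halving (so the deviance
#' is non-increasing across iterations); convergence at score norm below
#' `tol`. Wald intervals `exp(beta +/- z SE)` and two-sided Wald p-values
#' per covariate. Errors explicitly on a singular design (naming the
#' covariate) or on complete separation.
#'
#' @param rows Design tibble from [build_design()], or any tibble with a
#'   0/1 `outcome` column; every other non-`primaryid` column is a
#'   covariate.
#' @param conf_level Confidence level (default 0.95).
#' @param tol Convergence tolerance on the score norm (default 1e-8).
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `logistic_fit`. Methods: [tidy()] (per-term
#'   estimates, ORs, CIs, p-values), [glance()], [autoplot()], `print()`.
#' @export
fit_logistic <- function(rows, conf_level = 0.95, tol = 1e-8, max_iter = 50) {
  terms <- setdiff(names(rows), c("primaryid", "outcome"))
  y <- rows$outcome
  if (length(unique(y)) < 2) abort("outcome must contain both classes")
  x <- cbind(`(Intercept)` = 1, as.matrix(rows[terms]))
  storage.mode(x) <- "double"
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(sprintf("singular design: covariate '%s' is collinear", bad[1]))
  }

  beta <- rep(0, ncol(x))
  dev <- function(b) {
    eta <- drop(x %*% b)
    -2 * sum(y * eta - log1p(exp(eta)))
  }
  d_old <- dev(beta)
  deviance_trace <- d_old
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- stats::plogis(eta)
    score <- drop(crossprod(x, y - p))
    if (sqrt(sum(score^2)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(x * w, x)
    delta <- tryCatch(solve(info, score), error = function(e) {
      abort("singular information matrix in IRLS (quasi-separated design?)")
    })
    step <- 1
    repeat { # step-halving keeps the deviance non-increasing
      b_new <- beta + step * delta
      d_new <- dev(b_new)
      if (d_new <= d_old + 1e-10 || step < 1e-8) break
      step <- step / 2
    }
    beta <- b_new
    d_old <- d_new
    deviance_trace <- c(deviance_trace, d_new)
    if (max(abs(drop(x %*% beta))) > 20) {
      abort("complete or quasi-complete separation detected (diverging coefficients)")
    }
  }
  if (max(abs(drop(x %*% beta))) > 20) {
    abort("complete or quasi-complete separation detected (fitted probabilities numerically 0 or 1)")
  }
  if (!converged) {
    eta <- drop(x %*% beta)
    score <- drop(crossprod(x, y - stats::plogis(eta)))
    if (sqrt(sum(score^2)) >= tol) {
      abort(sprintf("IRLS did not converge in %d iterations", max_iter))
    }
    converged <- TRUE
  }

  p <- stats::plogis(drop(x %*% beta))
  w <- pmax(p * (1 - p), 1e-12)
  vc <- solve(crossprod(x * w, x))
  se <- sqrt(diag(vc))
  z <- qnorm(1 - (1 - conf_level) / 2)
  zstat <- beta / se
  coefs <- tibble(
    term = colnames(x), estimate = unname(beta), std.error = unname(se),
    statistic = unname(zstat),
    p.value = unname(2 * pnorm(-abs(zstat))),
    or = exp(unname(beta)),
    conf.low = exp(unname(beta - z * se)),
    conf.high = exp(unname(beta + z * se))
  )
  structure(
    list(coefficients = coefs, n = length(y), deviance = d_old,
         deviance_trace = deviance_trace, loglik = -d_old / 2,
         converged = converged, iterations = length(deviance_trace) - 1,
         conf_level = conf_level, vcov = vc, design = as_tibble(rows)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, deviance %.2f, %d IRLS iterations)\n",
              x$n, x$deviance, x$iterations))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname fit_logistic
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_logistic
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(n = x$n, deviance = x$deviance, logLik = x$loglik,
         iterations = x$iterations, converged = x$converged)
}

#' Risk-factor table (odds ratios with reference-level counts)
#'
#' Per binary covariate: reference/alternative level counts and the Wald
#' odds ratio, CI and p-value from the fitted model.
#'
#' @param fit A `logistic_fit` whose design columns are 0/1 covariates.
#' @return Tibble: `covariate`, `n_ref`, `n_alt`, `or`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
risk_table <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  terms <- setdiff(names(fit$design), c("primaryid", "outcome"))
  counts <- purrr::map_dfr(terms, function(tm) {
    tibble(covariate = tm,
           n_ref = sum(fit$design[[tm]] == 0),
           n_alt = sum(fit$design[[tm]] == 1))
  })
  counts %>%
    left_join(select(tidy(fit), covariate = "term", "or", "conf.low",
                     "conf.high", "p.value"),
              by = "covariate")
}
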