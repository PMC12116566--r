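# Time to onset (TTO): days from therapy initiation (THER start date) to
# adverse-event occurrence (DEMO event date). Only strictly positive onsets
# computed from full-precision dates enter the analysis.

#' Compute time-to-onset records for a case set
#'
#' Onset is `event_dt - therapy_start_dt` in whole days, one record per
#' case x dermatologic PT. Rows are excluded, with a reason code, when a
#' date is missing or only partial-precision (`missing_date`), when the
#' therapy start falls after the event (`erroneous_date`), or when the
#' onset is zero days (`zero_onset`). The reasons partition all dropped
#' rows; retrieve them with [tto_exclusions()].
#'
#' @param cases Case tibble from [build_cases()] (carries `event_dt` and
#'   `therapy_start_dt`).
#' @return Tibble of kept records: `primaryid`, `drug`, `pt`,
#'   `onset_days` (positive integer), with attribute `"exclusions"`.
#' @export
compute_tto <- function(cases) {
  rows <- cases %>%
    select("primaryid", "drug", "pts", "event_dt", "therapy_start_dt") %>%
    tidyr::unnest_longer("pts", values_to = "pt") %>%
    mutate(
      event = ymd_to_date(.data$event_dt),
      start = ymd_to_date(.data$therapy_start_dt),
      onset_days = as.integer(.data$event - .data$start),
      reason = case_when(
        is.na(.data$event) | is.na(.data$start) ~ "missing_date",
        .data$onset_days < 0 ~ "erroneous_date",
        .data$onset_days == 0 ~ "zero_onset",
        TRUE ~ NA_character_
      )
    )
  kept <- rows %>%
    filter(is.na(.data$reason)) %>%
    select("primaryid", "drug", "pt", "onset_days")
  excl <- rows %>%
    filter(!is.na(.data$reason)) %>%
    select("primaryid", "drug", "pt", "reason")
  attr(kept, "exclusions") <- excl
  kept
}

#' Exclusion audit of a time-to-onset computation
#'
#' @param tto Result of [compute_tto()].
#' @return Tibble of excluded rows with their `reason` codes.
#' @export
tto_exclusions <- function(tto) {
  attr(tto, "exclusions") %||%
    tibble(primaryid = integer(), drug = character(), pt = character(),
           reason = character())
}

#' Summarize onset times per drug-PT pair
#'
#' Median and quartiles by linear interpolation (an even group size yields
#' the mean of the two middle order statistics, hence half-day medians).
#'
#' @param tto Records from [compute_tto()].
#' @return Tibble: `drug`, `pt`, `n`, `median_days`, `q1_days`, `q3_days`,
#'   one row per pair with `n >= 1`, ordered by median.
#' @examples
#' recs <- tibble::tibble(primaryid = 1:2, drug = "d", pt = "Night sweats",
#'                        onset_days = c(20L, 21L))
#' summarize_tto(recs) # median 20.5
#' @export
summarize_tto <- function(tto) {
  tto %>%
    group_by(.data$drug, .data$pt) %>%
    summarise(n = dplyr::n(),
              median_days = median(.data$onset_days),
              q1_days = unname(quantile(.data$onset_days, 0.25, type = 7)),
              q3_days = unname(quantile(.data$onset_days, 0.75, type = 7)),
              .groups = "drop") %>%
    arrange(.data$median_days, .data$pt)
}

# numerical gradient of the Weibull negative log-likelihood (log-parameter scale)
num_grad <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, numeric(1))
}

#' Fit a Weibull onset model by maximum likelihood
#'
#' Fits the density `f(t) = (k/lambda) (t/lambda)^(k-1) exp(-(t/lambda)^k)`
#' to observed onset days. Optimization is on `(log k, log lambda)` with
#' method-of-moments initialization; Wald confidence intervals come from
#' the observed information on the log scale. The hazard is classified
#' from the shape CI: `early-failure` when entirely below 1 (decreasing
#' hazard), `random` when it covers 1 (constant hazard, the exponential
#' special case), `late-failure` when entirely above 1.
#'
#' @param onsets Positive onset days (`n >= 10` required).
#' @param conf_level Confidence level (default 0.95).
#' @param fix_shape Optional: hold the shape at this value and estimate the
#'   scale only (`fix_shape = 1` is the exponential model, whose scale MLE
#'   is the sample mean).
#' @return An object of class `weibull_fit`: shape `k` and scale `lambda`
#'   (days) with CIs, `n`, `loglik`, `hazard_class`. Methods: [tidy()],
#'   [glance()], [autoplot()], `print()`.
#' @export
fit_weibull <- function(onsets, conf_level = 0.95, fix_shape = NULL) {
  onsets <- as.numeric(onsets)
  stopifnot(all(onsets > 0))
  if (length(onsets) < 10) {
    abort(sprintf("Weibull fit requires n >= 10 onsets (got %d)", length(onsets)))
  }
  if (!is.null(fix_shape)) return(fit_weibull_fixed(onsets, fix_shape, conf_level))
  m <- mean(onsets); s <- sd(onsets)
  k0 <- if (s > 0) (s / m)^(-1.086) else 1 # CV-based method of moments
  l0 <- m / gamma(1 + 1 / k0)
  nll <- function(par) {
    val <- suppressWarnings(
      -sum(dweibull(onsets, shape = exp(par[1]), scale = exp(par[2]), log = TRUE)))
    if (!is.finite(val)) val <- 1e10 # overflow guard for wild line-search steps
    val
  }
  start <- log(c(k0, l0))
  fit <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  if (fit$convergence != 0) {
    abort(sprintf("Weibull MLE did not converge (start k=%.4g, lambda=%.4g)",
                  k0, l0))
  }
  g <- num_grad(nll, fit$par)
  if (sqrt(sum(g^2)) > 1e-4) {
    # BFGS polish from the current point if the gradient is not yet flat
    fit <- optim(fit$par, nll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500, reltol = 1e-14))
  }
  vc <- tryCatch(solve(fit$hessian), error = function(e) {
    abort(sprintf("singular information matrix (start k=%.4g, lambda=%.4g)", k0, l0))
  })
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(vc))
  est <- exp(fit$par)
  lo <- exp(fit$par - z * se)
  hi <- exp(fit$par + z * se)
  hazard_class <- if (hi[1] < 1) "early-failure" else if (lo[1] > 1) "late-failure" else "random"
  structure(
    list(shape = est[1], shape_lo = lo[1], shape_hi = hi[1],
         scale = est[2], scale_lo = lo[2], scale_hi = hi[2],
         n = length(onsets), loglik = -fit$value, hazard_class = hazard_class,
         conf_level = conf_level, vcov_log = vc, onsets = onsets),
    class = "weibull_fit"
  )
}

# fixed-shape profile: closed-form scale MLE lambda = (mean(t^k))^(1/k)
fit_weibull_fixed <- function(onsets, k, conf_level) {
  stopifnot(k > 0)
  lam <- mean(onsets^k)^(1 / k)
  ll <- sum(dweibull(onsets, shape = k, scale = lam, log = TRUE))
  # observed information for log(lambda) at the MLE: n * k^2
  se <- 1 / sqrt(length(onsets) * k^2)
  z <- qnorm(1 - (1 - conf_level) / 2)
  hazard_class <- if (k < 1) "early-failure" else if (k > 1) "late-failure" else "random"
  structure(
    list(shape = k, shape_lo = k, shape_hi = k,
         scale = lam, scale_lo = exp(log(lam) - z * se),
         scale_hi = exp(log(lam) + z * se),
         n = length(onsets), loglik = ll, hazard_class = hazard_class,
         conf_level = conf_level,
         vcov_log = matrix(c(0, 0, 0, se^2), 2,
                           dimnames = list(c("log_k", "log_lambda"),
                                           c("log_k", "log_lambda"))),
         onsets = onsets),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull onset fit (n = %d)\n", x$n))
  cat(sprintf("  shape k      %6.3f  [%.3f, %.3f]\n", x$shape, x$shape_lo, x$shape_hi))
  cat(sprintf("  scale lambda %6.1f  [%.1f, %.1f] days\n", x$scale, x$scale_lo, x$scale_hi))
  cat(sprintf("  hazard: %s;  log-lik %.2f\n", x$hazard_class, x$loglik))
  invisible(x)
}

#' @rdname fit_weibull
#' @param x A `weibull_fit`.
#' @param ... Unused.
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble(term = c("shape", "scale"),
         estimate = c(x$shape, x$scale),
         std.error = c(x$shape * sqrt(x$vcov_log[1, 1]),
                       x$scale * sqrt(x$vcov_log[2, 2])),
         conf.low = c(x$shape_lo, x$scale_lo),
         conf.high = c(x$shape_hi, x$scale_hi))
}

#' @rdname fit_weibull
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(n = x$n, logLik = x$loglik, hazard_class = x$hazard_class,
         conf.level = x$conf_level)
}

#' Weibull onset fits for every drug-PT pair with enough onsets
#'
#' @param tto Records from [compute_tto()].
#' @param min_n Minimum onsets per pair (default 10, the fitting floor).
#' @return Tibble: `drug`, `pt`, `n`, `shape`, `shape_lo`, `shape_hi`,
#'   `scale`, `scale_lo`, `scale_hi`, `hazard_class`, `loglik`.
#' @export
weibull_by_pair <- function(tto, min_n = 10) {
  tto %>%
    group_by(.data$drug, .data$pt) %>%
    filter(dplyr::n() >= min_n) %>%
    summarise(fit = list(fit_weibull(.data$onset_days)), .groups = "drop") %>%
    mutate(n = purrr::map_int(.data$fit, "n"),
           shape = purrr::map_dbl(.data$fit, "shape"),
           shape_lo = purrr::map_dbl(.data$fit, "shape_lo"),
           shape_hi = purrr::map_dbl(.data$fit, "shape_hi"),
           scale = purrr::map_dbl(.data$fit, "scale"),
           scale_lo = purrr::map_dbl(.data$fit, "scale_lo"),
           scale_hi = purrr::map_dbl(.data$fit, "scale_hi"),
           hazard_class = purrr::map_chr(.data$fit, "hazard_class"),
           loglik = purrr::map_dbl(.data$fit, "loglik")) %>%
    select(-"fit")
}
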