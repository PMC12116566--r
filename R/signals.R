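# Disproportionality statistics on 2x2 contingency tables of spontaneous
# reports: a = drug & event, b = drug only, c = event only, d = neither.
# Counting unit is the deduplicated report.

#' Build a 2x2 contingency table for one drug-event pair
#'
#' Counts deduplicated reports: `a` with both the target drug and the
#' event, `b` with the drug only, `c` with the event only, `d` with
#' neither.
#'
#' @param universe A deduplicated `faers_bundle`, or an integer vector of
#'   the universe's primaryids.
#' @param drug_ids,event_ids Primaryid sets (must be subsets of the
#'   universe).
#' @return One-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @examples
#' build_contingency(1:10, drug_ids = 1:4, event_ids = 3:6) # a=2 b=2 c=2 d=4
#' @export
build_contingency <- function(universe, drug_ids, event_ids) {
  ids <- if (inherits(universe, "faers_bundle")) universe$demo$primaryid else universe
  stopifnot(all(drug_ids %in% ids), all(event_ids %in% ids))
  n <- length(ids)
  a <- length(intersect(drug_ids, event_ids))
  b <- length(drug_ids) - a
  c <- length(event_ids) - a
  tibble(a = a, b = b, c = c, d = n - a - b - c, n = n)
}

# Haldane-Anscombe: +0.5 on all four cells, only when some cell is zero
haldane <- function(a, b, c, d) {
  z <- (a == 0 | b == 0 | c == 0 | d == 0)
  list(a = a + 0.5 * z, b = b + 0.5 * z, c = c + 0.5 * z, d = d + 0.5 * z,
       corrected = z)
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d)/(b c)` with the 95% Wald interval
#' `exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero
#' the Haldane-Anscombe correction (+0.5 on all four cells) is applied and
#' flagged; with `correction = FALSE` such tables yield `NA` (flagged, not
#' silently dropped).
#'
#' @param a,b,c,d Contingency cells (vectorized).
#' @param conf_level Confidence level (default 0.95).
#' @param correction Apply Haldane-Anscombe on zero cells (default TRUE).
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`, `corrected`.
#' @examples
#' ror_stats(10, 90, 100, 9900) # ror 11, CI (5.56, 21.76)
#' @export
ror_stats <- function(a, b, c, d, conf_level = 0.95, correction = TRUE) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (correction) {
    h <- haldane(a, b, c, d)
    wa <- h$a; wb <- h$b; wc <- h$c; wd <- h$d; corrected <- h$corrected
  } else {
    wa <- a; wb <- b; wc <- c; wd <- d
    corrected <- rep(FALSE, length(a))
    bad <- (a == 0 | b == 0 | c == 0 | d == 0)
    wa[bad] <- NA_real_
  }
  est <- (wa * wd) / (wb * wc)
  se <- sqrt(1 / wa + 1 / wb + 1 / wc + 1 / wd)
  tibble(ror = est, ror_lo = exp(log(est) - z * se),
         ror_hi = exp(log(est) + z * se), corrected = corrected)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is Pearson's
#' on the raw 2x2, without Yates continuity correction by default. Zero
#' margins yield `NA` (flagged by `NaN`/`NA`, never dropped); a zero cell
#' in the PRR ratio is handled by the same Haldane correction as
#' [ror_stats()].
#'
#' @param a,b,c,d Contingency cells (vectorized).
#' @param yates Apply Yates continuity correction to the chi-squared
#'   statistic (default FALSE).
#' @param correction Haldane-Anscombe on zero cells for the PRR.
#' @return Tibble with columns `prr`, `chi2`.
#' @examples
#' prr_chi2(10, 90, 100, 9900) # prr 10, chi2 ~74.4
#' @export
prr_chi2 <- function(a, b, c, d, yates = FALSE, correction = TRUE) {
  if (correction) {
    h <- haldane(a, b, c, d)
    wa <- h$a; wb <- h$b; wc <- h$c; wd <- h$d
  } else {
    wa <- a; wb <- b; wc <- c; wd <- d
  }
  prr <- (wa / (wa + wb)) / (wc / (wc + wd))
  n <- a + b + c + d
  det <- a * d - b * c
  if (yates) det <- pmax(abs(det) - n / 2, 0)
  denom <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom == 0, NA_real_, n * det^2 / denom)
  tibble(prr = prr, chi2 = chi2)
}

#' BCPNN information component (closed-form shrinkage)
#'
#' The expected count under independence is `E = (a+b)(a+c)/N`. The
#' shrunken information component is `IC = log2((a + 0.5)/(E + 0.5))` with
#' lower 2.5% credibility bound
#' `IC025 = IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}`
#' (the Noren closed-form approximation; defined for `a = 0`).
#'
#' @param a,b,c,d Contingency cells (vectorized).
#' @return Tibble with columns `ic`, `ic025`, `expected`.
#' @examples
#' ic_bcpnn(8, 92, 92, 9808) # ic ~2.503, ic025 ~1.29
#' @export
ic_bcpnn <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  tibble(ic = ic, ic025 = ic025, expected = e)
}

#' Gamma-mixture prior for the multi-item gamma-Poisson shrinker
#'
#' DuMouchel's empirical-Bayes model places a two-component gamma mixture
#' prior on the relative reporting rate; the canonical default is
#' `w Gamma(0.2, 0.1) + (1-w) Gamma(2, 4)` with `w = 1/3`.
#'
#' @param alpha1,beta1 Shape/rate of the first component (> 0).
#' @param alpha2,beta2 Shape/rate of the second component (> 0).
#' @param w Mixture weight of the first component, in `[0, 1]`.
#' @return An object of class `mgps_prior`.
#' @export
mgps_prior <- function(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2.0, beta2 = 4.0,
                       w = 1 / 3) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha2 > 0, beta2 > 0, w >= 0, w <= 1)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, w = w),
            class = "mgps_prior")
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf("<mgps_prior> %.3f Gamma(%.3g, %.3g) + %.3f Gamma(%.3g, %.3g)\n",
              x$w, x$alpha1, x$beta1, 1 - x$w, x$alpha2, x$beta2))
  invisible(x)
}

# posterior mixture weight of component 1 given count a and expectation E
posterior_weight <- function(a, e, prior) {
  if (prior$w == 0) return(rep(0, length(a)))
  if (prior$w == 1) return(rep(1, length(a)))
  l1 <- log(prior$w) + dnbinom(a, size = prior$alpha1,
                               prob = prior$beta1 / (prior$beta1 + e), log = TRUE)
  l2 <- log1p(-prior$w) + dnbinom(a, size = prior$alpha2,
                                  prob = prior$beta2 / (prior$beta2 + e), log = TRUE)
  1 / (1 + exp(l2 - l1))
}

#' Empirical Bayes geometric mean (MGPS)
#'
#' Under the gamma-mixture prior, the posterior of the relative reporting
#' rate given count `a` and independence expectation `E` is a mixture of
#' `Gamma(alpha_j + a, beta_j + E)` with updated weights.
#' `EBGM = exp(E[log lambda])` (via the digamma function) and `EBGM05` is
#' the 5th percentile of the posterior, root-found from the mixture CDF.
#'
#' @param a Observed count(s).
#' @param e Expected count(s) under independence, `(a+b)(a+c)/N` (> 0).
#' @param prior An [mgps_prior()].
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @examples
#' ct <- build_contingency(1:10000, 1:100, c(1:10, 101:190))
#' e <- with(ct, (a + b) * (a + c) / n)
#' ebgm_mgps(ct$a, e)
#' @export
ebgm_mgps <- function(a, e, prior = mgps_prior()) {
  stopifnot(inherits(prior, "mgps_prior"), all(e > 0))
  one <- function(a, e) {
    q <- posterior_weight(a, e, prior)
    s1 <- prior$alpha1 + a; r1 <- prior$beta1 + e
    s2 <- prior$alpha2 + a; r2 <- prior$beta2 + e
    elog <- q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2))
    cdf <- function(x) q * pgamma(x, s1, rate = r1) +
      (1 - q) * pgamma(x, s2, rate = r2) - 0.05
    lo <- min(stats::qgamma(1e-4, s1, rate = r1), stats::qgamma(1e-4, s2, rate = r2))
    hi <- max(stats::qgamma(0.5, s1, rate = r1), stats::qgamma(0.5, s2, rate = r2))
    q05 <- tryCatch(uniroot(cdf, c(lo, hi), tol = 1e-10)$root,
                    error = function(err) {
                      abort(sprintf(
                        "EBGM05 percentile root-find failed (a=%g, E=%g, bracket [%g, %g]): %s",
                        a, e, lo, hi, conditionMessage(err)))
                    })
    c(exp(elog), q05)
  }
  res <- purrr::map2(a, e, one)
  tibble(ebgm = purrr::map_dbl(res, 1), ebgm05 = purrr::map_dbl(res, 2))
}

#' Fit the MGPS prior by maximum marginal likelihood (EM)
#'
#' The marginal distribution of `a` given `E` under the gamma-mixture
#' prior is a two-component negative-binomial mixture. Hyperparameters are
#' estimated by a generalized EM: the E-step computes posterior component
#' memberships, the M-step updates the mixture weight in closed form and
#' each component's (shape, rate) by maximizing the weighted likelihood
#' (Nelder-Mead on the log scale), so the marginal log-likelihood is
#' non-decreasing across iterations. Falls back to the canonical default
#' prior with a warning on non-convergence.
#'
#' @param a Observed counts (>= 50 pairs required).
#' @param e Expected counts under independence.
#' @param init Starting prior (default [mgps_prior()]).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return An `mgps_prior` with attributes `loglik` (per-iteration trace)
#'   and `converged`.
#' @export
fit_mgps_prior <- function(a, e, init = mgps_prior(), max_iter = 100,
                           tol = 1e-6) {
  if (length(a) < 50) abort("prior fitting requires >= 50 drug-event pairs")
  stopifnot(length(a) == length(e), all(e > 0))

  comp_ll <- function(theta, wts) {
    alpha <- exp(theta[1]); beta <- exp(theta[2])
    -sum(wts * dnbinom(a, size = alpha, prob = beta / (beta + e), log = TRUE))
  }
  marginal_ll <- function(p) {
    l1 <- log(p$w) + dnbinom(a, size = p$alpha1,
                             prob = p$beta1 / (p$beta1 + e), log = TRUE)
    l2 <- log1p(-p$w) + dnbinom(a, size = p$alpha2,
                                prob = p$beta2 / (p$beta2 + e), log = TRUE)
    m <- pmax(l1, l2)
    sum(m + log(exp(l1 - m) + exp(l2 - m)))
  }

  p <- init
  trace <- marginal_ll(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    q <- posterior_weight(a, e, p)
    w_new <- mean(q)
    f1 <- optim(log(c(p$alpha1, p$beta1)), comp_ll, wts = q,
                method = "Nelder-Mead", control = list(maxit = 40))
    f2 <- optim(log(c(p$alpha2, p$beta2)), comp_ll, wts = 1 - q,
                method = "Nelder-Mead", control = list(maxit = 40))
    p <- mgps_prior(exp(f1$par[1]), exp(f1$par[2]),
                    exp(f2$par[1]), exp(f2$par[2]),
                    w = min(max(w_new, 1e-6), 1 - 1e-6))
    ll <- marginal_ll(p)
    trace <- c(trace, ll)
    if (abs(ll - trace[length(trace) - 1]) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn("MGPS prior fitting did not converge; falling back to the default prior")
    p <- mgps_prior()
  }
  attr(p, "loglik") <- trace
  attr(p, "converged") <- converged
  p
}

#' Positive-signal classifier
#'
#' A drug-event pair is a signal when the lower bound of the 95%
#' confidence interval of its ROR exceeds 1 and the pair has at least
#' `min_count` co-reports.
#'
#' @param ror_lo Lower 95% CI bound(s) of the ROR.
#' @param a Co-report count(s).
#' @param min_count Minimum count (default 3).
#' @return Logical vector.
#' @examples
#' classify_signal(c(1.03, 1.04, 0.91), a = c(2986, 1331, 3975)) # T T F
#' @export
classify_signal <- function(ror_lo, a, min_count = 3) {
  !is.na(ror_lo) & ror_lo > 1 & a >= min_count
}

#' All four disproportionality statistics for one pair
#'
#' @param universe Deduplicated bundle or primaryid vector.
#' @param drug_ids,event_ids Primaryid sets defining the pair.
#' @param drug,event Labels for the output row.
#' @param prior MGPS prior ([mgps_prior()] by default).
#' @param min_count Minimum count for the signal rule.
#' @param yates Yates correction for the chi-squared statistic.
#' @return One-row `signal_result` tibble: `drug`, `event`, `a`, `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`,
#'   `is_signal`.
#' @export
signal_stats <- function(universe, drug_ids, event_ids, drug = "drug",
                         event = "event", prior = mgps_prior(),
                         min_count = 3, yates = FALSE) {
  ct <- build_contingency(universe, drug_ids, event_ids)
  signal_from_cells(ct$a, ct$b, ct$c, ct$d, drug = drug, event = event,
                    prior = prior, min_count = min_count, yates = yates)
}

# vectorized assembly of SignalResult rows from raw cells
signal_from_cells <- function(a, b, c, d, drug, event, prior = mgps_prior(),
                              min_count = 3, yates = FALSE) {
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  res <- bind_cols(
    tibble(drug = drug, event = event, a = a),
    ror_stats(a, b, c, d),
    prr_chi2(a, b, c, d, yates = yates),
    select(ic_bcpnn(a, b, c, d), "ic", "ic025"),
    ebgm_mgps(a, pmax(e, 1e-12), prior)
  )
  res <- mutate(res, is_signal = classify_signal(.data$ror_lo, .data$a,
                                                 min_count = min_count))
  class(res) <- c("signal_result", class(res))
  res
}

#' Preferred-term level signal scan within a system organ class
#'
#' For each PT of the SOC with at least one co-report with the target
#' drug, builds the 2x2 against the whole deduplicated universe and
#' computes ROR, PRR/chi-squared, IC and EBGM plus the signal flag.
#' Results are ordered by ROR descending, ties broken by count descending
#' then PT name, so output is stable under permutation of input records.
#'
#' @param bundle Deduplicated `faers_bundle`.
#' @param drug_ids Primaryids of the target drug's reports
#'   ([match_drug()]).
#' @param meddra Stub dictionary ([derm_meddra()]).
#' @param soc_code SOC to scan (default dermatologic, 10040785).
#' @param drug Label for the output rows.
#' @param prior MGPS prior.
#' @param min_count Minimum count for the signal rule (default 3).
#' @return A `signal_scan` tibble, one row per PT.
#' @export
pt_scan <- function(bundle, drug_ids, meddra = derm_meddra(),
                    soc_code = 10040785L, drug = "drug",
                    prior = mgps_prior(), min_count = 3) {
  stopifnot(inherits(bundle, "faers_bundle"))
  ids <- bundle$demo$primaryid
  n <- length(ids)
  soc_pts <- meddra$pt[meddra$soc_code == soc_code]
  key <- normalize_name(soc_pts)
  reac <- bundle$reac %>%
    mutate(.norm = normalize_name(.data$pt)) %>%
    filter(.data$.norm %in% key) %>%
    distinct(.data$primaryid, .data$.norm)
  counts <- reac %>%
    group_by(.data$.norm) %>%
    summarise(a = sum(.data$primaryid %in% drug_ids),
              event_n = dplyr::n(), .groups = "drop") %>%
    filter(.data$a >= 1)
  if (nrow(counts) == 0) {
    res <- signal_from_cells(integer(), integer(), integer(), integer(),
                             drug = character(), event = character())
  } else {
    nd <- length(drug_ids)
    res <- signal_from_cells(
      a = counts$a, b = nd - counts$a, c = counts$event_n - counts$a,
      d = n - nd - counts$event_n + counts$a,
      drug = drug, event = soc_pts[match(counts$.norm, key)],
      prior = prior, min_count = min_count
    )
  }
  res <- res %>%
    arrange(desc(.data$ror), desc(.data$a), .data$event)
  class(res) <- c("signal_scan", "signal_result", class(tibble()))
  res
}
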