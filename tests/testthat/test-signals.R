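test_that("contingency tables count the deduplicated universe correctly", {
  ct <- build_contingency(1:10, drug_ids = 1:4, event_ids = 3:6)
  expect_equal(unlist(ct[c("a", "b", "c", "d")]),
               c(a = 2, b = 2, c = 2, d = 4))
  ct0 <- build_contingency(1:10, drug_ids = 1:4, event_ids = integer(0))
  expect_equal(ct0$a, 0)
  expect_equal(ct0$c, 0)
  expect_equal(ct0$a + ct0$b + ct0$c + ct0$d, ct0$n)
  expect_error(build_contingency(1:10, drug_ids = 11L, event_ids = 1L))
})

test_that("ROR point estimate, Wald CI and Haldane correction are exact", {
  r <- ror_stats(10, 10, 10, 10)
  expect_equal(r$ror, 1)

  r <- ror_stats(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  # hand values use z = 1.96; the package uses qnorm(0.975) = 1.959964
  expect_equal(r$ror_lo, 5.559515, tolerance = 1e-4)
  expect_equal(r$ror_hi, 21.76449, tolerance = 1e-4)
  expect_false(r$corrected)

  # zero cell: +0.5 on all four cells, flagged
  r0 <- ror_stats(0, 10, 10, 100)
  expect_equal(r0$ror, (0.5 * 100.5) / (10.5 * 10.5))
  expect_true(r0$corrected)
  # with correction disabled the result is flagged undefined, not dropped
  rna <- ror_stats(0, 10, 10, 100, correction = FALSE)
  expect_true(is.na(rna$ror))
})

test_that("PRR and Pearson chi-squared match direct arithmetic and chisq.test", {
  p <- prr_chi2(10, 90, 100, 900)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  p <- prr_chi2(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, 74.44717, tolerance = 1e-6)
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(p$chi2, unname(ref$statistic), tolerance = 1e-10)
  refy <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                      correct = TRUE))
  expect_equal(prr_chi2(10, 90, 100, 9900, yates = TRUE)$chi2,
               unname(refy$statistic), tolerance = 1e-10)
})

test_that("ror/prr/chi2 agree with the brute-force oracle on random tables", {
  set.seed(99)
  for (i in 1:200) {
    a <- sample(1:50, 1); b <- sample(1:500, 1)
    c <- sample(1:500, 1); d <- sample(1:5000, 1)
    o <- oracle_2x2(a, b, c, d)
    expect_equal(ror_stats(a, b, c, d)$ror, o$or, tolerance = 1e-10)
    pc <- prr_chi2(a, b, c, d)
    expect_equal(pc$prr, o$prr, tolerance = 1e-10)
    expect_equal(pc$chi2, o$chi2, tolerance = 1e-10)
  }
})

test_that("information component follows the closed-form shrinkage formulas", {
  # observed equals expected at large a -> IC 0
  ic <- ic_bcpnn(1000, 9000, 99000, 891000) # E = (10000*100000)/1e6 = 1000
  expect_equal(ic$expected, 1000)
  expect_equal(ic$ic, 0, tolerance = 1e-12)

  ic <- ic_bcpnn(8, 92, 92, 9808) # E = 1
  expect_equal(ic$ic, log2(8.5 / 1.5), tolerance = 1e-12)
  expect_equal(ic$ic025, log2(8.5 / 1.5) - 3.3 / sqrt(8.5) - 2 / 8.5^1.5,
               tolerance = 1e-12)
  expect_equal(ic$ic, 2.5025, tolerance = 1e-4)
  expect_equal(ic$ic025, 1.29, tolerance = 1e-2)

  # defined at a = 0: E = 100 * 50 / 10000 = 0.5 -> log2(0.5/1.0) = -1
  ic0 <- ic_bcpnn(0, 100, 50, 9850)
  expect_equal(ic0$expected, 0.5)
  expect_equal(ic0$ic, -1)

  # shrinkage washout: IC -> log2(a N / ((a+b)(a+c))) as a (and E) grow
  a <- 1000; b <- 1000; c <- 1000; d <- 50000
  n <- a + b + c + d
  raw <- log2(a * n / ((a + b) * (a + c)))
  expect_equal(ic_bcpnn(a, b, c, d)$ic / raw, 1, tolerance = 0.01)
})

test_that("EBGM honours the degenerate-prior identity and asymptotics", {
  # single-component prior with alpha + a = 1, beta + E = 1:
  # EBGM = exp(E[log lambda]) = exp(digamma(1)) = e^(-gamma)
  pr <- mgps_prior(alpha1 = 0.5, beta1 = 0.5, alpha2 = 0.5, beta2 = 0.5, w = 1)
  out <- ebgm_mgps(a = 0.5, e = 0.5, prior = pr)
  expect_equal(out$ebgm, exp(digamma(1)), tolerance = 1e-10)
  expect_equal(out$ebgm, exp(-0.5772157), tolerance = 1e-6)

  # shrinkage vanishes: a = 1000, E = 100 -> EBGM within 1% of a/E
  out <- ebgm_mgps(1000, 100)
  expect_equal(out$ebgm / 10, 1, tolerance = 0.01)
  expect_lt(out$ebgm05, out$ebgm)

  # EBGM05 is the 5th posterior percentile: check against the mixture CDF
  pr <- mgps_prior()
  for (case in list(c(3, 1), c(20, 4), c(2, 10))) {
    o <- ebgm_mgps(case[1], case[2], pr)
    q <- pvsignal:::posterior_weight(case[1], case[2], pr)
    cdf <- q * pgamma(o$ebgm05, pr$alpha1 + case[1], rate = pr$beta1 + case[2]) +
      (1 - q) * pgamma(o$ebgm05, pr$alpha2 + case[1], rate = pr$beta2 + case[2])
    expect_equal(cdf, 0.05, tolerance = 1e-8)
    expect_lt(o$ebgm05, o$ebgm)
  }
})

test_that("all four statistics increase with a (b, c, d held)", {
  as <- c(5, 10, 20, 40)
  r <- ror_stats(as, 100, 100, 10000)$ror
  p <- prr_chi2(as, 100, 100, 10000)$prr
  ic <- ic_bcpnn(as, 100, 100, 10000)$ic
  eb <- ebgm_mgps(as, (as + 100) * (as + 100) / (as + 100 + 100 + 10000))$ebgm
  expect_true(all(diff(r) > 0))
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(eb) > 0))
})

test_that("ROR and PRR agree in the rare-event limit", {
  # a << b, c << d
  r <- ror_stats(20, 5000, 200, 500000)$ror
  p <- prr_chi2(20, 5000, 200, 500000)$prr
  expect_lt(abs(r - p) / p, 0.01)
})

test_that("EM fitting of the MGPS prior is monotone and recovers a planted prior", {
  set.seed(4)
  n <- 5000
  w_true <- 0.4
  comp <- rbinom(n, 1, w_true)
  lam <- ifelse(comp == 1, rgamma(n, 2, rate = 4), rgamma(n, 0.2, rate = 0.1))
  e <- exp(runif(n, log(0.5), log(50)))
  a <- rpois(n, lam * e)
  fit <- fit_mgps_prior(a, e, max_iter = 60)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-6)) # GEM: non-decreasing marginal likelihood
  # label alignment: the Gamma(2,4) component has mean 0.5, Gamma(.2,.1) mean 2
  m1 <- fit$alpha1 / fit$beta1
  w_hat <- if (abs(m1 - 0.5) < abs(m1 - 2)) fit$w else 1 - fit$w
  expect_lt(abs(w_hat - w_true), 0.1)
})

test_that("a null stream concentrates the fitted prior near 1", {
  set.seed(8)
  n <- 2000
  e <- exp(runif(n, log(1), log(50)))
  a <- rpois(n, e) # lambda = 1 exactly
  fit <- fit_mgps_prior(a, e, max_iter = 60)
  med <- which.min(abs(a / e - stats::median(a / e)))
  eb <- ebgm_mgps(a[med], e[med], fit)$ebgm
  expect_gt(eb, 0.8)
  expect_lt(eb, 1.2)
  expect_error(fit_mgps_prior(a[1:10], e[1:10]), ">= 50")
})

test_that("the signal rule is CI-lower-bound > 1 with a count floor", {
  expect_true(classify_signal(1.03, a = 2986))
  expect_true(classify_signal(1.04, a = 1331))
  expect_false(classify_signal(0.91, a = 3975))
  expect_false(classify_signal(5.0, a = 2, min_count = 3))
  expect_true(classify_signal(5.0, a = 3, min_count = 3))
})

test_that("pt_scan ranks the planted pair first and is order-stable", {
  sim <- generate_bundle(default_ai_config(n_reports = 20000, seed = 33,
                                           planted_ror = 10))
  bd <- dedup_bundle(sim$bundle)
  m <- match_drug(bd$drug, ai_lexicon(), "anastrozole")
  scan <- pt_scan(bd, m, drug = "anastrozole")
  expect_s3_class(scan, "signal_scan")
  expect_equal(scan$event[1], "Alopecia")
  expect_true(scan$is_signal[1])
  expect_true(all(diff(scan$ror) <= 1e-12))
  expect_true(all(scan$ror_lo <= scan$ror & scan$ror <= scan$ror_hi))
  expect_true(all(scan$ic025 <= scan$ic))
  expect_true(all(scan$ebgm05 <= scan$ebgm))

  # permuting input record order leaves the scan identical
  bd2 <- bd
  set.seed(2)
  bd2$reac <- bd2$reac[sample(nrow(bd2$reac)), ]
  bd2$drug <- bd2$drug[sample(nrow(bd2$drug)), ]
  scan2 <- pt_scan(bd2, match_drug(bd2$drug, ai_lexicon(), "anastrozole"),
                   drug = "anastrozole")
  expect_equal(as.data.frame(scan2), as.data.frame(scan))
})

test_that("a null universe yields few false-positive PT signals", {
  sim <- generate_bundle(default_ai_config(n_reports = 20000, seed = 44,
                                           planted_ror = 1))
  bd <- dedup_bundle(sim$bundle)
  m <- match_drug(bd$drug, ai_lexicon(), "anastrozole")
  scan <- pt_scan(bd, m, drug = "anastrozole")
  expect_lt(mean(scan$is_signal), 0.10)
})
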