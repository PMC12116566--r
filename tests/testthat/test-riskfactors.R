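design_bundle <- function() {
  # 6 reports on one drug: mixtures of outcomes/covariates incl. missing wt
  demo <- tibble::tibble(
    primaryid = 1:6, caseid = 1:6,
    fda_dt = 20200101L, event_dt = 20200101L,
    sex = "F",
    age = c(70, 64, 65, 40, 80, 55),
    age_cod = "YR",
    wt = c(65, 45, 70, 120, NA, 80), wt_cod = "KG",
    occp_cod = "MD", reporter_country = "US"
  )
  drug <- tibble::tibble(primaryid = 1:6, caseid = 1:6, drug_seq = 1L,
                         role_cod = "PS", drugname = "Arimidex",
                         prod_ai = "ANASTROZOLE")
  reac <- tibble::tibble(primaryid = 1:6, caseid = 1:6, pt = "Alopecia")
  ther <- tibble::tibble(primaryid = integer(), caseid = integer(),
                         dsg_drug_seq = integer(), start_dt = integer(),
                         end_dt = integer())
  outc <- tibble::tibble(primaryid = c(1L, 4L), caseid = c(1L, 4L),
                         outc_cod = c("HO", "HO"))
  faers_bundle(demo, drug, reac, ther, outc, "TEST")
}

test_that("the regression design bands covariates and drops incomplete reports", {
  bundle <- design_bundle()
  expect_message(
    des <- build_design(bundle, drug_ids = 1:6, derm_ids = c(1L, 2L)),
    "1 incomplete")
  expect_equal(nrow(des), 5)                       # report 5 missing weight
  r1 <- des[des$primaryid == 1, ]
  expect_equal(unlist(r1[c("outcome", "hospitalized", "age_ge65", "weight_extreme")]),
               c(outcome = 1L, hospitalized = 1L, age_ge65 = 1L,
                 weight_extreme = 0L))
  expect_equal(des$age_ge65[des$primaryid == 3], 1L)  # age exactly 65 -> >=65
  expect_equal(des$age_ge65[des$primaryid == 2], 0L)
  expect_equal(des$weight_extreme[des$primaryid == 2], 1L) # 45 kg < 50
  expect_equal(des$weight_extreme[des$primaryid == 4], 1L) # 120 kg > 100
})

test_that("a single-covariate fit reproduces the closed-form 2x2 odds ratio", {
  # outcome x covariate counts: (20, 80, 10, 90)
  rows <- tibble::tibble(
    outcome = rep(c(1L, 1L, 0L, 0L), c(20, 10, 80, 90)),
    exposed = rep(c(1L, 0L, 1L, 0L), c(20, 10, 80, 90))
  )
  fit <- fit_logistic(rows)
  td <- tidy(fit)
  or_hat <- td$or[td$term == "exposed"]
  expect_equal(or_hat, (20 * 90) / (80 * 10), tolerance = 1e-8)
  # Woolf SE of the log odds ratio
  woolf <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  expect_equal(td$std.error[td$term == "exposed"], woolf, tolerance = 1e-8)
})

test_that("IRLS agrees with glm and its deviance never increases", {
  set.seed(6)
  n <- 2000
  x1 <- rbinom(n, 1, 0.3); x2 <- rbinom(n, 1, 0.5); x3 <- rbinom(n, 1, 0.2)
  eta <- -1 + 0.8 * x1 - 0.5 * x2 + 0.3 * x3
  y <- rbinom(n, 1, plogis(eta))
  rows <- tibble::tibble(outcome = y, x1 = x1, x2 = x2, x3 = x3)
  fit <- fit_logistic(rows)
  ref <- glm(y ~ x1 + x2 + x3, family = binomial())
  expect_equal(unname(tidy(fit)$estimate), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$deviance, unname(ref$deviance), tolerance = 1e-9)
  expect_true(all(diff(fit$deviance_trace) <= 1e-10))
  expect_true(fit$converged)
  g <- glance(fit)
  expect_equal(g$n, n)
})

test_that("flipping the outcome flips every coefficient's sign", {
  set.seed(7)
  rows <- tibble::tibble(
    outcome = rbinom(500, 1, 0.4),
    a = rbinom(500, 1, 0.5), b = rbinom(500, 1, 0.3)
  )
  f1 <- fit_logistic(rows)
  f2 <- fit_logistic(dplyr::mutate(rows, outcome = 1L - outcome))
  expect_equal(tidy(f2)$estimate, -tidy(f1)$estimate, tolerance = 1e-7)
})

test_that("an independent covariate's CI covers 1 on a balanced null", {
  set.seed(8)
  n <- 10000
  rows <- tibble::tibble(outcome = rbinom(n, 1, 0.3), z = rbinom(n, 1, 0.5))
  td <- tidy(fit_logistic(rows))
  expect_true(td$conf.low[td$term == "z"] < 1 && 1 < td$conf.high[td$term == "z"])
})

test_that("separation and singular designs raise explicit errors", {
  sep <- tibble::tibble(outcome = rep(c(0L, 1L), each = 50),
                        x = rep(c(0L, 1L), each = 50))
  expect_error(fit_logistic(sep), "separation")

  sing <- tibble::tibble(outcome = rbinom(100, 1, 0.5),
                         u = rep(1L, 100)) # collinear with the intercept
  expect_error(fit_logistic(sing), "collinear|singular")

  onecls <- tibble::tibble(outcome = rep(1L, 30), x = rbinom(30, 1, 0.5))
  expect_error(fit_logistic(onecls), "both classes")
})

test_that("risk_table reports reference/alternative counts with the fitted ORs", {
  set.seed(9)
  n <- 1500
  rows <- tibble::tibble(
    primaryid = seq_len(n),
    outcome = rbinom(n, 1, 0.3),
    hospitalized = rbinom(n, 1, 0.25),
    age_ge65 = rbinom(n, 1, 0.5)
  )
  fit <- fit_logistic(rows)
  rt <- risk_table(fit)
  expect_equal(rt$covariate, c("hospitalized", "age_ge65"))
  expect_equal(rt$n_ref + rt$n_alt, rep(n, 2))
  expect_equal(rt$n_alt, c(sum(rows$hospitalized), sum(rows$age_ge65)))
  expect_equal(rt$or, tidy(fit)$or[-1])
})
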