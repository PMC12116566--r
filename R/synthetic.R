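# Synthetic FAERS-like quarter generator. Every downstream stage (dedup,
# cohort extraction, disproportionality, TTO, regression) is validated
# against bundles produced here, where the ground truth is known exactly.

#' Build a simulation configuration
#'
#' Describes one synthetic reporting stream: marginal reporting
#' probabilities per drug and per preferred term (PT), planted drug-event
#' associations with a target odds ratio, a duplicate-report rate, date
#' error/missingness rates, demographic mixes and Weibull onset clocks.
#'
#' @param n_reports Number of base reports (before duplicate re-emission).
#' @param drug_catalog Tibble with columns `generic` (string), `brands`
#'   (list-column of character vectors), `target` (logical: gets role PS,
#'   otherwise C), `prob` (marginal reporting probability).
#' @param pt_catalog Tibble with columns `pt`, `soc_code` (integer),
#'   `soc_name`, `prob`.
#' @param planted_signals Tibble with columns `drug`, `pt`, `ror`
#'   (target odds ratio of the generating 2x2, > 0). Each drug and each PT
#'   may appear in at most one planted pair.
#' @param onset_models Tibble with columns `drug`, `pt`, `shape`, `scale`:
#'   reports carrying the pair receive an event date `start + Weibull(shape,
#'   scale)` days after therapy start.
#' @param duplicate_rate Fraction of base reports re-emitted as a later
#'   version of the same case (same CASEID, new PRIMARYID, later FDA_DT).
#' @param bad_date_rate Fraction of therapy start dates shifted to after
#'   the event date (the erroneous-date pattern real FAERS contains).
#' @param partial_date_rate Fraction of event dates degraded to YYYYMM
#'   precision.
#' @param missing_rate Named list of per-field missingness probabilities
#'   (`age`, `wt`, `sex`, `occp`, `country`, `event_dt`, `start_dt`).
#' @param sex_mix Named probabilities over `F`, `M`, `UNK`.
#' @param age_mixture Tibble mixture of normals (`weight`, `mean`, `sd`),
#'   in years, truncated to (0, 100].
#' @param weight_meanlog,weight_sdlog Log-normal body-weight parameters (kg).
#' @param outcome_probs Named probabilities over outcome codes `DE`, `DS`,
#'   `HO`, `LT`, `OT`, `RI` and `none` (no OUTC row).
#' @param seed Integer seed; a fixed seed reproduces the bundle bit-for-bit.
#' @return An object of class `sim_config`.
#' @seealso [default_ai_config()], [generate_bundle()]
#' @export
sim_config <- function(n_reports, drug_catalog, pt_catalog,
                       planted_signals = tibble(drug = character(), pt = character(), ror = numeric()),
                       onset_models = tibble(drug = character(), pt = character(), shape = numeric(), scale = numeric()),
                       duplicate_rate = 0.05, bad_date_rate = 0.02,
                       partial_date_rate = 0.01,
                       missing_rate = list(age = 0.30, wt = 0.32, sex = 0.025,
                                           occp = 0.09, country = 0.025,
                                           event_dt = 0.15, start_dt = 0.25),
                       sex_mix = c(F = 0.967, M = 0.008, UNK = 0.025),
                       age_mixture = tibble(weight = c(0.97, 0.02, 0.01),
                                            mean = c(66, 35, 10), sd = c(11, 7, 4)),
                       weight_meanlog = log(68), weight_sdlog = 0.18,
                       outcome_probs = c(DE = 0.0519, DS = 0.0344, HO = 0.2253,
                                         LT = 0.0295, OT = 0.4926, RI = 0.0045,
                                         none = 0.1618),
                       seed = 1L) {
  stopifnot(n_reports >= 1, nrow(drug_catalog) > 0, nrow(pt_catalog) > 0)
  stopifnot(all(drug_catalog$prob > 0 & drug_catalog$prob < 1))
  stopifnot(all(pt_catalog$prob > 0 & pt_catalog$prob < 1))
  stopifnot(duplicate_rate >= 0, duplicate_rate < 1,
            bad_date_rate >= 0, bad_date_rate < 1)
  stopifnot(all(unlist(missing_rate) >= 0), all(unlist(missing_rate) < 1))
  if (nrow(planted_signals) > 0) {
    stopifnot(all(planted_signals$ror > 0))
    if (anyDuplicated(planted_signals$drug) || anyDuplicated(planted_signals$pt)) {
      abort("each drug and each PT may appear in at most one planted pair")
    }
    bad <- setdiff(planted_signals$drug, drug_catalog$generic)
    if (length(bad)) abort(sprintf("planted drug not in catalog: %s", bad[1]))
    bad <- setdiff(planted_signals$pt, pt_catalog$pt)
    if (length(bad)) abort(sprintf("planted PT not in catalog: %s", bad[1]))
  }
  structure(
    list(n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
         pt_catalog = pt_catalog, planted_signals = planted_signals,
         onset_models = onset_models, duplicate_rate = duplicate_rate,
         bad_date_rate = bad_date_rate, partial_date_rate = partial_date_rate,
         missing_rate = missing_rate, sex_mix = sex_mix,
         age_mixture = age_mixture, weight_meanlog = weight_meanlog,
         weight_sdlog = weight_sdlog, outcome_probs = outcome_probs,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default aromatase-inhibitor simulation world
#'
#' A reporting stream shaped like the dermatologic adverse-event cohorts
#' seen for third-generation aromatase inhibitors: the three AI generics
#' with their brand names (anastrozole/Arimidex, exemestane/Aromasin,
#' letrozole/Femara), a dermatologic PT catalog mapped to system organ
#' class 10040785 plus non-dermatologic background PTs, a heavily female
#' demographic (~97%) with ages centred near 66 years and body weight with
#' median ~68 kg, and one planted pair — anastrozole with alopecia at odds
#' ratio 5, with a Weibull(shape 1.5, scale 60 days) onset clock.
#'
#' @param n_reports Number of base reports (default 20000).
#' @param seed Integer seed.
#' @param planted_ror Odds ratio of the planted anastrozole-alopecia pair
#'   (set to 1 for a null stream).
#' @return A `sim_config`.
#' @export
default_ai_config <- function(n_reports = 20000, seed = 1L, planted_ror = 5) {
  drug_catalog <- tibble(
    generic = c("anastrozole", "exemestane", "letrozole",
                "tamoxifen", "metformin", "atorvastatin", "ibuprofen",
                "lisinopril", "acetaminophen"),
    brands = list(c("Arimidex"), c("Aromasin"), c("Femara"),
                  c("Nolvadex"), c("Glucophage"), c("Lipitor"),
                  c("Advil", "Motrin"), c("Zestril"), c("Tylenol")),
    target = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    prob = c(0.05, 0.02, 0.04, 0.04, 0.06, 0.06, 0.08, 0.05, 0.10)
  )
  derm <- tibble(
    pt = c("Alopecia", "Rash", "Pruritus", "Urticaria", "Erythema",
           "Dry skin", "Hyperhidrosis", "Night sweats", "Nail disorder",
           "Onychoclasis", "Skin ulcer", "Dermatitis bullous",
           "Rash maculo-papular", "Angioedema", "Rash pruritic",
           "Hair growth abnormal", "Anhidrosis", "Pseudo cellulitis",
           "Nail toxicity"),
    soc_code = 10040785L,
    soc_name = "Skin and subcutaneous tissue disorders",
    prob = c(0.010, 0.012, 0.008, 0.006, 0.005, 0.004, 0.004, 0.003, 0.002,
             0.0015, 0.0015, 0.001, 0.002, 0.002, 0.0015, 0.001, 0.0005,
             0.0005, 0.0008)
  )
  background <- tibble(
    pt = c("Nausea", "Vomiting", "Diarrhoea", "Headache", "Dizziness",
           "Fatigue", "Arthralgia", "Dyspnoea", "Anaemia", "Insomnia"),
    soc_code = c(10017947L, 10017947L, 10017947L, 10029205L, 10029205L,
                 10018065L, 10028395L, 10038738L, 10005329L, 10037175L),
    soc_name = c("Gastrointestinal disorders", "Gastrointestinal disorders",
                 "Gastrointestinal disorders", "Nervous system disorders",
                 "Nervous system disorders",
                 "General disorders and administration site conditions",
                 "Musculoskeletal and connective tissue disorders",
                 "Respiratory, thoracic and mediastinal disorders",
                 "Blood and lymphatic system disorders",
                 "Psychiatric disorders"),
    prob = c(0.05, 0.02, 0.03, 0.04, 0.03, 0.05, 0.03, 0.02, 0.01, 0.02)
  )
  sim_config(
    n_reports = n_reports,
    drug_catalog = drug_catalog,
    pt_catalog = bind_rows(derm, background),
    planted_signals = tibble(drug = "anastrozole", pt = "Alopecia",
                             ror = planted_ror),
    onset_models = tibble(drug = "anastrozole", pt = "Alopecia",
                          shape = 1.5, scale = 60),
    seed = seed
  )
}

#' Solve the joint cell of a 2x2 from its marginals and odds ratio
#'
#' Given P(drug) = `pd`, P(event) = `pe` and a target odds ratio `psi`,
#' returns the joint probability P(drug & event) of the unique 2x2
#' distribution with those margins and that odds ratio (Plackett's
#' closed form; the product `pd * pe` when `psi` is 1).
#'
#' @param pd,pe Marginal probabilities in (0, 1).
#' @param psi Target odds ratio (> 0).
#' @return The joint probability `p11`.
#' @examples
#' p11 <- solve_joint_or(0.05, 0.01, 5)
#' p10 <- 0.05 - p11; p01 <- 0.01 - p11; p00 <- 1 - 0.05 - 0.01 + p11
#' (p11 * p00) / (p10 * p01) # 5
#' @export
solve_joint_or <- function(pd, pe, psi) {
  stopifnot(pd > 0, pd < 1, pe > 0, pe < 1, psi > 0)
  if (abs(psi - 1) < 1e-12) return(pd * pe)
  s <- 1 + (pd + pe) * (psi - 1)
  disc <- s^2 - 4 * psi * (psi - 1) * pd * pe
  if (disc < 0) abort("infeasible odds ratio for the given marginals")
  p11 <- (s - sqrt(disc)) / (2 * (psi - 1))
  lo <- max(0, pd + pe - 1)
  hi <- min(pd, pe)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    abort(sprintf("infeasible joint probability (p11 = %.4g outside [%.4g, %.4g])",
                  p11, lo, hi))
  }
  min(max(p11, lo), hi)
}

# Expected pre-duplication contingency table for each planted pair
planted_truth <- function(config) {
  ps <- config$planted_signals
  if (nrow(ps) == 0) {
    return(tibble(drug = character(), pt = character(), ror = numeric(),
                  p11 = numeric(), a = numeric(), b = numeric(),
                  c = numeric(), d = numeric(),
                  shape = numeric(), scale = numeric()))
  }
  n <- config$n_reports
  ps %>%
    left_join(select(config$drug_catalog, generic, pd = "prob"),
              by = c(drug = "generic")) %>%
    left_join(select(config$pt_catalog, pt, pe = "prob"), by = "pt") %>%
    mutate(p11 = purrr::pmap_dbl(list(.data$pd, .data$pe, .data$ror), solve_joint_or),
           a = n * .data$p11,
           b = n * (.data$pd - .data$p11),
           c = n * (.data$pe - .data$p11),
           d = n * (1 - .data$pd - .data$pe + .data$p11)) %>%
    left_join(select(config$onset_models, "drug", "pt", "shape", "scale"),
              by = c("drug", "pt")) %>%
    select("drug", "pt", "ror", "p11", "a", "b", "c", "d", "shape", "scale")
}

# helper: random spelling of a drug mention (generic or brand, random case)
random_spelling <- function(names_pool, k) {
  nm <- sample(names_pool, k, replace = TRUE)
  style <- sample(3, k, replace = TRUE)
  out <- nm
  out[style == 1] <- toupper(nm[style == 1])
  out[style == 2] <- tolower(nm[style == 2])
  out
}

#' Generate a synthetic FAERS-like quarter bundle
#'
#' Draws `n_reports` base reports: per-report drug and PT presence from the
#' catalog marginals, with each planted pair drawn jointly from the 2x2
#' distribution whose odds ratio equals the pair's `ror` (so the planted
#' truth is exact, not approximate); therapy start and event dates with a
#' configurable fraction of erroneous (start after event), partial and
#' missing dates; Weibull onset clocks for pairs with an onset model; and a
#' `duplicate_rate` fraction of cases re-emitted under a new PRIMARYID with
#' a later FDA_DT. Drug mentions are written under a randomly chosen
#' generic or brand spelling with randomised case; target drugs get role
#' PS, co-medications role C.
#'
#' @param config A [sim_config()].
#' @return A list with elements `bundle` (a [faers_bundle()]) and `truth`
#'   (tibble: per planted pair the exact generating cell probabilities,
#'   expected pre-duplication contingency counts `a`, `b`, `c`, `d`, the
#'   planted odds ratio and the onset Weibull parameters).
#' @examples
#' sim <- generate_bundle(default_ai_config(n_reports = 500, seed = 42))
#' sim$bundle
#' sim$truth
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  mr <- config$missing_rate

  drugs <- config$drug_catalog
  pts <- config$pt_catalog
  nd <- nrow(drugs); np <- nrow(pts)

  # --- presence matrices ----------------------------------------------------
  drug_pres <- matrix(runif(n * nd) < rep(drugs$prob, each = n), n, nd)
  pt_pres <- matrix(runif(n * np) < rep(pts$prob, each = n), n, np)
  colnames(drug_pres) <- drugs$generic
  colnames(pt_pres) <- pts$pt

  ps <- config$planted_signals
  if (nrow(ps) > 0) {
    for (i in seq_len(nrow(ps))) {
      di <- match(ps$drug[i], drugs$generic)
      pi <- match(ps$pt[i], pts$pt)
      p11 <- solve_joint_or(drugs$prob[di], pts$prob[pi], ps$ror[i])
      pd <- drugs$prob[di]; pe <- pts$prob[pi]
      cell <- sample.int(4, n, replace = TRUE,
                         prob = c(p11, pd - p11, pe - p11, 1 - pd - pe + p11))
      drug_pres[, di] <- cell %in% c(1L, 2L)
      pt_pres[, pi] <- cell %in% c(1L, 3L)
    }
  }

  # every report needs >= 1 drug and >= 1 PT; fall back to a background
  # (non-planted) catalog entry so planted contingencies stay exact
  bg_drugs <- setdiff(seq_len(nd), match(ps$drug, drugs$generic))
  bg_pts <- setdiff(seq_len(np), match(ps$pt, pts$pt))
  no_drug <- which(rowSums(drug_pres) == 0)
  if (length(no_drug) > 0) {
    pick <- sample(bg_drugs, length(no_drug), replace = TRUE,
                   prob = drugs$prob[bg_drugs])
    drug_pres[cbind(no_drug, pick)] <- TRUE
  }
  no_pt <- which(rowSums(pt_pres) == 0)
  if (length(no_pt) > 0) {
    pick <- sample(bg_pts, length(no_pt), replace = TRUE, prob = pts$prob[bg_pts])
    pt_pres[cbind(no_pt, pick)] <- TRUE
  }

  # --- demographics ---------------------------------------------------------
  primaryid <- 100000L + seq_len(n)
  caseid <- 10000L + seq_len(n)

  sex <- sample(names(config$sex_mix), n, replace = TRUE, prob = config$sex_mix)
  sex[runif(n) < mr$sex] <- NA

  comp <- sample.int(nrow(config$age_mixture), n, replace = TRUE,
                     prob = config$age_mixture$weight)
  age_yr <- rnorm(n, config$age_mixture$mean[comp], config$age_mixture$sd[comp])
  age_yr <- pmin(pmax(age_yr, 0.5), 100)
  age <- age_yr
  age_cod <- rep("YR", n)
  u <- runif(n)
  mon <- u < 0.01
  dy <- u >= 0.01 & u < 0.015
  age[mon] <- round(age_yr[mon] * 12); age_cod[mon] <- "MON"
  age[dy] <- round(age_yr[dy] * 365.25); age_cod[dy] <- "DY"
  age <- round(age, 1)
  miss <- runif(n) < mr$age
  age[miss] <- NA; age_cod[miss] <- NA

  wt_kg <- exp(rnorm(n, config$weight_meanlog, config$weight_sdlog))
  wt <- round(wt_kg, 1)
  wt_cod <- rep("KG", n)
  lbs <- runif(n) < 0.2
  wt[lbs] <- round(wt_kg[lbs] / 0.453592, 1); wt_cod[lbs] <- "LBS"
  miss <- runif(n) < mr$wt
  wt[miss] <- NA; wt_cod[miss] <- NA

  occp <- sample(c("CN", "MD", "PH", "OT"), n, replace = TRUE,
                 prob = c(0.25, 0.48, 0.06, 0.21))
  occp[runif(n) < mr$occp] <- NA
  country <- sample(c("US", "JP", "GB", "FR", "DE", "CN", "IT", "CA"), n,
                    replace = TRUE,
                    prob = c(0.27, 0.12, 0.12, 0.11, 0.11, 0.10, 0.09, 0.08))
  country[runif(n) < mr$country] <- NA

  # --- dates ----------------------------------------------------------------
  start_date <- as.Date("2023-01-01") + sample.int(270, n, replace = TRUE) - 1

  onset_days <- rep(NA_real_, n)
  om <- config$onset_models
  if (nrow(om) > 0) {
    for (i in seq_len(nrow(om))) {
      di <- match(om$drug[i], drugs$generic)
      pi <- match(om$pt[i], pts$pt)
      if (is.na(di) || is.na(pi)) next
      idx <- which(drug_pres[, di] & pt_pres[, pi] & is.na(onset_days))
      if (length(idx) > 0) {
        onset_days[idx] <- pmax(1, ceiling(rweibull(length(idx), om$shape[i],
                                                    om$scale[i])))
      }
    }
  }
  lag <- sample.int(90, n, replace = TRUE)
  event_offset <- ifelse(is.na(onset_days), lag, onset_days)
  event_date <- start_date + event_offset
  fda_date <- event_date + sample.int(90, n, replace = TRUE) + 4

  event_dt <- date_to_ymd(event_date)
  part <- runif(n) < config$partial_date_rate
  event_dt[part] <- event_dt[part] %/% 100L # degrade to YYYYMM
  event_dt[runif(n) < mr$event_dt] <- NA

  # erroneous dates: therapy start recorded after the event
  bad <- runif(n) < config$bad_date_rate
  start_date[bad] <- event_date[bad] + sample.int(30, sum(bad), replace = TRUE)
  start_dt <- date_to_ymd(start_date)
  start_missing <- runif(n) < mr$start_dt

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_to_ymd(fda_date), event_dt = event_dt,
    sex = sex, age = age, age_cod = age_cod, wt = wt, wt_cod = wt_cod,
    occp_cod = occp, reporter_country = country
  )

  # --- DRUG and THER --------------------------------------------------------
  hits <- which(drug_pres, arr.ind = TRUE)
  drug_rows <- tibble(report = hits[, 1], drug_idx = hits[, 2]) %>%
    mutate(target = drugs$target[.data$drug_idx]) %>%
    arrange(.data$report, desc(.data$target), .data$drug_idx) %>%
    group_by(.data$report) %>%
    mutate(drug_seq = row_number()) %>%
    ungroup()
  pool <- purrr::map2(drugs$generic, drugs$brands, ~ c(.x, .y))
  spelling <- character(nrow(drug_rows))
  for (j in seq_len(nd)) {
    idx <- which(drug_rows$drug_idx == j)
    if (length(idx) > 0) spelling[idx] <- random_spelling(pool[[j]], length(idx))
  }
  prod_ai <- toupper(drugs$generic[drug_rows$drug_idx])
  prod_ai[runif(nrow(drug_rows)) < 0.1] <- NA

  drug_tab <- tibble(
    primaryid = primaryid[drug_rows$report],
    caseid = caseid[drug_rows$report],
    drug_seq = drug_rows$drug_seq,
    role_cod = if_else(drug_rows$target, "PS", "C"),
    drugname = spelling,
    prod_ai = prod_ai
  )

  ther_tab <- tibble(
    primaryid = primaryid[drug_rows$report],
    caseid = caseid[drug_rows$report],
    dsg_drug_seq = drug_rows$drug_seq,
    start_dt = if_else(start_missing[drug_rows$report], NA_integer_,
                       start_dt[drug_rows$report]),
    end_dt = NA_integer_
  )

  # --- REAC -----------------------------------------------------------------
  phits <- which(pt_pres, arr.ind = TRUE)
  reac_tab <- tibble(
    primaryid = primaryid[phits[, 1]],
    caseid = caseid[phits[, 1]],
    pt = pts$pt[phits[, 2]]
  ) %>% arrange(.data$primaryid, .data$pt)

  # --- OUTC -----------------------------------------------------------------
  oc <- sample(names(config$outcome_probs), n, replace = TRUE,
               prob = config$outcome_probs)
  keep <- oc != "none"
  outc_tab <- tibble(primaryid = primaryid[keep], caseid = caseid[keep],
                     outc_cod = oc[keep])

  # --- duplicate re-emission ------------------------------------------------
  dup <- which(rbinom(n, 1, config$duplicate_rate) == 1)
  if (length(dup) > 0) {
    dup_pids <- primaryid[dup]
    new_pid <- max(primaryid) + seq_along(dup)
    map <- setNames(new_pid, dup_pids)
    demo_dup <- demo[dup, ] %>%
      mutate(primaryid = new_pid,
             fda_dt = date_to_ymd(ymd_to_date(.data$fda_dt) +
                                    sample.int(60, length(dup), replace = TRUE)))
    redo <- function(tab) {
      sub <- tab[tab$primaryid %in% dup_pids, ]
      sub$primaryid <- unname(map[as.character(sub$primaryid)])
      sub
    }
    demo <- bind_rows(demo, demo_dup)
    drug_tab <- bind_rows(drug_tab, redo(drug_tab))
    reac_tab <- bind_rows(reac_tab, redo(reac_tab))
    ther_tab <- bind_rows(ther_tab, redo(ther_tab))
    outc_tab <- bind_rows(outc_tab, redo(outc_tab))
  }

  bundle <- faers_bundle(demo, drug_tab, reac_tab, ther_tab, outc_tab,
                         quarter_label = sprintf("SIM-seed%d", config$seed))
  list(bundle = bundle, truth = planted_truth(config))
}
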