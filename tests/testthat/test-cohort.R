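test_that("drug matching accepts brands, normalizes spelling and filters roles", {
  bundle <- tiny_bundle()
  lex <- ai_lexicon()
  # ARIMIDEX (brand, uppercase) and "anastrozole." (trailing punctuation)
  expect_equal(match_drug(bundle$drug, lex, "anastrozole"), c(1L, 2L))
  expect_equal(match_drug(bundle$drug, lex, "letrozole"), 3L)
  # concomitant-only roles are excluded
  drug_c <- dplyr::mutate(bundle$drug, role_cod = "C")
  expect_length(match_drug(drug_c, lex, "anastrozole", roles = c("PS", "SS")), 0)
  expect_error(match_drug(bundle$drug, lex, "aspirin"), "not in lexicon")
})

test_that("SOC filtering uses any-match semantics and ignores unknown PTs", {
  bundle <- tiny_bundle()
  md <- derm_meddra()
  # report 1 has Alopecia (derm) + Nausea; report 3 only Nausea
  expect_equal(filter_soc(bundle$reac, md, 10040785L), c(1L, 2L))
  reac_unknown <- tibble::tibble(primaryid = 1L, caseid = 11L,
                                 pt = "Totally novel PT")
  expect_message(out <- filter_soc(reac_unknown, md, 10040785L),
                 "absent from the dictionary")
  expect_length(out, 0)
  expect_error(filter_soc(bundle$reac, md, 99L), "not present")
})

test_that("case records convert units and intersect drug with SOC", {
  bundle <- tiny_bundle()
  lex <- ai_lexicon()
  matched <- match_drug(bundle$drug, lex, "anastrozole")
  derm <- filter_soc(bundle$reac, derm_meddra(), 10040785L)
  cases <- build_cases(bundle, matched, derm, lex, "anastrozole")
  expect_equal(cases$primaryid, c(1L, 2L))      # report 3: matched drug absent
  expect_equal(cases$age_years, c(66, 792 / 12))  # 792 MON -> 66 years
  expect_equal(cases$weight_kg, c(70, 150 * 0.453592), tolerance = 1e-6)
  expect_equal(round(cases$weight_kg[2], 2), 68.04)
  expect_equal(cases$pts[[1]], "Alopecia")
  expect_equal(cases$therapy_start_dt, c(20191201L, 20200115L))
  expect_setequal(cases$outcomes[[1]], "HO")
})

test_that("unit conversion treats unknown codes as missing", {
  expect_equal(age_to_years(c(66, 792, 730.5, 50), c("YR", "MON", "DY", "XX")),
               c(66, 66, 2, NA))
  expect_equal(weight_to_kg(c(70, 150, 3), c("KG", "LBS", "GRAM")),
               c(70, 68.0388, NA))
})

test_that("characteristics reproduces printed-percentage arithmetic", {
  # stratum of 2237 cases with the sex margin 2164 F / 17 M / 56 unknown
  cases <- tibble::tibble(
    primaryid = seq_len(2237),
    drug = "anastrozole",
    pts = replicate(2237, "Alopecia", simplify = FALSE),
    sex = c(rep("F", 2164), rep("M", 17), rep(NA, 56)),
    age_years = NA_real_, weight_kg = NA_real_,
    occp_cod = NA_character_, reporter_country = NA_character_,
    outcomes = replicate(2237, character(), simplify = FALSE),
    event_dt = NA_integer_, therapy_start_dt = NA_integer_
  )
  ch <- characteristics(cases, strata = "all")
  sexrows <- ch[ch$block == "sex", ]
  expect_equal(sexrows$pct[sexrows$level == "Female"], 96.74)
  expect_equal(sexrows$pct[sexrows$level == "Male"], 0.76)
  expect_equal(sexrows$pct[sexrows$level == "Unknown"], 2.50)
})

test_that("percentages use half-up rounding and blocks sum to ~100", {
  expect_equal(pct(555, 725), 76.55)
  expect_equal(pct(1120, 2237), 50.07)
  expect_equal(pct(0, 10), 0)
  expect_equal(round_half_up(0.125, 2), 0.13) # half-up, not banker's

  sim <- generate_bundle(default_ai_config(n_reports = 4000, seed = 13))
  bd <- dedup_bundle(sim$bundle)
  m <- match_drug(bd$drug, ai_lexicon(), "anastrozole")
  derm <- filter_soc(bd$reac, derm_meddra(), 10040785L)
  cases <- build_cases(bd, m, derm, ai_lexicon(), "anastrozole")
  ch <- characteristics(cases)
  catrows <- ch[!is.na(ch$pct), ]
  sums <- dplyr::summarise(dplyr::group_by(catrows, stratum, block),
                           s = sum(pct), n = sum(n), total = total[1],
                           .groups = "drop")
  expect_true(all(abs(sums$s - 100) <= 0.02 + 1e-9))
  expect_true(all(sums$n == sums$total)) # counts partition every stratum
})

test_that("characteristics is permutation-invariant and matches a brute-force recount", {
  sim <- generate_bundle(default_ai_config(n_reports = 3000, seed = 17))
  bd <- dedup_bundle(sim$bundle)
  m <- match_drug(bd$drug, ai_lexicon(), "anastrozole")
  derm <- filter_soc(bd$reac, derm_meddra(), 10040785L)
  cases <- build_cases(bd, m, derm, ai_lexicon(), "anastrozole")

  set.seed(1)
  shuffled <- cases[sample(nrow(cases)), ]
  expect_equal(as.data.frame(characteristics(cases)),
               as.data.frame(characteristics(shuffled)))

  # independent recount straight off the raw records
  ch <- characteristics(cases, strata = "all")
  raw <- bd$demo[bd$demo$primaryid %in% cases$primaryid, ]
  n_female <- sum(raw$sex == "F", na.rm = TRUE)
  expect_equal(ch$n[ch$block == "sex" & ch$level == "Female"], n_female)
  age_yrs <- age_to_years(raw$age, raw$age_cod)
  expect_equal(ch$n[ch$block == "age_years" & ch$level == ">65"],
               sum(age_yrs > 65, na.rm = TRUE))
  expect_equal(ch$n[ch$block == "age_years" & ch$level == "Unknown"],
               sum(is.na(age_yrs)))
  ho <- bd$outc$primaryid[bd$outc$outc_cod == "HO"]
  de <- bd$outc$primaryid[bd$outc$outc_cod == "DE"]
  expect_equal(ch$n[ch$block == "outcome" & ch$level == "HO"],
               sum(cases$primaryid %in% ho & !cases$primaryid %in% de))
  expect_equal(ch$median[ch$block == "age_median_years"],
               median(age_yrs, na.rm = TRUE))
})
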