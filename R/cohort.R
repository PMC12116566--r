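# Cohort extraction: name-matched drug reports, restricted to a system
# organ class through a MedDRA-like stub dictionary, plus the descriptive
# characteristics table.

#' Normalize a drug or PT name for matching
#'
#' Lowercases, trims surrounding whitespace and strips trailing
#' punctuation, so `"ARIMIDEX."` matches `"Arimidex"`. Matching is exact on
#' the normalized string, never substring.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_name <- function(x) {
  x <- stringr::str_trim(tolower(x))
  stringr::str_remove(x, "[[:punct:][:space:]]+$")
}

#' Drug name lexicon for the three aromatase inhibitors
#'
#' Generic plus FDA-approved brand names: anastrozole (Arimidex),
#' exemestane (Aromasin), letrozole (Femara).
#'
#' @return Tibble with columns `generic`, `alias`.
#' @export
ai_lexicon <- function() {
  tibble(
    generic = c("anastrozole", "anastrozole", "exemestane", "exemestane",
                "letrozole", "letrozole"),
    alias = c("anastrozole", "Arimidex", "exemestane", "Aromasin",
              "letrozole", "Femara")
  )
}

#' MedDRA-like stub dictionary for the simulated world
#'
#' Maps each preferred term of [default_ai_config()] to its system organ
#' class; dermatologic PTs carry SOC code 10040785 ("Skin and subcutaneous
#' tissue disorders"). Real MedDRA is licensed and out of scope: any PT
#' absent from this stub is logged and ignored by [filter_soc()].
#'
#' @return Tibble with columns `pt`, `soc_code`, `soc_name`.
#' @export
derm_meddra <- function() {
  cfg <- suppressWarnings(default_ai_config(n_reports = 10))
  select(cfg$pt_catalog, "pt", "soc_code", "soc_name")
}

#' Read a two-column lexicon file
#'
#' Tab-delimited text, one alias per line: `generic<TAB>alias`.
#'
#' @param path File path.
#' @return Tibble with columns `generic`, `alias`.
#' @export
read_lexicon <- function(path) {
  readr::read_tsv(path, col_names = c("generic", "alias"),
                  col_types = "cc", progress = FALSE)
}

#' Read a MedDRA-like stub file
#'
#' Tab-delimited text: `pt<TAB>soc_code` with an optional third `soc_name`
#' column.
#'
#' @param path File path.
#' @return Tibble with columns `pt`, `soc_code` and (possibly `NA`)
#'   `soc_name`.
#' @export
read_meddra <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  out <- tibble(pt = df[[1]], soc_code = as.integer(df[[2]]))
  out$soc_name <- if (ncol(df) >= 3) df[[3]] else NA_character_
  out
}

#' Find reports mentioning a target drug
#'
#' Matches `drugname` or `prod_ai` against the lexicon aliases for the
#' target generic, case-insensitively after normalization
#' ([normalize_name()]), restricted to the given reporting roles.
#'
#' @param drug_records DRUG tibble.
#' @param lexicon Lexicon tibble (`generic`, `alias`), e.g. [ai_lexicon()].
#' @param target Generic name present in the lexicon.
#' @param roles Role codes to accept (default suspect roles `PS`, `SS`).
#' @return Sorted integer vector of matching `primaryid`s.
#' @export
match_drug <- function(drug_records, lexicon, target, roles = c("PS", "SS")) {
  if (!target %in% lexicon$generic) {
    abort(sprintf("target '%s' not in lexicon", target))
  }
  aliases <- normalize_name(lexicon$alias[lexicon$generic == target])
  hit <- drug_records %>%
    filter(.data$role_cod %in% roles) %>%
    filter(normalize_name(.data$drugname) %in% aliases |
             (!is.na(.data$prod_ai) & normalize_name(.data$prod_ai) %in% aliases))
  sort(unique(hit$primaryid))
}

#' Find reports with at least one PT in a system organ class
#'
#' @param reac_records REAC tibble.
#' @param meddra Stub dictionary tibble (`pt`, `soc_code`), e.g.
#'   [derm_meddra()].
#' @param soc_code Integer SOC code (dermatologic: 10040785).
#' @return Sorted integer vector of `primaryid`s having >= 1 PT mapped to
#'   `soc_code`. PTs absent from the dictionary are logged and ignored.
#' @export
filter_soc <- function(reac_records, meddra, soc_code) {
  if (!soc_code %in% meddra$soc_code) {
    abort(sprintf("SOC code %s not present in dictionary", soc_code))
  }
  key <- normalize_name(meddra$pt)
  idx <- match(normalize_name(reac_records$pt), key)
  unknown <- unique(reac_records$pt[is.na(idx)])
  if (length(unknown) > 0) {
    inform(sprintf("%d PT(s) absent from the dictionary ignored (e.g. '%s')",
                   length(unknown), unknown[1]))
  }
  hit <- !is.na(idx) & meddra$soc_code[idx] == soc_code
  sort(unique(reac_records$primaryid[hit]))
}

#' Convert reported age to years
#'
#' `YR` passes through, `MON` divides by 12, `DY` by 365.25. A missing unit
#' code with a present value is taken as years (the dominant FAERS
#' convention); an unrecognized unit code makes the value missing.
#'
#' @param age Numeric vector of reported ages.
#' @param age_cod Unit codes (`YR`, `MON`, `DY`, or `NA`).
#' @return Age in years.
#' @export
age_to_years <- function(age, age_cod) {
  dplyr::case_when(
    is.na(age) ~ NA_real_,
    is.na(age_cod) | age_cod == "YR" ~ age,
    age_cod == "MON" ~ age / 12,
    age_cod == "DY" ~ age / 365.25,
    TRUE ~ NA_real_
  )
}

#' Convert reported weight to kilograms
#'
#' `KG` passes through, `LBS` multiplies by 0.453592; missing unit with a
#' present value is taken as kg; unrecognized units make the value missing.
#'
#' @param wt Numeric vector of reported weights.
#' @param wt_cod Unit codes (`KG`, `LBS`, or `NA`).
#' @return Weight in kg.
#' @export
weight_to_kg <- function(wt, wt_cod) {
  dplyr::case_when(
    is.na(wt) ~ NA_real_,
    is.na(wt_cod) | wt_cod == "KG" ~ wt,
    wt_cod == "LBS" ~ wt * 0.453592,
    TRUE ~ NA_real_
  )
}

#' Build case records for a drug within a system organ class
#'
#' One row per report in `matched` (target-drug reports) intersected with
#' `derm` (reports carrying >= 1 PT of the SOC). Units are converted (age
#' to years, weight to kg); the therapy start date is the earliest valid
#' full-precision start among THER rows linked to the matched drug's
#' sequence numbers.
#'
#' @param bundle A deduplicated `faers_bundle`.
#' @param matched Primaryids from [match_drug()].
#' @param derm Primaryids from [filter_soc()].
#' @param lexicon Lexicon used for the match (to re-identify the drug's
#'   sequence numbers).
#' @param target Generic name of the matched drug.
#' @param meddra Stub dictionary; `soc_code` selects which PTs populate
#'   the `pts` list-column.
#' @param soc_code SOC restricting the `pts` column (default 10040785).
#' @return Tibble with one row per case: `primaryid`, `drug`, `pts`
#'   (list-column of PTs in the SOC), `sex`, `age_years`, `weight_kg`,
#'   `occp_cod`, `reporter_country`, `outcomes` (list-column of outcome
#'   codes), `event_dt`, `therapy_start_dt`.
#' @export
build_cases <- function(bundle, matched, derm, lexicon, target,
                        meddra = derm_meddra(), soc_code = 10040785L) {
  ids <- intersect(matched, derm)
  demo <- filter(bundle$demo, .data$primaryid %in% ids)
  if (nrow(demo) == 0) {
    return(tibble(primaryid = integer(), drug = character(), pts = list(),
                  sex = character(), age_years = numeric(),
                  weight_kg = numeric(), occp_cod = character(),
                  reporter_country = character(), outcomes = list(),
                  event_dt = integer(), therapy_start_dt = integer()))
  }

  key <- normalize_name(meddra$pt)
  soc_pts <- bundle$reac %>%
    filter(.data$primaryid %in% ids) %>%
    filter(meddra$soc_code[match(normalize_name(.data$pt), key)] %in% soc_code) %>%
    group_by(.data$primaryid) %>%
    summarise(pts = list(sort(unique(.data$pt))), .groups = "drop")

  aliases <- normalize_name(lexicon$alias[lexicon$generic == target])
  drug_seqs <- bundle$drug %>%
    filter(.data$primaryid %in% ids) %>%
    filter(normalize_name(.data$drugname) %in% aliases |
             (!is.na(.data$prod_ai) & normalize_name(.data$prod_ai) %in% aliases)) %>%
    select("primaryid", "drug_seq")
  starts <- bundle$ther %>%
    inner_join(drug_seqs, by = c("primaryid", dsg_drug_seq = "drug_seq")) %>%
    mutate(start_full = if_else(is_valid_ymd(.data$start_dt),
                                .data$start_dt, NA_integer_)) %>%
    filter(!is.na(.data$start_full)) %>%
    group_by(.data$primaryid) %>%
    summarise(therapy_start_dt = min(.data$start_full), .groups = "drop")

  outc <- bundle$outc %>%
    filter(.data$primaryid %in% ids) %>%
    group_by(.data$primaryid) %>%
    summarise(outcomes = list(sort(unique(.data$outc_cod))), .groups = "drop")

  demo %>%
    transmute(.data$primaryid, drug = target,
              sex = .data$sex,
              age_years = age_to_years(.data$age, .data$age_cod),
              weight_kg = weight_to_kg(.data$wt, .data$wt_cod),
              occp_cod = .data$occp_cod,
              reporter_country = .data$reporter_country,
              event_dt = .data$event_dt) %>%
    left_join(soc_pts, by = "primaryid") %>%
    left_join(outc, by = "primaryid") %>%
    left_join(starts, by = "primaryid") %>%
    mutate(pts = purrr::map(.data$pts, ~ .x %||% character()),
           outcomes = purrr::map(.data$outcomes, ~ .x %||% character())) %>%
    select("primaryid", "drug", "pts", "sex", "age_years", "weight_kg",
           "occp_cod", "reporter_country", "outcomes", "event_dt",
           "therapy_start_dt") %>%
    arrange(.data$primaryid)
}

# one outcome per case for the characteristics table: severity precedence
outcome_precedence <- c("DE", "LT", "HO", "DS", "RI", "OT")

primary_outcome <- function(outcomes) {
  purrr::map_chr(outcomes, function(x) {
    hit <- outcome_precedence[outcome_precedence %in% x]
    if (length(hit) == 0) "Unknown" else hit[1]
  })
}

band_weight <- function(w) {
  dplyr::case_when(
    is.na(w) ~ "Unknown",
    w < 80 ~ "<80",
    w <= 100 ~ "80-100",
    TRUE ~ ">100"
  )
}

band_age <- function(a) {
  dplyr::case_when(
    is.na(a) ~ "Unknown",
    a < 18 ~ "<18",
    a < 45 ~ "18-44",
    a <= 65 ~ "45-65",
    TRUE ~ ">65"
  )
}

count_block <- function(df, block, levels) {
  total <- nrow(df)
  tibble(block = block, level = levels) %>%
    mutate(n = purrr::map_int(.data$level, ~ sum(df$.value == .x)),
           pct = pct(.data$n, total))
}

characteristics_stratum <- function(cases, stratum) {
  total <- nrow(cases)
  sex_lv <- c(Female = "F", Male = "M")
  df <- cases %>%
    mutate(sexl = case_when(.data$sex == "F" ~ "Female",
                            .data$sex == "M" ~ "Male",
                            TRUE ~ "Unknown"),
           wband = band_weight(.data$weight_kg),
           aband = band_age(.data$age_years),
           occ = if_else(is.na(.data$occp_cod) |
                           !.data$occp_cod %in% c("CN", "MD", "PH", "OT"),
                         "Unknown", .data$occp_cod),
           region = case_when(is.na(.data$reporter_country) ~ "Unknown",
                              .data$reporter_country == "US" ~ "US",
                              TRUE ~ "Non-US"),
           outc1 = primary_outcome(.data$outcomes))
  blocks <- list(
    c(var = "sexl", block = "sex"),
    c(var = "wband", block = "weight_kg"),
    c(var = "aband", block = "age_years"),
    c(var = "occ", block = "occupation"),
    c(var = "region", block = "region"),
    c(var = "outc1", block = "outcome")
  )
  levels <- list(
    sex = c("Female", "Male", "Unknown"),
    weight_kg = c("<80", "80-100", ">100", "Unknown"),
    age_years = c("<18", "18-44", "45-65", ">65", "Unknown"),
    occupation = c("CN", "MD", "PH", "OT", "Unknown"),
    region = c("US", "Non-US", "Unknown"),
    outcome = c("DE", "DS", "HO", "LT", "OT", "RI", "Unknown")
  )
  cat_rows <- purrr::map_dfr(blocks, function(b) {
    df$.value <- df[[b[["var"]]]]
    count_block(df, b[["block"]], levels[[b[["block"]]]])
  })
  med_rows <- tibble(
    block = c("age_median_years", "weight_median_kg"),
    level = "median",
    n = c(sum(!is.na(df$age_years)), sum(!is.na(df$weight_kg))),
    pct = NA_real_,
    median = c(median(df$age_years, na.rm = TRUE),
               median(df$weight_kg, na.rm = TRUE)),
    min = c(suppressWarnings(min(df$age_years, na.rm = TRUE)),
            suppressWarnings(min(df$weight_kg, na.rm = TRUE))),
    max = c(suppressWarnings(max(df$age_years, na.rm = TRUE)),
            suppressWarnings(max(df$weight_kg, na.rm = TRUE)))
  )
  bind_rows(mutate(cat_rows, median = NA_real_, min = NA_real_, max = NA_real_),
            med_rows) %>%
    mutate(stratum = stratum, total = total) %>%
    select("stratum", "total", "block", "level", "n", "pct",
           "median", "min", "max")
}

#' Descriptive characteristics table
#'
#' Counts and half-up-rounded percentages per categorical block (sex,
#' weight and age bands, reporter occupation, US/non-US region, outcome
#' codes) and medians with min-max for age and weight — for the pooled
#' stratum `"All"` plus one stratum per drug. Within each block the counts
#' sum to the stratum total; a case with several outcome codes is counted
#' once under the most severe (DE > LT > HO > DS > RI > OT).
#'
#' @param cases Case tibble from [build_cases()] (several drugs may be
#'   concatenated with [dplyr::bind_rows()]).
#' @param strata `"all"`, `"drug"`, or both (default).
#' @return Tidy tibble: `stratum`, `total`, `block`, `level`, `n`, `pct`,
#'   `median`, `min`, `max`.
#' @export
characteristics <- function(cases, strata = c("all", "drug")) {
  stopifnot(nrow(cases) > 0)
  strata <- match.arg(strata, several.ok = TRUE)
  out <- list()
  if ("all" %in% strata) {
    out <- c(out, list(characteristics_stratum(cases, "All")))
  }
  if ("drug" %in% strata) {
    for (d in sort(unique(cases$drug))) {
      out <- c(out, list(characteristics_stratum(filter(cases, .data$drug == d), d)))
    }
  }
  res <- bind_rows(out)
  class(res) <- c("characteristics_table", class(res))
  res
}
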