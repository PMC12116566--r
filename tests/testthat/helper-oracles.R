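# Independent brute-force oracles, deliberately written along different
# arithmetic paths than the package implementation.

# odds ratio / proportional reporting ratio / Pearson chi2 via explicit
# expected-count loop on the 2x2
oracle_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  obs <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(obs), colSums(obs)) / n
  chi2 <- sum((obs - expected)^2 / expected)
  list(
    or = (a / b) / (c / d),
    prr = (a / (a + b)) / (c / (c + d)),
    chi2 = chi2
  )
}

# group-by dedup oracle: per case, scan records and keep the one winning on
# (padded fda_dt, then primaryid)
oracle_dedup <- function(demo) {
  keep <- integer(0)
  for (cid in unique(demo$caseid)) {
    sub <- demo[demo$caseid == cid, ]
    key <- pvsignal::pad_ymd(sub$fda_dt)
    key[is.na(key)] <- -1L
    best <- order(key, sub$primaryid, decreasing = TRUE)[1]
    keep <- c(keep, sub$primaryid[best])
  }
  sort(keep)
}

# tiny hand-built three-report bundle used across IO/cohort tests
tiny_bundle <- function() {
  demo <- tibble::tibble(
    primaryid = c(1L, 2L, 3L),
    caseid = c(11L, 12L, 13L),
    fda_dt = c(20200110L, 20200215L, 20200320L),
    event_dt = c(20200101L, 20200201L, 20200301L),
    sex = c("F", "F", "M"),
    age = c(66, 792, 70), age_cod = c("YR", "MON", "YR"),
    wt = c(70, 150, NA), wt_cod = c("KG", "LBS", NA),
    occp_cod = c("MD", "CN", NA),
    reporter_country = c("US", "FR", NA)
  )
  drug <- tibble::tibble(
    primaryid = c(1L, 1L, 2L, 3L),
    caseid = c(11L, 11L, 12L, 13L),
    drug_seq = c(1L, 2L, 1L, 1L),
    role_cod = c("PS", "C", "PS", "PS"),
    drugname = c("ARIMIDEX", "Tylenol", "anastrozole.", "Femara"),
    prod_ai = c("ANASTROZOLE", NA, "ANASTROZOLE", "LETROZOLE")
  )
  reac <- tibble::tibble(
    primaryid = c(1L, 1L, 2L, 3L),
    caseid = c(11L, 11L, 12L, 13L),
    pt = c("Alopecia", "Nausea", "Rash", "Nausea")
  )
  ther <- tibble::tibble(
    primaryid = c(1L, 2L, 3L),
    caseid = c(11L, 12L, 13L),
    dsg_drug_seq = c(1L, 1L, 1L),
    start_dt = c(20191201L, 20200115L, 20200310L),
    end_dt = c(NA_integer_, NA_integer_, NA_integer_)
  )
  outc <- tibble::tibble(
    primaryid = c(1L, 2L, 2L),
    caseid = c(11L, 12L, 12L),
    outc_cod = c("HO", "OT", "DE")
  )
  pvsignal::faers_bundle(demo, drug, reac, ther, outc, "TEST")
}
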