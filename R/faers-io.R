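# FAERS quarterly ASCII dialect: $-delimited text, one header row naming the
# columns, one record per line, no quoting. One canonical schema per table.

faers_schemas <- list(
  demo = list(
    cols = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
             "age_cod", "wt", "wt_cod", "occp_cod", "reporter_country"),
    required = c("primaryid", "caseid"),
    integer = c("primaryid", "caseid", "fda_dt", "event_dt"),
    double = c("age", "wt"),
    date = c("fda_dt", "event_dt")
  ),
  drug = list(
    cols = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    required = c("primaryid", "caseid", "drug_seq", "drugname"),
    integer = c("primaryid", "caseid", "drug_seq"),
    double = character(),
    date = character()
  ),
  reac = list(
    cols = c("primaryid", "caseid", "pt"),
    required = c("primaryid", "caseid", "pt"),
    integer = c("primaryid", "caseid"),
    double = character(),
    date = character()
  ),
  ther = list(
    cols = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
    required = c("primaryid", "caseid", "dsg_drug_seq"),
    integer = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
    double = character(),
    date = c("start_dt", "end_dt")
  ),
  outc = list(
    cols = c("primaryid", "caseid", "outc_cod"),
    required = c("primaryid", "caseid", "outc_cod"),
    integer = c("primaryid", "caseid"),
    double = character(),
    date = c()
  )
)

#' Read one FAERS-dialect table
#'
#' Parses a `$`-delimited FAERS quarterly ASCII table (header row, one record
#' per line, no quoting). Empty fields become `NA`. Date columns
#' (`fda_dt`, `event_dt`, `start_dt`, `end_dt`) are kept as YYYYMMDD
#' integers; values that are neither a valid calendar day nor a partial
#' YYYYMM / YYYY date are set to `NA` with a warning naming the column.
#'
#' @param path Path to the table file.
#' @param table_kind One of `"demo"`, `"drug"`, `"reac"`, `"ther"`, `"outc"`.
#' @return A tibble with the canonical columns for that table kind.
#' @seealso [write_faers_table()], [read_faers_bundle()]
#' @export
read_faers_table <- function(path, table_kind) {
  table_kind <- match.arg(tolower(table_kind), names(faers_schemas))
  sch <- faers_schemas[[table_kind]]
  df <- readr::read_delim(
    path, delim = "$", na = c("", "NA"), trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("malformed %s header: missing column(s) %s",
                  toupper(table_kind), paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(sch$cols, names(df))) df[[col]] <- NA_character_
  df <- df[sch$cols]
  for (col in sch$integer) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- !is.na(df[[col]]) & is.na(v)
    if (any(bad)) warn(sprintf("%s: %d non-numeric value(s) in '%s' set to NA",
                               toupper(table_kind), sum(bad), col))
    df[[col]] <- v
  }
  for (col in sch$double) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in sch$date) {
    x <- df[[col]]
    bad <- !is.na(x) & !is_valid_ymd(x) & !is_partial_ymd(x)
    if (any(bad)) {
      warn(sprintf("%s: %d unparseable date(s) in '%s' set to missing",
                   toupper(table_kind), sum(bad), col))
      df[[col]][bad] <- NA_integer_
    }
  }
  as_tibble(df)
}

#' Write one FAERS-dialect table
#'
#' Counterpart of [read_faers_table()]: `$`-delimited ASCII with a header
#' row; missing values are written as empty fields. Round-trips well-formed
#' tables byte-for-byte at the field level.
#'
#' @param df Tibble of records (canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(df, path) {
  readr::write_delim(df, path, delim = "$", na = "")
  invisible(path)
}

#' Assemble a quarter bundle of the five FAERS tables
#'
#' Validates the referential invariant: every `primaryid` appearing in the
#' DRUG / REAC / THER / OUTC tables must exist in DEMO.
#'
#' @param demo,drug,reac,ther,outc Tibbles as returned by
#'   [read_faers_table()].
#' @param quarter_label Label such as `"2020Q1"`.
#' @return An object of class `faers_bundle` (a named list of tibbles).
#' @export
faers_bundle <- function(demo, drug, reac, ther, outc, quarter_label = "SIM") {
  pid <- demo$primaryid
  if (anyDuplicated(pid) > 0) {
    # allowed pre-dedup; duplicates on primaryid itself are not
    abort("demo contains duplicated primaryid values")
  }
  for (nm in c("drug", "reac", "ther", "outc")) {
    tab <- get(nm)
    orphan <- setdiff(tab$primaryid, pid)
    if (length(orphan) > 0) {
      abort(sprintf("%s references %d primaryid(s) absent from demo (e.g. %s)",
                    toupper(nm), length(orphan), orphan[1]))
    }
  }
  structure(
    list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc,
         quarter_label = quarter_label),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat(sprintf("<faers_bundle %s>\n", x$quarter_label))
  for (nm in c("demo", "drug", "reac", "ther", "outc")) {
    cat(sprintf("  %-5s %7d rows\n", toupper(nm), nrow(x[[nm]])))
  }
  cat(sprintf("  %d distinct cases, %d reports\n",
              dplyr::n_distinct(x$demo$caseid), nrow(x$demo)))
  invisible(x)
}

#' Read a quarter bundle from a directory
#'
#' Expects the five files `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `THER.txt`,
#' `OUTC.txt` in `dir`.
#'
#' @param dir Directory holding the five tables.
#' @param quarter_label Label stored on the bundle.
#' @return A `faers_bundle`.
#' @export
read_faers_bundle <- function(dir, quarter_label = basename(dir)) {
  faers_bundle(
    demo = read_faers_table(file.path(dir, "DEMO.txt"), "demo"),
    drug = read_faers_table(file.path(dir, "DRUG.txt"), "drug"),
    reac = read_faers_table(file.path(dir, "REAC.txt"), "reac"),
    ther = read_faers_table(file.path(dir, "THER.txt"), "ther"),
    outc = read_faers_table(file.path(dir, "OUTC.txt"), "outc"),
    quarter_label = quarter_label
  )
}

#' Write a quarter bundle to a directory
#'
#' @param bundle A `faers_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_faers_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("demo", "drug", "reac", "ther", "outc")) {
    write_faers_table(bundle[[nm]], file.path(dir, paste0(toupper(nm), ".txt")))
  }
  invisible(dir)
}

#' FDA-recommended case-level deduplication
#'
#' A FAERS case (CASEID) accumulates report versions (PRIMARYID) over time.
#' Within each case only the report with the most recent FDA receipt date
#' (FDA_DT) is retained; ties on FDA_DT are broken by the highest PRIMARYID.
#' A missing FDA_DT always loses to any dated report of the same case
#' (treated as minus-infinity); partial dates (YYYYMM, YYYY) are padded with
#' 01 for this ordering only.
#'
#' @param demo DEMO tibble (must carry `caseid` on every record).
#' @return The kept DEMO records (one per case), with the dropped reports
#'   available via [dedup_dropped()] (attribute `"dropped"`: tibble of
#'   `primaryid`, `caseid`).
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c(11L, 10L, 12L), caseid = c(1L, 1L, 2L),
#'   fda_dt = c(20200101L, 20200301L, 20200105L)
#' )
#' dedup_reports(demo) # caseid 1 keeps primaryid 10 (later fda_dt)
#' @export
dedup_reports <- function(demo) {
  if (nrow(demo) > 0 && anyNA(demo$caseid)) {
    abort("deduplication requires caseid on every record")
  }
  ord <- demo %>%
    mutate(.fda_key = pad_ymd(.data$fda_dt)) %>%
    mutate(.fda_key = if_else(is.na(.data$.fda_key), -Inf, as.numeric(.data$.fda_key))) %>%
    arrange(.data$caseid, desc(.data$.fda_key), desc(.data$primaryid))
  kept <- ord %>%
    distinct(.data$caseid, .keep_all = TRUE) %>%
    select(-".fda_key")
  dropped <- ord %>%
    filter(!.data$primaryid %in% kept$primaryid) %>%
    select("primaryid", "caseid")
  attr(kept, "dropped") <- dropped
  kept
}

#' Audit trail of a deduplication
#'
#' @param kept Result of [dedup_reports()].
#' @return Tibble of dropped `primaryid` / `caseid` pairs.
#' @export
dedup_dropped <- function(kept) {
  attr(kept, "dropped") %||% tibble(primaryid = integer(), caseid = integer())
}

#' Restrict a bundle to a kept set of reports
#'
#' Filters all five tables to the given `primaryid` set, preserving the
#' referential invariant. Typically called with the survivors of
#' [dedup_reports()].
#'
#' @param bundle A `faers_bundle`.
#' @param kept Integer vector of primaryids, or a DEMO tibble (its
#'   `primaryid` column is used).
#' @return A `faers_bundle` containing only the kept reports.
#' @export
restrict_bundle <- function(bundle, kept) {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (is.data.frame(kept)) kept <- kept$primaryid
  unknown <- setdiff(kept, bundle$demo$primaryid)
  if (length(unknown) > 0) {
    abort(sprintf("kept set contains %d primaryid(s) not in demo (e.g. %s)",
                  length(unknown), unknown[1]))
  }
  faers_bundle(
    demo = filter(bundle$demo, .data$primaryid %in% kept),
    drug = filter(bundle$drug, .data$primaryid %in% kept),
    reac = filter(bundle$reac, .data$primaryid %in% kept),
    ther = filter(bundle$ther, .data$primaryid %in% kept),
    outc = filter(bundle$outc, .data$primaryid %in% kept),
    quarter_label = bundle$quarter_label
  )
}

#' Deduplicate a whole bundle
#'
#' Convenience wrapper: [dedup_reports()] on DEMO, then [restrict_bundle()].
#'
#' @param bundle A `faers_bundle`.
#' @return A deduplicated `faers_bundle` (one report per case).
#' @export
dedup_bundle <- function(bundle) {
  kept <- dedup_reports(bundle$demo)
  restrict_bundle(bundle, kept$primaryid)
}
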