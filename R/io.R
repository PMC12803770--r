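#' Read a donor visit table from delimited text
#'
#' Reads a registry-style extract with one row per donor visit. The file must
#' have a header naming the columns `donor_id`, `sex`, `date` and `hb`
#' (an optional logical `exclude_flag` column is carried through for
#' sensitivity filters). The delimiter (comma or tab) is sniffed from the
#' header line. Dates must be ISO-8601 (`YYYY-MM-DD`); sex is coded
#' `M`/`F` or `male`/`female` (case-insensitive).
#'
#' Rows that fail validation (unparseable date, unsupported sex code,
#' missing/non-positive Hb, or Hb outside the plausible 5-25 g/dL range after
#' unit conversion) are rejected and counted per reason -- never silently
#' dropped. Multiple rows for the same donor on the same date are collapsed
#' to a single visit according to `policy$same_day_rule`. If
#' `policy$units == "g_L"` Hb values are divided by 10 on read.
#'
#' @param path Path to a delimited text file.
#' @param policy An [policy_config()] object supplying `units` and
#'   `same_day_rule`. Default `policy_config()`.
#' @return A tibble of visits sorted by donor and date with columns
#'   `donor_id` (character), `sex` (`"male"`/`"female"`), `visit_date`
#'   (`Date`), `hb` (g/dL) and, when present in the input, `exclude_flag`.
#'   A validation report is attached as attribute `"validation"`; retrieve it
#'   with [validation_report()]. The report satisfies
#'   `rows_read == rows_kept + rows_rejected + rows_collapsed`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("donor_id,sex,date,hb",
#'              "D1,M,2020-01-01,15.1",
#'              "D1,M,2020-03-01,14.8"), f)
#' visits <- read_visits(f)
#' validation_report(visits)
#' @export
read_visits <- function(path, policy = policy_config()) {
  if (!file.exists(path)) stop("Visits file not found: ", path, call. = FALSE)
  stopifnot(inherits(policy, "hb_policy"))

  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("Empty visits file: ", path, call. = FALSE)
  delim <- if (grepl("\t", header)) "\t" else ","

  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  required <- c("donor_id", "sex", "date", "hb")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("Visits file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("Visits file has no data rows: ", path, call. = FALSE)

  rows_read <- nrow(raw)
  sex_norm <- c(m = "male", male = "male", f = "female", female = "female")
  sex <- unname(sex_norm[tolower(raw$sex)])
  date <- as.Date(suppressWarnings(
    readr::parse_date(raw$date, format = "%Y-%m-%d")
  ))
  hb <- suppressWarnings(as.numeric(raw$hb))
  if (policy$units == "g_L") hb <- hb / 10

  reject_reason <- dplyr::case_when(
    is.na(raw$donor_id) | raw$donor_id == "" ~ "missing_donor_id",
    is.na(sex) ~ "bad_sex",
    is.na(date) ~ "bad_date",
    is.na(hb) | hb <= 0 ~ "bad_hb",
    hb < 5 | hb > 25 ~ "hb_out_of_range",
    TRUE ~ NA_character_
  )

  keep <- is.na(reject_reason)
  rejected_by_reason <- table(reject_reason[!keep])

  visits <- tibble::tibble(
    donor_id = raw$donor_id[keep],
    sex = sex[keep],
    visit_date = date[keep],
    hb = hb[keep],
    .row = seq_len(rows_read)[keep]
  )
  if ("exclude_flag" %in% names(raw)) {
    visits$exclude_flag <- toupper(raw$exclude_flag[keep]) %in% c("TRUE", "T", "1", "YES")
  }

  # same-day collapse: stable order (input row order breaks intra-day ties)
  collapse_fun <- switch(policy$same_day_rule,
                         max = max, min = min, mean = mean)
  n_before <- nrow(visits)
  visits <- visits |>
    dplyr::arrange(.data$donor_id, .data$visit_date, .data$.row) |>
    dplyr::group_by(.data$donor_id, .data$visit_date) |>
    dplyr::summarise(
      sex = .data$sex[1],
      hb = collapse_fun(.data$hb),
      dplyr::across(dplyr::any_of("exclude_flag"), any),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("donor_id", "sex", "visit_date", "hb")),
                  dplyr::any_of("exclude_flag")) |>
    dplyr::arrange(.data$donor_id, .data$visit_date)
  rows_collapsed <- n_before - nrow(visits)

  report <- structure(
    list(
      rows_read = rows_read,
      rows_kept = nrow(visits),
      rows_rejected = sum(!keep),
      rows_collapsed = rows_collapsed,
      rejected_by_reason = stats::setNames(as.integer(rejected_by_reason),
                                           names(rejected_by_reason))
    ),
    class = "hb_validation"
  )
  stopifnot(report$rows_read ==
              report$rows_kept + report$rows_rejected + report$rows_collapsed)
  attr(visits, "validation") <- report
  visits
}

#' Retrieve the validation report attached by [read_visits()]
#'
#' @param visits A tibble returned by [read_visits()].
#' @return An `hb_validation` list with `rows_read`, `rows_kept`,
#'   `rows_rejected`, `rows_collapsed` and `rejected_by_reason`.
#' @export
validation_report <- function(visits) {
  rep <- attr(visits, "validation")
  if (is.null(rep)) stop("No validation report attached; was this tibble ",
                         "produced by read_visits()?", call. = FALSE)
  rep
}

#' @export
print.hb_validation <- function(x, ...) {
  cat("<hb_validation>\n")
  cat(sprintf("  rows read: %d  kept: %d  rejected: %d  same-day collapsed: %d\n",
              x$rows_read, x$rows_kept, x$rows_rejected, x$rows_collapsed))
  if (length(x$rejected_by_reason) > 0) {
    for (r in names(x$rejected_by_reason)) {
      cat(sprintf("    rejected (%s): %d\n", r, x$rejected_by_reason[[r]]))
    }
  }
  invisible(x)
}

assessment_numeric_cols <- c("hb", "hist_mean", "ci_bound", "outlier_cutoff")

#' Write per-visit assessments to delimited text
#'
#' Writes one row per assessed visit with the columns `donor_id`,
#' `visit_date`, `sex`, `hb`, `n_prior`, `hist_mean`, `ci_bound`,
#' `outlier_cutoff`, `current_decision`, `alt_decision` and `reason`.
#' Numeric columns are written with 4 decimals; the file round-trips
#' losslessly at that precision through [read_assessments()]. Visits that
#' could not be assessed (too little history) carry reason `"NA"`.
#'
#' @param assessments A non-empty tibble as produced by [assess_visits()].
#' @param path Output file path (CSV).
#' @return `path`, invisibly.
#' @export
write_assessments <- function(assessments, path) {
  stopifnot(is.data.frame(assessments))
  if (nrow(assessments) == 0L) {
    stop("`assessments` is empty; nothing to write.", call. = FALSE)
  }
  out <- assessments |>
    dplyr::select(dplyr::all_of(c(
      "donor_id", "visit_date", "sex", "hb", "n_prior", "hist_mean",
      "ci_bound", "outlier_cutoff", "current_decision", "alt_decision",
      "reason"
    ))) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(assessment_numeric_cols),
                                ~ round(.x, 4)))
  # missing numerics (not-assessed visits) are empty fields, so that the
  # literal reason string "NA" stays unambiguous
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read back an assessment table written by [write_assessments()]
#'
#' @param path Path to a CSV written by [write_assessments()].
#' @return A tibble with the same columns and types as [assess_visits()]
#'   output (numeric fields at 4-decimal precision).
#' @export
read_assessments <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      donor_id = readr::col_character(),
      visit_date = readr::col_date(format = "%Y-%m-%d"),
      sex = readr::col_character(),
      hb = readr::col_double(),
      n_prior = readr::col_integer(),
      hist_mean = readr::col_double(),
      ci_bound = readr::col_double(),
      outlier_cutoff = readr::col_double(),
      current_decision = readr::col_character(),
      alt_decision = readr::col_character(),
      reason = readr::col_character()
    ),
    na = "",
    progress = FALSE
  )
}

#' Write a visits tibble to delimited text
#'
#' Inverse of [read_visits()] for simulated or filtered data: writes
#' `donor_id`, `sex`, `date`, `hb` (and `exclude_flag` if present) as CSV.
#'
#' @param visits A visits tibble.
#' @param path Output file path.
#' @param digits Decimals for `hb` (default 4).
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, digits = 4) {
  stopifnot(is.data.frame(visits), nrow(visits) > 0)
  out <- visits |>
    dplyr::mutate(hb = round(.data$hb, digits)) |>
    dplyr::select(dplyr::all_of(c("donor_id", "sex")),
                  date = dplyr::all_of("visit_date"),
                  dplyr::all_of("hb"), dplyr::any_of("exclude_flag"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
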