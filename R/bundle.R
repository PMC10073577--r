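# The claims bundle: the pipeline's sole input. Five tables mirroring an
# administrative claims extract -- month-granular enrollment spans, ICD-10
# diagnoses (optionally annotated with gestational age), prescriptions with
# days of supply, delivery-related entries, and the mother-infant linkage.

BUNDLE_TABLES <- c("enrollment", "diagnoses", "prescriptions",
                   "delivery_entries", "links")

new_claims_bundle <- function(enrollment, diagnoses, prescriptions,
                              delivery_entries, links) {
  structure(
    list(enrollment = enrollment, diagnoses = diagnoses,
         prescriptions = prescriptions, delivery_entries = delivery_entries,
         links = links),
    class = "claims_bundle"
  )
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in BUNDLE_TABLES) {
    cat(sprintf("  %-17s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Validate claims-bundle invariants
#'
#' Checks structural invariants: every linked infant is enrolled with role
#' `infant`, every prescription carries a claim year-month and a positive
#' days-of-supply, gestational-age annotations are in range, and no infant is
#' linked to two mothers. Violations are reported with row numbers.
#'
#' @param bundle a `claims_bundle`.
#' @return The bundle, invisibly; aborts with all violations otherwise.
#' @export
validate_bundle <- function(bundle) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)

  enr <- bundle$enrollment
  infants_enrolled <- enr$person_id[enr$role == "infant"]
  missing_inf <- !(bundle$links$infant_id %in% infants_enrolled)
  if (any(missing_inf)) {
    add(sprintf("links row(s) %s: infant not enrolled with role=infant",
                paste(head(which(missing_inf), 5L), collapse = ", ")))
  }
  dup <- bundle$links |>
    dplyr::count(.data$infant_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    add(sprintf("infant(s) linked to multiple mothers: %s",
                paste(head(dup$infant_id, 5L), collapse = ", ")))
  }
  rx <- bundle$prescriptions
  bad_supply <- is.na(rx$days_of_supply) | rx$days_of_supply < 1
  if (any(bad_supply)) {
    add(sprintf("prescriptions row(s) %s: days_of_supply must be >= 1",
                paste(head(which(bad_supply), 5L), collapse = ", ")))
  }
  no_ym <- is.na(rx$claim_year_month) | rx$claim_year_month == ""
  if (any(no_ym)) {
    add(sprintf("prescriptions row(s) %s: claim_year_month missing",
                paste(head(which(no_ym), 5L), collapse = ", ")))
  }
  dx <- bundle$diagnoses
  bad_ga <- !is.na(dx$ga_weeks) & (dx$ga_weeks < 0 | dx$ga_weeks > 45)
  bad_ga <- bad_ga | (!is.na(dx$ga_days) & (dx$ga_days < 0 | dx$ga_days > 6))
  if (any(bad_ga)) {
    add(sprintf("diagnoses row(s) %s: gestational age out of range",
                paste(head(which(bad_ga), 5L), collapse = ", ")))
  }
  span_bad <- ym_index(enr$coverage_end_month) < ym_index(enr$coverage_start_month)
  if (any(span_bad, na.rm = TRUE)) {
    add(sprintf("enrollment row(s) %s: coverage ends before it starts",
                paste(head(which(span_bad), 5L), collapse = ", ")))
  }
  if (length(problems)) {
    rlang::abort(c("invalid claims bundle:", problems),
                 class = "kampopreg_bundle_error")
  }
  invisible(bundle)
}

#' Write a claims bundle (and optional truth table) to CSV
#'
#' Writes the five tables as UTF-8 comma-separated files with ISO-8601 dates,
#' `YYYY-MM` year-months and empty strings for missing values, plus
#' `truth.json` when a truth table is supplied. [read_bundle()] round-trips
#' the result losslessly.
#'
#' @param bundle a `claims_bundle`.
#' @param directory output directory (created if absent).
#' @param truth optional truth tibble from [generate_bundle()].
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, directory, truth = NULL) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("cannot create directory '%s'", directory))
  }
  for (nm in BUNDLE_TABLES) {
    readr::write_csv(bundle[[nm]], file.path(directory, paste0(nm, ".csv")),
                     na = "")
  }
  if (!is.null(truth)) {
    tr <- truth
    tr$true_onset_date <- format(tr$true_onset_date, "%Y-%m-%d")
    tr$true_delivery_date <- format(tr$true_delivery_date, "%Y-%m-%d")
    jsonlite::write_json(tr, file.path(directory, "truth.json"),
                         dataframe = "rows", na = "null", digits = NA)
  }
  invisible(directory)
}

#' Read a claims bundle from CSV
#'
#' @param directory directory holding the five bundle CSVs.
#' @param validate validate invariants after parsing (default TRUE).
#' @return A `claims_bundle`.
#' @export
read_bundle <- function(directory, validate = TRUE) {
  paths <- file.path(directory, paste0(BUNDLE_TABLES, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    rlang::abort(sprintf("missing bundle file(s): %s",
                         paste(basename(paths[missing]), collapse = ", ")),
                 class = "kampopreg_bundle_error")
  }
  raw <- function(p) {
    readr::read_csv(p, col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE)
  }
  chr_na <- function(x) dplyr::if_else(x == "", NA_character_, x)
  int_na <- function(x) suppressWarnings(as.integer(chr_na(x)))

  enr <- raw(paths[1])
  enrollment <- tibble::tibble(
    person_id = enr$person_id, family_id = enr$family_id, role = enr$role,
    coverage_start_month = enr$coverage_start_month,
    coverage_end_month = enr$coverage_end_month,
    birth_year_month = chr_na(enr$birth_year_month), sex = enr$sex
  )
  dx <- raw(paths[2])
  diagnoses <- tibble::tibble(
    person_id = dx$person_id, icd10_code = dx$icd10_code,
    diagnosis_date = parse_iso_date(dx$diagnosis_date, "diagnosis_date"),
    ga_weeks = int_na(dx$ga_weeks), ga_days = int_na(dx$ga_days)
  )
  rx <- raw(paths[3])
  prescriptions <- tibble::tibble(
    person_id = rx$person_id, drug_code = rx$drug_code,
    dispense_date = parse_iso_date(rx$dispense_date, "dispense_date"),
    admission_date = parse_iso_date(rx$admission_date, "admission_date"),
    claim_year_month = rx$claim_year_month,
    days_of_supply = int_na(rx$days_of_supply),
    as_needed = toupper(rx$as_needed) == "TRUE"
  )
  de <- raw(paths[4])
  delivery_entries <- tibble::tibble(
    person_id = de$person_id,
    entry_date = parse_iso_date(de$entry_date, "entry_date"),
    entry_kind = de$entry_kind
  )
  lk <- raw(paths[5])
  links <- tibble::tibble(
    mother_id = lk$mother_id, infant_id = lk$infant_id,
    family_id = lk$family_id
  )
  bundle <- new_claims_bundle(enrollment, diagnoses, prescriptions,
                              delivery_entries, links)
  if (validate) validate_bundle(bundle)
  bundle
}

#' @rdname read_bundle
#' @export
read_truth <- function(directory) {
  path <- file.path(directory, "truth.json")
  if (!file.exists(path)) {
    rlang::abort("missing truth.json", class = "kampopreg_bundle_error")
  }
  tr <- tibble::as_tibble(jsonlite::fromJSON(path))
  tr$true_onset_date <- as.Date(tr$true_onset_date)
  tr$true_delivery_date <- as.Date(tr$true_delivery_date)
  tr
}
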