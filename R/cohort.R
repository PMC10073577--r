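# Cohort construction: mother-infant linkage, the eligibility cascade with a
# stage-by-stage attrition report, and covariate derivation.

DELIVERY_YEAR_MIN <- 2010L
DELIVERY_YEAR_MAX <- 2019L
INFANT_FOLLOWUP_MONTHS <- 12L
MATERNAL_LOOKBACK_MONTHS <- 3L

#' Link mothers to infants enrolled from their birth month
#'
#' Retains mother-infant links whose infant's coverage starts in the infant's
#' birth month (the linkage criterion identifying true newborns of the
#' insured family). An infant linked to two mothers is a data error.
#'
#' @param bundle a `claims_bundle`.
#' @return A tibble of retained links with the infant's birth month, plus an
#'   attribute `dropped` holding the rejected links and reasons.
#' @export
link_mother_infant <- function(bundle) {
  dup <- bundle$links |>
    dplyr::count(.data$infant_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    rlang::abort(sprintf("infant(s) linked to multiple mothers: %s",
                         paste(head(dup$infant_id, 5L), collapse = ", ")),
                 class = "kampopreg_data_error")
  }
  lk <- bundle$links |>
    dplyr::left_join(
      bundle$enrollment |>
        dplyr::filter(.data$role == "infant") |>
        dplyr::select("person_id", "coverage_start_month", "birth_year_month"),
      by = c("infant_id" = "person_id")
    )
  keep <- !is.na(lk$birth_year_month) &
    lk$coverage_start_month == lk$birth_year_month
  out <- lk[keep, c("mother_id", "infant_id", "family_id", "birth_year_month")]
  attr(out, "dropped") <- lk[!keep, c("mother_id", "infant_id")] |>
    dplyr::mutate(reason = "infant_not_enrolled_from_birth_month")
  out
}

# months (as indices) a person is covered, from possibly multiple spans
covered_months <- function(enrollment, persons) {
  e <- enrollment[enrollment$person_id %in% persons, , drop = FALSE]
  s <- ym_index(e$coverage_start_month)
  t <- ym_index(e$coverage_end_month)
  len <- pmax(t - s + 1L, 0L)
  tibble::tibble(
    person_id = rep(e$person_id, len),
    month = sequence(len, from = s)
  ) |> dplyr::distinct()
}

# TRUE for persons covered in every month index of [from, to].
# Single-span persons (the common case) are checked directly; persons with
# several enrollment spans fall back to month-by-month expansion.
fully_covered <- function(enrollment, persons, from, to) {
  e <- enrollment[enrollment$person_id %in% persons, , drop = FALSE]
  n_span <- table(e$person_id)
  single <- names(n_span)[n_span == 1L]
  es <- e[e$person_id %in% single, , drop = FALSE]
  m <- match(persons, es$person_id)
  ok <- !is.na(m) &
    ym_index(es$coverage_start_month)[m] <= from &
    ym_index(es$coverage_end_month)[m] >= to
  multi <- persons[persons %in% names(n_span)[n_span > 1L]]
  if (length(multi)) {
    cov <- covered_months(e, multi)
    sel <- persons %in% multi
    need <- tibble::tibble(person_id = persons[sel], from = from[sel],
                           to = to[sel],
                           n_required = to[sel] - from[sel] + 1L)
    have <- need |>
      dplyr::left_join(cov, by = "person_id",
                       relationship = "many-to-many") |>
      dplyr::filter(.data$month >= .data$from, .data$month <= .data$to) |>
      dplyr::count(.data$person_id, name = "n_covered")
    need <- dplyr::left_join(need, have, by = "person_id")
    ok[sel] <- dplyr::coalesce(need$n_covered, 0L) >= need$n_required
  }
  ok
}

#' Apply the eligibility cascade
#'
#' Applies, in order: mother-infant linkage with enrollment-at-birth; a
#' datable pregnancy episode; continuous maternal coverage from 3 months
#' before pregnancy onset through delivery (month granularity); delivery year
#' within 2010-2019; infant coverage for at least 12 months from the birth
#' month; exclusion of multiple births; exclusion of infants with any
#' chromosomal-abnormality (Q90-Q99) diagnosis. Every dropped mother gets an
#' exclusion reason; stage counts form the attrition report.
#'
#' @param bundle a `claims_bundle`.
#' @param episodes tibble from [estimate_episodes()].
#' @return A list: `retained` (tibble of retained mother/infant ids with
#'   episode columns), `report` (class `eligibility_report`: `stage_counts`
#'   tibble and `exclusions` tibble).
#' @export
apply_eligibility <- function(bundle, episodes) {
  stages <- list()
  exclusions <- tibble::tibble(mother_id = character(), reason = character())
  note <- function(label, ids) {
    stages[[length(stages) + 1L]] <<- tibble::tibble(
      criterion = label, n_remaining = length(ids)
    )
    ids
  }
  drop_to <- function(ids, keep, reason, label) {
    lost <- ids[!keep]
    if (length(lost)) {
      exclusions <<- dplyr::bind_rows(
        exclusions, tibble::tibble(mother_id = lost, reason = reason)
      )
    }
    note(label, ids[keep])
  }

  all_mothers <- unique(bundle$links$mother_id)
  ids <- note("mothers with a linked infant", all_mothers)

  links <- link_mother_infant(bundle)
  ids <- drop_to(ids, ids %in% links$mother_id,
                 "infant_not_enrolled_from_birth_month",
                 "infant enrolled from birth month")

  ep <- episodes[match(ids, episodes$mother_id), ]
  ids <- drop_to(ids, !is.na(ep$datable) & ep$datable, "undatable_pregnancy",
                 "pregnancy onset and delivery estimable")

  ep <- episodes[match(ids, episodes$mother_id), ]
  from <- ym_index(date_ym(ep$onset_date)) - MATERNAL_LOOKBACK_MONTHS
  to <- ym_index(date_ym(ep$delivery_date))
  ok <- fully_covered(bundle$enrollment, ids, from, to)
  ids <- drop_to(ids, ok, "coverage_gap",
                 "maternal coverage from 3 months before onset to delivery")

  ep <- episodes[match(ids, episodes$mother_id), ]
  yr <- as.integer(format(ep$delivery_date, "%Y"))
  ids <- drop_to(ids, yr >= DELIVERY_YEAR_MIN & yr <= DELIVERY_YEAR_MAX,
                 "delivery_outside_study_years", "delivery in 2010-2019")

  lk <- links[links$mother_id %in% ids, ]
  birth_idx <- ym_index(lk$birth_year_month)
  inf_ok <- fully_covered(bundle$enrollment, lk$infant_id, birth_idx,
                          birth_idx + INFANT_FOLLOWUP_MONTHS - 1L)
  short_cov <- unique(lk$mother_id[!inf_ok])
  ids <- drop_to(ids, !(ids %in% short_cov), "infant_coverage_short",
                 "infant covered 12 months from birth")

  n_infants <- links |>
    dplyr::filter(.data$mother_id %in% ids) |>
    dplyr::count(.data$mother_id)
  multi <- n_infants$mother_id[n_infants$n > 1]
  ids <- drop_to(ids, !(ids %in% multi), "multiple_birth",
                 "singleton delivery")

  chromo_dx <- bundle$diagnoses |>
    dplyr::filter(icd_matches(.data$icd10_code, paste0("Q9", 0:9)))
  chromo_mothers <- links$mother_id[links$infant_id %in% chromo_dx$person_id]
  ids <- drop_to(ids, !(ids %in% chromo_mothers), "chromosomal_abnormality",
                 "no chromosomal abnormality (Q90-Q99) in infant")

  retained <- links |>
    dplyr::filter(.data$mother_id %in% ids) |>
    dplyr::left_join(episodes, by = "mother_id")
  report <- structure(
    list(stage_counts = dplyr::bind_rows(stages), exclusions = exclusions),
    class = "eligibility_report"
  )
  list(retained = retained, report = report)
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat("<eligibility_report>\n")
  print(as.data.frame(x$stage_counts), row.names = FALSE)
  invisible(x)
}

AGE_BANDS <- c("<=24", "25-29", "30-34", ">=35")
YEAR_BANDS <- c("2010-2012", "2013-2015", "2016-2019")

age_band <- function(age) {
  yrs <- floor(age)  # completed years at delivery
  dplyr::case_when(
    yrs <= 24 ~ "<=24",
    yrs <= 29 ~ "25-29",
    yrs <= 34 ~ "30-34",
    TRUE ~ ">=35"
  )
}

year_band <- function(year) {
  dplyr::case_when(
    year <= 2012 ~ "2010-2012",
    year <= 2015 ~ "2013-2015",
    TRUE ~ "2016-2019"
  )
}

#' Derive covariates for retained mothers
#'
#' Condition flags are true iff at least one diagnosis matching the
#' covariate's ICD-10 prefixes falls between `lookback_months` before
#' pregnancy onset and delivery. Maternal age at delivery is computed from
#' the mother's birth year-month (mid-month convention) and banded; delivery
#' year is banded likewise. First-trimester teratogen exposure comes from
#' the configured teratogen drug codes via the usual interval-overlap rule;
#' preterm birth is gestation under 259 days (37 weeks).
#'
#' @param bundle a `claims_bundle`.
#' @param retained retained tibble from [apply_eligibility()].
#' @param codelists a [covariate_codelists()].
#' @return A tibble of covariates, one row per retained mother; mothers with
#'   no recorded birth year-month have `maternal_age = NA` and are flagged
#'   `missing_age`.
#' @export
derive_covariates <- function(bundle, retained, codelists = covariate_codelists()) {
  mothers <- retained$mother_id
  mother_birth <- bundle$enrollment |>
    dplyr::filter(.data$role == "mother", .data$person_id %in% mothers) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::transmute(person_id = .data$person_id,
                     mother_birth_ym = .data$birth_year_month)

  base <- retained |>
    dplyr::left_join(mother_birth, by = c("mother_id" = "person_id")) |>
    dplyr::mutate(
      maternal_age = as.numeric(
        .data$delivery_date - ym_mid_day(.data$mother_birth_ym)) / 365.25,
      missing_age = is.na(.data$maternal_age),
      maternal_age_band = dplyr::if_else(
        .data$missing_age, NA_character_, age_band(.data$maternal_age)),
      delivery_year_band = year_band(
        as.integer(format(.data$delivery_date, "%Y"))),
      preterm_birth = .data$gestation_days < PRETERM_DAYS
    )

  # condition flags from diagnoses in [onset - lookback, delivery]
  lb_days <- 31L * codelists$lookback_months  # month granularity, generous
  dx <- bundle$diagnoses |>
    dplyr::filter(.data$person_id %in% mothers)
  for (cond in names(codelists$conditions)) {
    hit <- dx |>
      dplyr::filter(icd_matches(.data$icd10_code,
                                codelists$conditions[[cond]])) |>
      dplyr::inner_join(
        dplyr::select(base, "mother_id", "onset_date", "delivery_date"),
        by = c("person_id" = "mother_id")
      ) |>
      dplyr::filter(.data$diagnosis_date >= .data$onset_date - lb_days,
                    .data$diagnosis_date <= .data$delivery_date) |>
      dplyr::distinct(.data$person_id)
    base[[cond]] <- base$mother_id %in% hit$person_id
  }

  # first-trimester teratogen prescriptions (interval overlap with window 1)
  ter_rx <- bundle$prescriptions |>
    dplyr::filter(.data$person_id %in% mothers,
                  .data$drug_code %in% codelists$teratogen_codes)
  if (nrow(ter_rx)) {
    ter_iv <- resolve_exposure_date(ter_rx) |>
      dplyr::mutate(end_date = .data$exposure_date + .data$days_of_supply - 1L) |>
      dplyr::inner_join(
        dplyr::select(base, "mother_id", "t1_start", "t1_end"),
        by = c("person_id" = "mother_id")
      ) |>
      dplyr::filter(.data$exposure_date <= .data$t1_end,
                    .data$end_date >= .data$t1_start) |>
      dplyr::distinct(.data$person_id)
    base$teratogen_rx_t1 <- base$mother_id %in% ter_iv$person_id
  } else {
    base$teratogen_rx_t1 <- FALSE
  }

  dplyr::select(
    base, "mother_id", "infant_id", "maternal_age", "maternal_age_band",
    "missing_age", "delivery_year_band", "preterm_birth",
    dplyr::all_of(names(codelists$conditions)), "teratogen_rx_t1"
  )
}
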