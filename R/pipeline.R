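# End-to-end assembly: episodes -> eligibility -> covariates -> exposure ->
# outcomes -> one analysis row per retained mother -> the four report tables.

#' Assemble analysis rows
#'
#' Joins episodes, covariates, exposure profiles and outcomes into one row
#' per retained mother-infant pair. Mothers with no recorded birth
#' year-month (age underivable) are dropped with a warning.
#'
#' @param retained retained tibble from [apply_eligibility()].
#' @param covariates tibble from [derive_covariates()].
#' @param profiles tibble from [exposure_profiles()].
#' @param outcomes tibble from [ascertain_mcm()].
#' @param enrollment enrollment table (for infant sex).
#' @return A tibble of analysis rows; `krr` is the Group-2 indicator.
#' @export
build_analysis_rows <- function(retained, covariates, profiles, outcomes,
                                enrollment) {
  rows <- retained |>
    dplyr::select("mother_id", "infant_id", "onset_date", "delivery_date",
                  "delivery_method", "capped_294", "gestation_days") |>
    dplyr::left_join(dplyr::select(covariates, -"infant_id"),
                     by = "mother_id") |>
    dplyr::left_join(profiles, by = "mother_id") |>
    dplyr::left_join(outcomes, by = "infant_id") |>
    dplyr::left_join(
      enrollment |>
        dplyr::filter(.data$role == "infant") |>
        dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
        dplyr::transmute(infant_id = .data$person_id,
                         infant_sex = .data$sex),
      by = "infant_id"
    ) |>
    dplyr::mutate(
      krr = .data$group == "group2_krr",
      mcm = dplyr::coalesce(.data$mcm_any, FALSE),
      index_t1_supply_days = dplyr::if_else(
        .data$krr, .data$krr_t1_supply_days, .data$mgo_t1_supply_days),
      index_all_as_needed = dplyr::if_else(
        .data$krr, .data$krr_t1_all_as_needed, .data$mgo_t1_all_as_needed)
    )
  if (any(rows$missing_age)) {
    rlang::warn(sprintf("dropping %d mother(s) with no recorded birth month",
                        sum(rows$missing_age)))
    rows <- rows[!rows$missing_age, , drop = FALSE]
  }
  rows
}

or_from_rows <- function(rows) {
  crude_or(
    a = sum(rows$krr & rows$mcm), b = sum(rows$krr & !rows$mcm),
    c = sum(!rows$krr & rows$mcm), d = sum(!rows$krr & !rows$mcm)
  )
}

#' Run one of the four sensitivity analyses
#'
#' Variant 1 keeps only mothers without a first-trimester teratogen
#' prescription; variant 2 keeps mothers with more than 30 first-trimester
#' supply days of their index laxative class; variant 3 drops mothers
#' exposed to both MgO and rhubarb-Kampo in the first trimester; variant 4
#' drops mothers whose index-class first-trimester prescriptions were all
#' as-needed. The crude and adjusted odds ratios are then re-estimated on
#' the subset.
#'
#' @param rows analysis rows restricted or restrictable to the two groups.
#' @param variant integer 1-4.
#' @return A list: `variant`, `n`, `n_events`, `crude` and `adjusted`
#'   (`or_result`s).
#' @export
run_sensitivity <- function(rows, variant) {
  stopifnot(variant %in% 1:4)
  rows <- rows[rows$group %in% c("group1_mgo", "group2_krr"), , drop = FALSE]
  sub <- switch(variant,
    rows[!rows$teratogen_rx_t1, , drop = FALSE],
    rows[rows$index_t1_supply_days > 30L, , drop = FALSE],
    rows[!(rows$mgo_t1 & rows$krr_t1), , drop = FALSE],
    rows[!rows$index_all_as_needed, , drop = FALSE]
  )
  if (!nrow(sub) || !any(sub$krr) || !any(!sub$krr)) {
    rlang::abort(sprintf(
      "sensitivity analysis %d leaves no usable subset", variant
    ))
  }
  list(
    variant = variant,
    n = nrow(sub),
    n_events = sum(sub$mcm),
    crude = or_from_rows(sub),
    adjusted = fit_logistic(sub)$adjusted_or
  )
}

#' Run the full analysis on a claims bundle
#'
#' The complete pipeline: pregnancy dating, eligibility cascade, covariates,
#' exposure classification and grouping, first-year malformation
#' ascertainment, and the four report tables (group characteristics,
#' prescription prevalence with trend tests, malformation prevalence by
#' organ system, and crude/adjusted odds ratios with the four sensitivity
#' analyses).
#'
#' @param bundle a `claims_bundle`.
#' @param dict a [drug_dictionary()].
#' @param codelists a [covariate_codelists()].
#' @param mcm_codes an [mcm_codelist()].
#' @param exposure_rule `"overlap"` (default) or `"dispense_date"`.
#' @param sensitivity run the four sensitivity analyses (default TRUE;
#'   skipped automatically when a subset is degenerate, with a warning).
#' @return A list of class `kampopreg_study`: `episodes`, `rows`,
#'   `attrition`, `table1`, `table2`, `table3`, `table4`, `crude`,
#'   `adjusted`.
#' @export
#' @examples
#' sim <- generate_bundle(sim_config(n_mothers = 400, seed = 42))
#' study <- run_study(sim$bundle)
#' study$attrition
run_study <- function(bundle, dict = drug_dictionary(),
                      codelists = covariate_codelists(),
                      mcm_codes = mcm_codelist(),
                      exposure_rule = c("overlap", "dispense_date"),
                      sensitivity = TRUE) {
  exposure_rule <- match.arg(exposure_rule)
  validate_bundle(bundle)

  episodes <- estimate_episodes(bundle)
  elig <- apply_eligibility(bundle, episodes)
  retained <- elig$retained
  covariates <- derive_covariates(bundle, retained, codelists)
  ep_retained <- episodes[episodes$mother_id %in% retained$mother_id, ,
                          drop = FALSE]
  profiles <- exposure_profiles(bundle, ep_retained, dict, rule = exposure_rule)
  infants <- dplyr::select(retained, "infant_id", "birth_year_month")
  outcomes <- ascertain_mcm(bundle$diagnoses, infants, mcm_codes)
  rows <- build_analysis_rows(retained, covariates, profiles, outcomes,
                              bundle$enrollment)

  groups <- dplyr::select(rows, "infant_id", "group")
  table2 <- prevalence_table(bundle, ep_retained, dict)
  table3 <- tabulate_by_system(outcomes, groups)

  comparison <- rows[rows$group %in% c("group1_mgo", "group2_krr"), ,
                     drop = FALSE]
  table1 <- NULL
  crude <- NULL
  adjusted <- NULL
  table4 <- NULL
  if (nrow(comparison) && any(comparison$krr) && any(!comparison$krr)) {
    table1 <- compare_groups(comparison)
    crude <- tryCatch(or_from_rows(comparison),
                      kampopreg_zero_cell = function(e) NULL)
    adjusted <- tryCatch(fit_logistic(comparison)$adjusted_or,
                         error = function(e) {
                           rlang::warn(conditionMessage(e))
                           NULL
                         })
    t4 <- list(primary = list(
      variant = 0L, n = nrow(comparison), n_events = sum(comparison$mcm),
      crude = crude, adjusted = adjusted
    ))
    if (sensitivity) {
      for (v in 1:4) {
        t4[[paste0("sensitivity_", v)]] <- tryCatch(
          run_sensitivity(rows, v),
          error = function(e) {
            rlang::warn(sprintf("sensitivity %d not estimable: %s", v,
                                conditionMessage(e)))
            NULL
          }
        )
      }
    }
    table4 <- dplyr::bind_rows(lapply(Filter(Negate(is.null), t4), function(x) {
      tibble::tibble(
        analysis = if (x$variant == 0) "primary"
                   else paste0("sensitivity_", x$variant),
        n = x$n, n_events = x$n_events,
        crude_or = if (is.null(x$crude)) NA_real_ else x$crude$or_point,
        crude_ci_low = if (is.null(x$crude)) NA_real_ else x$crude$ci_low,
        crude_ci_high = if (is.null(x$crude)) NA_real_ else x$crude$ci_high,
        adjusted_or = if (is.null(x$adjusted)) NA_real_ else x$adjusted$or_point,
        adjusted_ci_low = if (is.null(x$adjusted)) NA_real_ else x$adjusted$ci_low,
        adjusted_ci_high = if (is.null(x$adjusted)) NA_real_ else x$adjusted$ci_high
      )
    }))
  } else {
    rlang::warn("comparison groups degenerate: odds ratios not estimated")
  }

  structure(list(
    episodes = episodes, rows = rows, attrition = elig$report,
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    crude = crude, adjusted = adjusted
  ), class = "kampopreg_study")
}

#' @export
print.kampopreg_study <- function(x, ...) {
  cat("<kampopreg_study>\n")
  print(x$attrition)
  if (!is.null(x$crude)) {
    cat("crude    "); print(x$crude)
  }
  if (!is.null(x$adjusted)) {
    cat("adjusted "); print(x$adjusted)
  }
  invisible(x)
}

#' Write the study's report files
#'
#' Emits `table1.csv` through `table4.csv`, `attrition.json`, plus the
#' intermediate `episodes.csv`, `cohort.csv` and `exposure.csv`.
#'
#' @param study a `kampopreg_study`.
#' @param directory output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report <- function(study, directory) {
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  }
  tables <- c("table1", "table2", "table3", "table4")
  for (tb in tables) {
    if (!is.null(study[[tb]])) {
      readr::write_csv(study[[tb]], file.path(directory, paste0(tb, ".csv")),
                       na = "")
    }
  }
  jsonlite::write_json(
    list(stage_counts = study$attrition$stage_counts,
         exclusion_reasons = study$attrition$exclusions |>
           dplyr::count(.data$reason, name = "n")),
    file.path(directory, "attrition.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  readr::write_csv(
    dplyr::select(study$episodes, "mother_id", "onset_date", "delivery_date",
                  "delivery_method", "capped_294", "gestation_days",
                  "datable"),
    file.path(directory, "episodes.csv"), na = ""
  )
  readr::write_csv(
    dplyr::select(study$rows, "mother_id", "infant_id", "group", "mcm",
                  "maternal_age_band", "delivery_year_band",
                  dplyr::any_of(c("preterm_birth", "hypertension", "diabetes",
                                  "obesity", "epilepsy", "phenylketonuria",
                                  "teratogen_rx_t1", "caesarean"))),
    file.path(directory, "cohort.csv"), na = ""
  )
  readr::write_csv(
    dplyr::select(study$rows, "mother_id", dplyr::ends_with("_t1"),
                  dplyr::ends_with("_t2"), dplyr::ends_with("_t3"), "group"),
    file.path(directory, "exposure.csv"), na = ""
  )
  invisible(directory)
}
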