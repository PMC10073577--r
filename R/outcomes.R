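# Outcome ascertainment: major congenital malformations (MCM) diagnosed in
# the infant's first year of life, organised by organ system. Birth dates are
# only available to the month, so "first year" is the birth month plus the
# eleven following months. Minor malformations are excluded by the
# codelist's minor list; chromosomal abnormalities never reach this stage
# (they are excluded at cohort construction).

#' Ascertain major congenital malformations for infants
#'
#' An infant is MCM-positive iff at least one diagnosis matches an included
#' organ-system code, does not match the minor-malformation exclusion list,
#' and falls within the first-year window: from the first day of the birth
#' month through the last day of the eleventh month after it.
#'
#' @param diagnoses infant diagnosis rows (`person_id`, `icd10_code`,
#'   `diagnosis_date`).
#' @param infants tibble with `infant_id` and `birth_year_month`.
#' @param codelist an [mcm_codelist()].
#' @return A tibble, one row per infant: `mcm_any`, one logical column per
#'   organ system, and `first_mcm_date`.
#' @export
ascertain_mcm <- function(diagnoses, infants, codelist = mcm_codelist()) {
  dx <- diagnoses |>
    dplyr::inner_join(
      dplyr::select(infants, "infant_id", "birth_year_month"),
      by = c("person_id" = "infant_id")
    ) |>
    dplyr::filter(
      .data$diagnosis_date >= ym_first_day(.data$birth_year_month),
      .data$diagnosis_date <= ym_last_day(ym_shift(.data$birth_year_month, 11L)),
      !icd_matches(.data$icd10_code, codelist$excluded_minor),
      !icd_matches(.data$icd10_code, codelist$chromosomal)
    )

  out <- tibble::tibble(infant_id = infants$infant_id)
  systems <- names(codelist$included)
  first_date <- rep(as.Date(NA), nrow(out))
  for (sys in systems) {
    hit <- dx[icd_matches(dx$icd10_code, codelist$included[[sys]]), ,
              drop = FALSE]
    out[[sys]] <- out$infant_id %in% hit$person_id
    if (nrow(hit)) {
      earliest <- hit |>
        dplyr::group_by(.data$person_id) |>
        dplyr::summarise(d = min(.data$diagnosis_date))
      m <- match(out$infant_id, earliest$person_id)
      cand <- earliest$d[m]
      first_date <- pmin(first_date, cand, na.rm = TRUE)
    }
  }
  out$mcm_any <- Reduce(`|`, out[systems])
  out$first_mcm_date <- first_date
  dplyr::relocate(out, "mcm_any", .after = "infant_id")
}

#' Tabulate malformation prevalence by organ system and comparison group
#'
#' @param outcomes tibble from [ascertain_mcm()].
#' @param groups tibble with `infant_id` and `group`.
#' @param which_groups groups to tabulate (default the two comparison arms).
#' @return A tibble: one row for overall MCM and one per organ system, with
#'   count and percentage columns per group.
#' @export
tabulate_by_system <- function(outcomes, groups,
                               which_groups = c("group1_mgo", "group2_krr")) {
  joined <- outcomes |>
    dplyr::inner_join(groups, by = "infant_id") |>
    dplyr::filter(.data$group %in% which_groups)
  systems <- setdiff(names(outcomes),
                     c("infant_id", "mcm_any", "first_mcm_date"))
  rows <- c("mcm_overall", systems)
  out <- tibble::tibble(outcome = rows)
  for (g in which_groups) {
    sub <- joined[joined$group == g, , drop = FALSE]
    n <- nrow(sub)
    counts <- unname(c(sum(sub$mcm_any),
                       vapply(systems, function(s) sum(sub[[s]]), integer(1))))
    out[[paste0(g, "_n")]] <- counts
    out[[paste0(g, "_pct")]] <- if (n > 0) round(100 * counts / n, 1) else NA_real_
  }
  attr(out, "group_sizes") <- stats::setNames(
    vapply(which_groups, function(g) sum(joined$group == g), integer(1)),
    which_groups
  )
  out
}
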