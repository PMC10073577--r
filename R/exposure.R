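# Exposure ascertainment. Prescriptions are classified into laxative
# classes, given an exposure start date through the fallback chain
# (dispensing date, else admission date, else the 15th of the claim month),
# extended into an interval by the days of supply, and flagged per trimester
# by interval overlap with the episode's trimester windows. Group assignment
# implements the active-comparator contrast: first-trimester rhubarb-Kampo
# (Group 2) versus first-trimester magnesium oxide (Group 1), with senna
# glycoside users excluded because senna shares sennoside A with rhubarb.

#' Resolve the exposure start date of prescriptions
#'
#' Applies the fallback chain: the dispensing date when present, else the
#' admission date, else the 15th of the claim month.
#'
#' @param prescriptions data frame with `dispense_date`, `admission_date`
#'   (Dates, may be NA) and `claim_year_month`.
#' @return The input with columns `exposure_date` and `date_provenance`
#'   (`dispense`, `admission` or `month_15th`) appended.
#' @export
#' @examples
#' resolve_exposure_date(data.frame(
#'   dispense_date = as.Date(NA), admission_date = as.Date(NA),
#'   claim_year_month = "2015-02"
#' ))$exposure_date  # 2015-02-15
resolve_exposure_date <- function(prescriptions) {
  rx <- tibble::as_tibble(prescriptions)
  rx |>
    dplyr::mutate(
      exposure_date = dplyr::coalesce(.data$dispense_date,
                                      .data$admission_date,
                                      ym_mid_day(.data$claim_year_month)),
      date_provenance = dplyr::case_when(
        !is.na(.data$dispense_date) ~ "dispense",
        !is.na(.data$admission_date) ~ "admission",
        TRUE ~ "month_15th"
      )
    )
}

#' Build drug-class exposure intervals from prescriptions
#'
#' One interval per prescription whose drug code the dictionary classifies;
#' unclassified codes produce no interval. The interval runs from the
#' resolved exposure date for `days_of_supply` days (end = start + supply -
#' 1). As-needed prescriptions are kept with the same interval rule. Rows
#' with non-positive days of supply are dropped with a warning.
#'
#' @param prescriptions prescription rows (see `claims_bundle`).
#' @param dict a [drug_dictionary()].
#' @return A tibble of intervals: `person_id`, `drug_class`, `product`,
#'   `start_date`, `end_date`, `date_provenance`, `as_needed`,
#'   `days_of_supply`.
#' @export
build_intervals <- function(prescriptions, dict = drug_dictionary()) {
  rx <- resolve_exposure_date(prescriptions)
  bad <- is.na(rx$days_of_supply) | rx$days_of_supply < 1
  if (any(bad)) {
    rlang::warn(sprintf(
      "dropping %d prescription(s) with non-positive days_of_supply", sum(bad)
    ))
    rx <- rx[!bad, , drop = FALSE]
  }
  rx |>
    dplyr::mutate(drug_class = classify_drug(.data$drug_code, dict)) |>
    dplyr::filter(!is.na(.data$drug_class)) |>
    dplyr::transmute(
      person_id = .data$person_id,
      drug_class = .data$drug_class,
      product = .data$drug_code,
      start_date = .data$exposure_date,
      end_date = .data$exposure_date + .data$days_of_supply - 1L,
      date_provenance = .data$date_provenance,
      as_needed = .data$as_needed,
      days_of_supply = .data$days_of_supply
    )
}

#' Flag per-trimester exposure for one episode
#'
#' A class is flagged in a trimester iff any of its intervals intersects the
#' trimester's calendar-day window (closed intervals). The alternative
#' dispensing-date-in-window rule is available for sensitivity via
#' `rule = "dispense_date"`.
#'
#' @param intervals interval tibble from [build_intervals()] (one mother).
#' @param episode a `pregnancy_episode` (or one row of
#'   [estimate_episodes()]).
#' @param rule `"overlap"` (default) or `"dispense_date"`.
#' @return Named list of logical length-3 vectors (`MgO`, `KRR`, `SG`,
#'   `daikenchuto`), one element per trimester.
#' @export
flag_trimester_exposure <- function(intervals, episode, rule = "overlap") {
  rule <- match.arg(rule, c("overlap", "dispense_date"))
  wins <- list(
    c(episode$t1_start, episode$t1_end),
    c(episode$t2_start, episode$t2_end),
    c(episode$t3_start, episode$t3_end)
  )
  classes <- c("MgO", "KRR", "SG", "daikenchuto")
  out <- lapply(classes, function(cl) {
    iv <- intervals[intervals$drug_class == cl, , drop = FALSE]
    vapply(wins, function(w) {
      if (is.na(w[1]) || !nrow(iv)) return(FALSE)
      if (rule == "overlap") {
        any(iv$start_date <= w[2] & iv$end_date >= w[1])
      } else {
        any(iv$start_date >= w[1] & iv$start_date <= w[2])
      }
    }, logical(1))
  })
  names(out) <- classes
  out
}

#' Assign the comparison group from first-trimester flags
#'
#' Senna-glycoside exposure excludes the mother outright (shared sennoside A
#' with rhubarb); otherwise any first-trimester rhubarb-Kampo exposure puts
#' her in Group 2 (even with concomitant MgO), MgO alone in Group 1, and
#' neither leaves her unexposed.
#'
#' @param mgo_t1,krr_t1,sg_t1 logical first-trimester flags (vectorised).
#' @return Character vector: `group1_mgo`, `group2_krr`, `excluded_sg` or
#'   `unexposed`.
#' @export
#' @examples
#' assign_group(mgo_t1 = TRUE, krr_t1 = TRUE, sg_t1 = FALSE)  # "group2_krr"
assign_group <- function(mgo_t1, krr_t1, sg_t1) {
  dplyr::case_when(
    sg_t1 ~ "excluded_sg",
    krr_t1 ~ "group2_krr",
    mgo_t1 ~ "group1_mgo",
    TRUE ~ "unexposed"
  )
}

#' Exposure profiles for every mother in an episodes table
#'
#' Vectorised trimester flagging and group assignment across a bundle:
#' intervals from [build_intervals()] are intersected with each mother's
#' trimester windows.
#'
#' @param bundle a `claims_bundle`.
#' @param episodes tibble from [estimate_episodes()] (datable rows used).
#' @param dict a [drug_dictionary()].
#' @param rule exposure rule, see [flag_trimester_exposure()].
#' @return A tibble, one row per datable mother: 12 class-by-trimester flags,
#'   `group`, first-trimester supply-day totals and as-needed-only markers
#'   for the two index classes (used by the sensitivity analyses).
#' @export
exposure_profiles <- function(bundle, episodes, dict = drug_dictionary(),
                              rule = c("overlap", "dispense_date")) {
  rule <- match.arg(rule)
  ep <- episodes[episodes$datable, , drop = FALSE]
  iv <- build_intervals(
    bundle$prescriptions[bundle$prescriptions$person_id %in% ep$mother_id, ],
    dict
  ) |>
    dplyr::inner_join(ep, by = c("person_id" = "mother_id"))

  hit <- function(ws, we) {
    if (rule == "overlap") {
      !is.na(ws) & iv$start_date <= we & iv$end_date >= ws
    } else {
      !is.na(ws) & iv$start_date >= ws & iv$start_date <= we
    }
  }
  iv$in_t1 <- hit(iv$t1_start, iv$t1_end)
  iv$in_t2 <- hit(iv$t2_start, iv$t2_end)
  iv$in_t3 <- hit(iv$t3_start, iv$t3_end)
  # first-trimester overlap in days (for the >30-supply-days sensitivity)
  iv$t1_overlap_days <- pmax(
    0L,
    as.integer(pmin(iv$end_date, iv$t1_end) - pmax(iv$start_date, iv$t1_start)) + 1L
  )
  iv$t1_overlap_days[is.na(iv$t1_overlap_days)] <- 0L

  # per person x class aggregation via rowsum (fast at claims scale)
  key <- paste(iv$person_id, iv$drug_class, sep = "\r")
  uk <- unique(key)
  gi <- factor(key, levels = uk)
  agg <- rowsum(
    cbind(t1 = iv$in_t1 + 0L, t2 = iv$in_t2 + 0L, t3 = iv$in_t3 + 0L,
          supply = iv$t1_overlap_days * iv$in_t1,
          sched_t1 = (iv$in_t1 & !iv$as_needed) + 0L),
    gi
  )
  parts <- matrix(unlist(strsplit(uk, "\r", fixed = TRUE)),
                  ncol = 2, byrow = TRUE)
  per_class <- tibble::tibble(
    person_id = parts[, 1], drug_class = parts[, 2],
    t1 = agg[, "t1"] > 0, t2 = agg[, "t2"] > 0, t3 = agg[, "t3"] > 0,
    t1_supply_days = as.integer(agg[, "supply"]),
    t1_all_as_needed = agg[, "t1"] > 0 & agg[, "sched_t1"] == 0
  )

  wide <- function(cl, prefix) {
    sel <- per_class[per_class$drug_class == cl, , drop = FALSE]
    out <- tibble::tibble(
      mother_id = sel$person_id,
      t1 = sel$t1, t2 = sel$t2, t3 = sel$t3,
      t1_supply_days = sel$t1_supply_days,
      t1_all_as_needed = sel$t1_all_as_needed
    )
    names(out)[-1] <- paste0(prefix, "_", names(out)[-1])
    out
  }
  prof <- tibble::tibble(mother_id = ep$mother_id) |>
    dplyr::left_join(wide("MgO", "mgo"), by = "mother_id") |>
    dplyr::left_join(wide("KRR", "krr"), by = "mother_id") |>
    dplyr::left_join(wide("SG", "sg"), by = "mother_id") |>
    dplyr::left_join(wide("daikenchuto", "dkt"), by = "mother_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.logical),
                                ~ dplyr::coalesce(.x, FALSE)),
                  dplyr::across(dplyr::ends_with("supply_days"),
                                ~ dplyr::coalesce(.x, 0L))) |>
    dplyr::mutate(group = assign_group(.data$mgo_t1, .data$krr_t1, .data$sg_t1))
  prof
}
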