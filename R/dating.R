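# Pregnancy dating from claims. Neither pregnancy onset nor delivery date is
# recorded in administrative claims, so both are estimated: onset by
# subtracting the gestational age annotated on an antenatal diagnosis from
# that diagnosis date (using the most recent annotation, which is the most
# accurately staged), delivery from delivery-related claim entries with a
# mid-month fallback on the infant's birth month. Gestation is capped at 294
# days, the threshold at which labor induction is recommended.

GESTATION_CAP_DAYS <- 294L
T1_END_DAY <- 97L   # week 13 day 6
T2_END_DAY <- 195L  # week 27 day 6
PRETERM_DAYS <- 259L  # < 37 weeks 0 days

#' Estimate pregnancy onset from gestational-age annotated diagnoses
#'
#' Onset is the diagnosis date minus the annotated gestational age
#' (`7 * ga_weeks + ga_days`) for the most recently dated annotation. A
#' missing days component counts as 0. When two annotations share the latest
#' date but disagree, the one implying the later onset (smaller gestational
#' age) is used and a warning is emitted.
#'
#' @param ga_diagnoses a data frame with columns `diagnosis_date` (Date),
#'   `ga_weeks` (integer) and optionally `ga_days`.
#' @return The estimated onset date.
#' @export
#' @examples
#' estimate_onset(data.frame(
#'   diagnosis_date = as.Date("2015-06-01"), ga_weeks = 38, ga_days = 0
#' ))  # 2014-09-08
estimate_onset <- function(ga_diagnoses) {
  dx <- as.data.frame(ga_diagnoses)
  dx <- dx[!is.na(dx$ga_weeks), , drop = FALSE]
  if (!nrow(dx)) {
    rlang::abort("no gestational-age annotated diagnoses: pregnancy undatable",
                 class = "kampopreg_undatable")
  }
  if (any(dx$ga_weeks > 45L)) {
    rlang::abort("ga_weeks above 45 is not a plausible annotation")
  }
  ga_days <- if ("ga_days" %in% names(dx)) dx$ga_days else 0L
  ga_days[is.na(ga_days)] <- 0L
  total <- 7L * dx$ga_weeks + ga_days
  latest <- dx$diagnosis_date == max(dx$diagnosis_date)
  cand <- total[latest]
  if (length(unique(cand)) > 1) {
    rlang::warn(
      "conflicting gestational ages on the latest visit; using the smaller (later onset)"
    )
  }
  max(dx$diagnosis_date) - min(cand)
}

#' Estimate the delivery date
#'
#' Tiered rule: the latest specific delivery procedure entry if any; else the
#' latest other delivery-related entry; else the 15th of the infant's birth
#' month. Entries dated outside the birth month plus or minus one month are
#' implausible and ignored with a warning.
#'
#' @param delivery_entries data frame with columns `entry_date` (Date) and
#'   `entry_kind` (`"specific_procedure"` or `"other_delivery_related"`); may
#'   be empty.
#' @param infant_birth_year_month the infant's birth month, `"YYYY-MM"`.
#' @return A list of class `delivery_estimate` with `delivery_date` and
#'   `method` (`specific_entry`, `other_entry` or `month_midpoint`).
#' @export
estimate_delivery <- function(delivery_entries, infant_birth_year_month) {
  stopifnot(length(infant_birth_year_month) == 1,
            !is.na(infant_birth_year_month))
  de <- as.data.frame(delivery_entries)
  if (nrow(de)) {
    birth_idx <- ym_index(infant_birth_year_month)
    entry_idx <- ym_index(date_ym(de$entry_date))
    plausible <- abs(entry_idx - birth_idx) <= 1L
    if (any(!plausible)) {
      rlang::warn(sprintf(
        "%d delivery entr%s dated outside the birth month +/- 1 ignored",
        sum(!plausible), if (sum(!plausible) == 1) "y" else "ies"
      ))
      de <- de[plausible, , drop = FALSE]
    }
  }
  pick <- function(kind) {
    sel <- de[de$entry_kind == kind, , drop = FALSE]
    if (nrow(sel)) max(sel$entry_date) else NULL
  }
  d <- pick("specific_procedure")
  if (!is.null(d)) {
    return(new_delivery_estimate(d, "specific_entry"))
  }
  d <- pick("other_delivery_related")
  if (!is.null(d)) {
    return(new_delivery_estimate(d, "other_entry"))
  }
  new_delivery_estimate(ym_mid_day(infant_birth_year_month), "month_midpoint")
}

new_delivery_estimate <- function(date, method) {
  structure(list(delivery_date = date, method = method),
            class = "delivery_estimate")
}

#' Build a pregnancy episode with trimester windows
#'
#' Combines the onset and delivery estimates into a dated episode. If the
#' implied gestation exceeds 294 days, onset is moved to 294 days before
#' delivery (`capped_294 = TRUE`). Trimester windows are closed calendar-day
#' intervals over gestational days 0-97 (first), 98-195 (second) and
#' 196-delivery (third), each clipped at delivery; a window the pregnancy
#' never reaches is empty (NA dates).
#'
#' @param onset estimated onset date.
#' @param delivery a `delivery_estimate` (or a bare Date, treated as a
#'   specific entry).
#' @return A list of class `pregnancy_episode`.
#' @export
#' @examples
#' ep <- build_episode(as.Date("2014-09-08"),
#'                     as.Date("2015-06-01"))
#' ep$gestation_days  # 266
build_episode <- function(onset, delivery) {
  if (inherits(delivery, "delivery_estimate")) {
    dd <- delivery$delivery_date
    method <- delivery$method
  } else {
    dd <- as.Date(delivery)
    method <- "specific_entry"
  }
  if (is.na(onset) || is.na(dd) || onset > dd) {
    rlang::abort("invalid episode: onset must be on or before delivery",
                 class = "kampopreg_invalid_episode")
  }
  capped <- FALSE
  if (as.integer(dd - onset) > GESTATION_CAP_DAYS) {
    onset <- dd - GESTATION_CAP_DAYS
    capped <- TRUE
  }
  gestation <- as.integer(dd - onset)
  win <- function(lo, hi) {
    if (gestation < lo) return(c(as.Date(NA), as.Date(NA)))
    c(onset + lo, min(onset + hi, dd))
  }
  structure(list(
    onset_date = onset,
    delivery_date = dd,
    delivery_method = method,
    capped_294 = capped,
    gestation_days = gestation,
    t1_start = onset, t1_end = win(0L, T1_END_DAY)[2],
    t2_start = win(98L, T2_END_DAY)[1], t2_end = win(98L, T2_END_DAY)[2],
    t3_start = win(196L, GESTATION_CAP_DAYS)[1],
    t3_end = win(196L, GESTATION_CAP_DAYS)[2]
  ), class = "pregnancy_episode")
}

#' Trimester containing a date
#'
#' @param d a date (vectorised).
#' @param episode a `pregnancy_episode`.
#' @return Factor-like character vector: `pre_pregnancy`, `first`, `second`,
#'   `third` or `post_delivery`.
#' @export
assign_trimester <- function(d, episode) {
  stopifnot(inherits(episode, "pregnancy_episode"))
  d <- as.Date(d)
  offset <- as.integer(d - episode$onset_date)
  dplyr::case_when(
    offset < 0L ~ "pre_pregnancy",
    offset > episode$gestation_days ~ "post_delivery",
    offset <= T1_END_DAY ~ "first",
    offset <= T2_END_DAY ~ "second",
    TRUE ~ "third"
  )
}

#' Estimate pregnancy episodes for every linkable mother in a bundle
#'
#' Vectorised dating over a claims bundle: onset from each mother's most
#' recent gestational-age annotation, delivery from her delivery entries with
#' the mid-month fallback on the (first) linked infant's birth month, then
#' the 294-day cap and trimester windows. Mothers with no gestational-age
#' annotation are returned with `datable = FALSE`.
#'
#' @param bundle a `claims_bundle`.
#' @return A tibble, one row per mother appearing in `links`, with onset and
#'   delivery dates, dating method, `capped_294`, `gestation_days`, trimester
#'   window bounds and `datable`.
#' @export
estimate_episodes <- function(bundle) {
  mothers <- unique(bundle$links$mother_id)
  birth_ym <- bundle$links |>
    dplyr::left_join(
      dplyr::select(bundle$enrollment, "person_id", "birth_year_month"),
      by = c("infant_id" = "person_id")
    ) |>
    dplyr::distinct(.data$mother_id, .keep_all = TRUE) |>
    dplyr::transmute(mother_id = .data$mother_id,
                     birth_ym = .data$birth_year_month)

  # onset: latest GA-annotated diagnosis; smaller GA wins on date ties
  onset_tbl <- bundle$diagnoses |>
    dplyr::filter(!is.na(.data$ga_weeks), .data$person_id %in% mothers) |>
    dplyr::mutate(ga_total = 7L * .data$ga_weeks +
                    dplyr::coalesce(.data$ga_days, 0L)) |>
    dplyr::arrange(.data$person_id, dplyr::desc(.data$diagnosis_date),
                   .data$ga_total) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::transmute(mother_id = .data$person_id,
                     onset_date = .data$diagnosis_date - .data$ga_total)

  # delivery: specific entry > other entry > mid-month fallback
  entries <- bundle$delivery_entries |>
    dplyr::filter(.data$person_id %in% mothers) |>
    dplyr::left_join(birth_ym, by = c("person_id" = "mother_id")) |>
    dplyr::filter(abs(ym_index(date_ym(.data$entry_date)) -
                        ym_index(.data$birth_ym)) <= 1L) |>
    dplyr::mutate(tier = dplyr::if_else(
      .data$entry_kind == "specific_procedure", 1L, 2L)) |>
    dplyr::arrange(.data$person_id, .data$tier,
                   dplyr::desc(.data$entry_date)) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::transmute(
      mother_id = .data$person_id,
      entry_delivery = .data$entry_date,
      entry_method = dplyr::if_else(.data$tier == 1L, "specific_entry",
                                    "other_entry")
    )

  ep <- birth_ym |>
    dplyr::left_join(onset_tbl, by = "mother_id") |>
    dplyr::left_join(entries, by = "mother_id") |>
    dplyr::mutate(
      delivery_date = dplyr::coalesce(.data$entry_delivery,
                                      ym_mid_day(.data$birth_ym)),
      delivery_method = dplyr::coalesce(.data$entry_method, "month_midpoint"),
      datable = !is.na(.data$onset_date) &
        .data$onset_date <= .data$delivery_date,
      capped_294 = .data$datable &
        as.integer(.data$delivery_date - .data$onset_date) > GESTATION_CAP_DAYS,
      onset_date = dplyr::if_else(.data$capped_294,
                                  .data$delivery_date - GESTATION_CAP_DAYS,
                                  .data$onset_date),
      gestation_days = as.integer(.data$delivery_date - .data$onset_date)
    ) |>
    dplyr::mutate(
      t1_start = .data$onset_date,
      t1_end = pmin(.data$onset_date + T1_END_DAY, .data$delivery_date),
      t2_start = dplyr::if_else(.data$gestation_days >= 98L,
                                .data$onset_date + 98L, as.Date(NA)),
      t2_end = dplyr::if_else(.data$gestation_days >= 98L,
                              pmin(.data$onset_date + T2_END_DAY,
                                   .data$delivery_date), as.Date(NA)),
      t3_start = dplyr::if_else(.data$gestation_days >= 196L,
                                .data$onset_date + 196L, as.Date(NA)),
      t3_end = dplyr::if_else(.data$gestation_days >= 196L,
                              .data$delivery_date, as.Date(NA))
    ) |>
    dplyr::select("mother_id", "onset_date", "delivery_date",
                  "delivery_method", "capped_294", "gestation_days",
                  "datable", dplyr::starts_with("t1_"),
                  dplyr::starts_with("t2_"), dplyr::starts_with("t3_"))
  ep
}
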