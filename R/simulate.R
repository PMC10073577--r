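# Synthetic claims generator. Every downstream stage of the pipeline is
# exercised on bundles produced here, with a truth table (true pregnancy
# dates, true exposure flags, true outcome status) retained so parameter
# recovery can be tested. Generation is truth-first: all claim rows are laid
# down consistently with the true dates, then missingness (lost dispensing
# dates, absent delivery entries) is injected, so the truth file stays exact.

MCM_SYSTEM_CODES <- c(
  nervous = "Q05", eye_ear_face_neck = "Q11", circulatory = "Q21",
  respiratory = "Q33", cleft_lip_palate = "Q35", digestive = "Q41",
  genital = "Q54", urinary = "Q61", musculoskeletal = "Q71", other = "Q80"
)

# organ-system mix among malformed infants (relative weights)
MCM_SYSTEM_WEIGHTS <- c(
  nervous = 43, eye_ear_face_neck = 13, circulatory = 248, respiratory = 34,
  cleft_lip_palate = 15, digestive = 47, genital = 44, urinary = 48,
  musculoskeletal = 216, other = 27
)

# relative product mix within the rhubarb-Kampo class
KRR_PRODUCT_WEIGHTS <- c(
  mashiningan = 321, daiokanzoto = 198, otsujito = 160, bofutsushosan = 111,
  tokakujokito = 74, keishikashakuyakudaioto = 64, junchoto = 51,
  crude_daio = 30, tsudosan = 10, choijokito = 8, jidabokuippo = 8,
  daisaikoto = 8, daiobotampito = 5, sanoshashinto = 4, inchinkoto = 3,
  jizusoippo = 1, daijokito = 1
)

CONDITION_DX_CODE <- c(
  hypertension = "I10", diabetes = "E11", obesity = "E66",
  epilepsy = "G40", phenylketonuria = "E70.0"
)

#' Generate a synthetic claims bundle with known ground truth
#'
#' Simulates one pregnancy per mother: true onset and delivery dates,
#' month-granular enrollment spans for mother and infant, gestational-age
#' annotated antenatal diagnoses consistent with the true onset, delivery
#' related entries (or their absence), laxative and teratogen prescriptions
#' with days of supply, maternal condition diagnoses, and infant
#' malformation diagnoses whose probability follows a logistic model with a
#' configurable true exposure effect.
#'
#' @param config a [sim_config()].
#' @return A list with elements `bundle` (class `claims_bundle`: tibbles
#'   `enrollment`, `diagnoses`, `prescriptions`, `delivery_entries`, `links`)
#'   and `truth` (one row per mother: true dates, true per-class trimester
#'   exposure flags, true covariates and outcome).
#' @export
#' @examples
#' sim <- generate_bundle(sim_config(n_mothers = 50, seed = 1))
#' nrow(sim$truth)
generate_bundle <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be built with sim_config()",
                 class = "kampopreg_config_error")
  }
  withr::with_seed(config$seed, generate_bundle_impl(config))
}

generate_bundle_impl <- function(cfg) {
  n <- cfg$n_mothers
  mother_id <- sprintf("M%06d", seq_len(n))
  infant_id <- sprintf("I%06d", seq_len(n))
  family_id <- sprintf("F%06d", seq_len(n))

  ## --- true pregnancy dates ------------------------------------------------
  year <- sample(cfg$delivery_years, n, replace = TRUE,
                 prob = cfg$delivery_year_weights)
  day_in_year <- sample.int(365L, n, replace = TRUE) - 1L
  delivery <- as.Date(sprintf("%d-01-01", year)) + day_in_year
  # truncated-normal gestation via inverse CDF
  lo <- pnorm(cfg$gestation_min_days, cfg$gestation_mean_days,
              cfg$gestation_sd_days)
  hi <- pnorm(cfg$gestation_max_days, cfg$gestation_mean_days,
              cfg$gestation_sd_days)
  gestation <- round(qnorm(runif(n, lo, hi), cfg$gestation_mean_days,
                           cfg$gestation_sd_days))
  gestation <- pmin(pmax(gestation, cfg$gestation_min_days),
                    cfg$gestation_max_days)
  gestation <- as.integer(gestation)
  onset <- delivery - gestation

  ## --- maternal covariates -------------------------------------------------
  age <- pmin(pmax(rnorm(n, cfg$maternal_age_mean, cfg$maternal_age_sd), 16), 49)
  mother_birth_ym <- date_ym(delivery - round(age * 365.25))
  prev <- cfg$covariate_prevalences
  draw <- function(name) {
    p <- if (name %in% names(prev)) prev[[name]] else 0
    runif(n) < p
  }
  cov_flags <- tibble::tibble(
    hypertension = draw("hypertension"), diabetes = draw("diabetes"),
    obesity = draw("obesity"), epilepsy = draw("epilepsy"),
    phenylketonuria = draw("phenylketonuria"),
    teratogen = draw("teratogen"), caesarean = draw("caesarean")
  )
  preterm <- gestation < 259L
  churned <- runif(n) < cfg$enrollment_churn
  twins <- runif(n) < cfg$p_multiple_birth
  chromo <- runif(n) < cfg$p_chromosomal_abnormality

  ## --- enrollment ----------------------------------------------------------
  onset_ym <- date_ym(onset)
  delivery_ym <- date_ym(delivery)
  # churned mothers enroll too late for the 3-months-before-onset requirement
  mother_start <- ifelse(churned, ym_shift(onset_ym, -1L), ym_shift(onset_ym, -4L))
  mother_end <- ym_shift(delivery_ym, 2L)
  enrollment_mother <- tibble::tibble(
    person_id = mother_id, family_id = family_id, role = "mother",
    coverage_start_month = mother_start, coverage_end_month = mother_end,
    birth_year_month = mother_birth_ym, sex = "F"
  )
  infant_sex <- sample(c("M", "F"), n, replace = TRUE)
  enrollment_infant <- tibble::tibble(
    person_id = infant_id, family_id = family_id, role = "infant",
    coverage_start_month = delivery_ym,
    coverage_end_month = ym_shift(delivery_ym, 13L),
    birth_year_month = delivery_ym, sex = infant_sex
  )
  links <- tibble::tibble(
    mother_id = mother_id, infant_id = infant_id, family_id = family_id
  )
  # twins: a second infant born the same month, linked to the same mother
  if (any(twins)) {
    tw <- which(twins)
    twin_id <- sprintf("W%06d", tw)
    enrollment_twin <- enrollment_infant[tw, ]
    enrollment_twin$person_id <- twin_id
    enrollment_twin$sex <- sample(c("M", "F"), length(tw), replace = TRUE)
    enrollment_infant <- dplyr::bind_rows(enrollment_infant, enrollment_twin)
    links <- dplyr::bind_rows(links, tibble::tibble(
      mother_id = mother_id[tw], infant_id = twin_id, family_id = family_id[tw]
    ))
  }
  enrollment <- dplyr::bind_rows(enrollment_mother, enrollment_infant)

  ## --- delivery entries ----------------------------------------------------
  u <- runif(n)
  entry_kind <- dplyr::case_when(
    u < cfg$p_delivery_entry_specific ~ "specific_procedure",
    u < cfg$p_delivery_entry_specific + cfg$p_delivery_entry_other ~
      "other_delivery_related",
    TRUE ~ NA_character_
  )
  has_entry <- !is.na(entry_kind)
  delivery_entries <- tibble::tibble(
    person_id = mother_id[has_entry],
    entry_date = delivery[has_entry],
    entry_kind = entry_kind[has_entry]
  )

  ## --- gestational-age annotated antenatal diagnoses -----------------------
  sched <- sort(as.integer(cfg$ga_visit_schedule))
  ga_dx <- tidyr::expand_grid(idx = seq_len(n), ga_weeks = sched) |>
    dplyr::mutate(gest = gestation[.data$idx]) |>
    dplyr::filter(7L * .data$ga_weeks <= .data$gest) |>
    dplyr::mutate(
      person_id = mother_id[.data$idx],
      icd10_code = "Z34",
      diagnosis_date = onset[.data$idx] + 7L * .data$ga_weeks,
      ga_days = 0L
    ) |>
    dplyr::select("person_id", "icd10_code", "diagnosis_date",
                  "ga_weeks", "ga_days")

  ## --- maternal condition diagnoses ----------------------------------------
  cond_dx <- purrr::map(names(CONDITION_DX_CODE), function(cv) {
    hit <- which(cov_flags[[cv]])
    if (!length(hit)) return(NULL)
    tibble::tibble(
      person_id = mother_id[hit],
      icd10_code = CONDITION_DX_CODE[[cv]],
      diagnosis_date = onset[hit] +
        floor(runif(length(hit)) * pmin(gestation[hit], 180L)),
      ga_weeks = NA_integer_, ga_days = NA_integer_
    )
  }) |> dplyr::bind_rows()
  cae <- which(cov_flags$caesarean)
  cae_dx <- tibble::tibble(
    person_id = mother_id[cae], icd10_code = "O82",
    diagnosis_date = delivery[cae],
    ga_weeks = NA_integer_, ga_days = NA_integer_
  )

  ## --- laxative prescriptions ----------------------------------------------
  # trimester windows in gestational days (closed; third exists from day 196)
  tri_lo <- c(0L, 98L, 196L)
  tri_hi_cap <- c(97L, 195L, 294L)
  rx_parts <- list()
  for (cl in names(cfg$rx_propensity)) {
    for (tri in 1:3) {
      p <- cfg$rx_propensity[[cl]][tri]
      if (p <= 0) next
      reach <- gestation >= tri_lo[tri]           # pregnancy reaches trimester
      hit <- which(reach & runif(n) < p)
      if (!length(hit)) next
      # repeat dispensings: chronic laxative use is refilled within a
      # trimester, so a prescribed mother draws 1 + Poisson(1) fills
      n_fill <- 1L + stats::rpois(length(hit), cfg$rx_repeats_lambda)
      hit <- rep(hit, n_fill)
      win_lo <- tri_lo[tri]
      win_hi <- pmin(tri_hi_cap[tri], gestation[hit])
      offset <- win_lo + floor(runif(length(hit)) * (win_hi - win_lo + 1L))
      rx_parts[[length(rx_parts) + 1L]] <- tibble::tibble(
        idx = hit, drug_class = cl,
        true_date = onset[hit] + as.integer(offset)
      )
    }
  }
  rx <- dplyr::bind_rows(rx_parts)
  if (nrow(rx)) {
    rx$days_of_supply <- sample(c(7L, 14L, 30L), nrow(rx), replace = TRUE,
                                prob = c(0.35, 0.45, 0.20))
    rx$as_needed <- runif(nrow(rx)) < cfg$p_as_needed
    rx$drug_code <- rx$drug_class
    rx$drug_code[rx$drug_class == "MgO"] <- "A02AA02"
    rx$drug_code[rx$drug_class == "SG"] <- "A06AB06"
    is_krr <- rx$drug_class == "KRR"
    if (any(is_krr)) {
      rx$drug_code[is_krr] <- sample(
        names(KRR_PRODUCT_WEIGHTS), sum(is_krr), replace = TRUE,
        prob = KRR_PRODUCT_WEIGHTS / sum(KRR_PRODUCT_WEIGHTS)
      )
    }
    rx$drug_code[rx$drug_class == "daikenchuto"] <- "daikenchuto"
  } else {
    rx <- tibble::tibble(idx = integer(), drug_class = character(),
                         true_date = as.Date(character()),
                         days_of_supply = integer(), as_needed = logical(),
                         drug_code = character())
  }

  ## --- true exposure flags (interval overlap with true trimester windows) --
  truth_flags <- matrix(FALSE, nrow = n, ncol = 12)
  classes <- c("MgO", "KRR", "SG", "daikenchuto")
  colnames(truth_flags) <- paste0(
    rep(c("mgo", "krr", "sg", "dkt"), each = 3), "_t", rep(1:3, 4)
  )
  if (nrow(rx)) {
    g <- gestation[rx$idx]
    start_off <- as.integer(rx$true_date - onset[rx$idx])
    end_off <- start_off + rx$days_of_supply - 1L
    for (ci in seq_along(classes)) {
      for (tri in 1:3) {
        w_lo <- tri_lo[tri]
        w_hi <- pmin(tri_hi_cap[tri], g)
        sel <- rx$drug_class == classes[ci] & g >= w_lo &
          start_off <= w_hi & end_off >= w_lo
        if (any(sel)) {
          col <- (ci - 1L) * 3L + tri
          truth_flags[unique(rx$idx[sel]), col] <- TRUE
        }
      }
    }
  }

  ## --- teratogen prescriptions (always dated, first trimester) -------------
  ter <- which(cov_flags$teratogen)
  ter_rx <- tibble::tibble(
    person_id = mother_id[ter], drug_code = "valproate",
    dispense_date = onset[ter] +
      floor(runif(length(ter)) * (pmin(97L, gestation[ter]) + 1L)),
    admission_date = as.Date(NA),
    days_of_supply = 14L, as_needed = FALSE
  )
  ter_rx$claim_year_month <- date_ym(ter_rx$dispense_date)

  ## --- missingness injection on laxative dispensing dates ------------------
  if (nrow(rx)) {
    miss <- runif(nrow(rx)) < cfg$p_missing_dispense_date
    keep_admission <- miss & (runif(nrow(rx)) < 0.5)
    prescriptions <- tibble::tibble(
      person_id = mother_id[rx$idx],
      drug_code = rx$drug_code,
      dispense_date = dplyr::if_else(miss, as.Date(NA), rx$true_date),
      admission_date = dplyr::if_else(keep_admission, rx$true_date, as.Date(NA)),
      claim_year_month = date_ym(rx$true_date),
      days_of_supply = rx$days_of_supply,
      as_needed = rx$as_needed
    )
  } else {
    prescriptions <- tibble::tibble(
      person_id = character(), drug_code = character(),
      dispense_date = as.Date(character()), admission_date = as.Date(character()),
      claim_year_month = character(), days_of_supply = integer(),
      as_needed = logical()
    )
  }
  prescriptions <- dplyr::bind_rows(
    prescriptions,
    ter_rx[, c("person_id", "drug_code", "dispense_date", "admission_date",
               "claim_year_month", "days_of_supply", "as_needed")]
  )

  ## --- infant outcome ------------------------------------------------------
  lor <- function(nm) {
    v <- cfg$covariate_log_or
    if (nm %in% names(v)) v[[nm]] else 0
  }
  lp <- qlogis(cfg$mcm_base_rate) +
    cfg$true_log_or_krr * truth_flags[, "krr_t1"] +
    lor("preterm_birth") * preterm +
    lor("obesity") * cov_flags$obesity +
    lor("hypertension") * cov_flags$hypertension +
    lor("diabetes") * cov_flags$diabetes +
    lor("epilepsy") * cov_flags$epilepsy +
    lor("teratogen") * cov_flags$teratogen
  mcm <- runif(n) < plogis(lp)
  mcm_system <- rep(NA_character_, n)
  mcm_system[mcm] <- sample(names(MCM_SYSTEM_WEIGHTS), sum(mcm), replace = TRUE,
                            prob = MCM_SYSTEM_WEIGHTS / sum(MCM_SYSTEM_WEIGHTS))
  mcm_idx <- which(mcm)
  mcm_dx <- tibble::tibble(
    person_id = infant_id[mcm_idx],
    icd10_code = unname(MCM_SYSTEM_CODES[mcm_system[mcm_idx]]),
    diagnosis_date = ym_first_day(delivery_ym[mcm_idx]) +
      floor(runif(length(mcm_idx)) * 330),
    ga_weeks = NA_integer_, ga_days = NA_integer_
  )
  # occasional minor anomalies, excluded from the major count downstream
  minor_idx <- which(runif(n) < 0.01)
  minor_dx <- tibble::tibble(
    person_id = infant_id[minor_idx], icd10_code = "Q17",
    diagnosis_date = ym_first_day(delivery_ym[minor_idx]) +
      floor(runif(length(minor_idx)) * 330),
    ga_weeks = NA_integer_, ga_days = NA_integer_
  )
  chromo_idx <- which(chromo)
  chromo_dx <- tibble::tibble(
    person_id = infant_id[chromo_idx], icd10_code = "Q91",
    diagnosis_date = ym_first_day(delivery_ym[chromo_idx]) +
      floor(runif(length(chromo_idx)) * 200),
    ga_weeks = NA_integer_, ga_days = NA_integer_
  )

  diagnoses <- dplyr::bind_rows(ga_dx, cond_dx, cae_dx, mcm_dx, minor_dx,
                                chromo_dx) |>
    dplyr::arrange(.data$person_id, .data$diagnosis_date, .data$icd10_code)

  bundle <- new_claims_bundle(
    enrollment = enrollment, diagnoses = diagnoses,
    prescriptions = dplyr::arrange(prescriptions, .data$person_id,
                                   .data$claim_year_month, .data$drug_code),
    delivery_entries = delivery_entries, links = links
  )

  truth <- dplyr::bind_cols(
    tibble::tibble(
      mother_id = mother_id, infant_id = infant_id,
      true_onset_date = onset, true_delivery_date = delivery,
      true_gestation_days = gestation,
      maternal_age = age, preterm_birth = preterm
    ),
    cov_flags,
    tibble::as_tibble(truth_flags),
    tibble::tibble(
      true_mcm = mcm, mcm_system = mcm_system,
      multiple_birth = twins, chromosomal = chromo, churned = churned
    )
  )
  list(bundle = bundle, truth = truth)
}
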