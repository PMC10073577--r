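#' Configuration for the synthetic claims generator
#'
#' Defines the study conditions the generator emulates. Defaults reproduce the
#' source database's published marginals: gestation length at delivery with
#' mean 270.7 days (SD 12.9, range 119-294), delivery-date provenance shares
#' (49.4% dated by a specific delivery procedure, 9.4% by another
#' delivery-related entry, the remaining 41.2% by the mid-month fallback),
#' per-trimester laxative prescription prevalences, Table-1-style covariate
#' prevalences, and a 6.1% base rate of major congenital malformations.
#'
#' @param n_mothers number of pregnancies to simulate (one infant each unless
#'   a multiple birth is drawn).
#' @param seed integer seed; identical configs give byte-identical bundles.
#' @param gestation_mean_days,gestation_sd_days,gestation_min_days,gestation_max_days
#'   truncated-normal gestation length in days.
#' @param p_delivery_entry_specific,p_delivery_entry_other probability a
#'   mother's claims carry a specific delivery procedure entry / some other
#'   delivery-related entry dated on the true delivery day; the remainder has
#'   no delivery entry at all and is datable only through the infant's birth
#'   month.
#' @param ga_visit_schedule gestational weeks at which a gestational-age
#'   annotated antenatal diagnosis is emitted (only visits falling before
#'   delivery occur).
#' @param p_missing_dispense_date probability a laxative prescription row
#'   loses its dispensing date; half of those retain an admission date, the
#'   rest fall back to the mid-month rule downstream.
#' @param p_as_needed probability a laxative prescription is flagged
#'   as-needed (PRN) rather than scheduled.
#' @param rx_repeats_lambda Poisson mean of extra fills beyond the first for
#'   a mother prescribed a class in a trimester (refills are routine for
#'   chronic laxative use).
#' @param rx_propensity named list (MgO, SG, KRR, daikenchuto) of length-3
#'   numeric vectors: probability of at least one prescription in trimesters
#'   1-3 (a trimester a pregnancy never reaches draws nothing).
#' @param mcm_base_rate probability of a major congenital malformation for an
#'   unexposed, covariate-free infant.
#' @param true_log_or_krr log odds ratio of MCM conferred by first-trimester
#'   rhubarb-Kampo exposure; 0 is the null.
#' @param covariate_prevalences named numeric vector of maternal covariate
#'   probabilities.
#' @param covariate_log_or named numeric vector of log odds ratios linking
#'   covariates to MCM; defaults are null except modest preterm-birth and
#'   obesity effects.
#' @param maternal_age_mean,maternal_age_sd maternal age at delivery (years).
#' @param p_multiple_birth probability a delivery is twins (excluded
#'   downstream by design).
#' @param p_chromosomal_abnormality probability the infant receives a
#'   chromosomal (Q90-Q99) diagnosis (an exclusion criterion, not an
#'   outcome).
#' @param enrollment_churn probability the mother's coverage starts too late
#'   to satisfy the 3-months-before-pregnancy enrollment requirement.
#' @param delivery_years integer years deliveries are drawn from.
#' @param delivery_year_weights sampling weight per delivery year.
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_mothers = 100, seed = 1)
sim_config <- function(n_mothers,
                       seed,
                       gestation_mean_days = 270.7,
                       gestation_sd_days = 12.9,
                       gestation_min_days = 119,
                       gestation_max_days = 294,
                       p_delivery_entry_specific = 0.494,
                       p_delivery_entry_other = 0.094,
                       ga_visit_schedule = c(8L, 12L, 20L, 30L, 38L),
                       p_missing_dispense_date = 0.10,
                       p_as_needed = 0.20,
                       rx_repeats_lambda = 1,
                       rx_propensity = list(
                         MgO = c(0.1390, 0.2128, 0.2245),
                         SG = c(0.0211, 0.0286, 0.0486),
                         KRR = c(0.0063, 0.0061, 0.0060),
                         daikenchuto = c(0.0018, 0.0020, 0.0026)
                       ),
                       mcm_base_rate = 0.061,
                       true_log_or_krr = 0,
                       covariate_prevalences = c(
                         hypertension = 0.017, diabetes = 0.045,
                         obesity = 0.007, epilepsy = 0.009,
                         phenylketonuria = 0, teratogen = 0.004,
                         caesarean = 0.227
                       ),
                       covariate_log_or = c(
                         preterm_birth = log(1.5), obesity = log(1.5)
                       ),
                       maternal_age_mean = 32.3,
                       maternal_age_sd = 4.6,
                       p_multiple_birth = 0.02,
                       p_chromosomal_abnormality = 0.003,
                       enrollment_churn = 0.05,
                       delivery_years = 2010:2019,
                       delivery_year_weights = c(
                         rep(0.113 / 3, 3), rep(0.358 / 3, 3), rep(0.53 / 4, 4)
                       )) {
  cfg <- as.list(environment())

  fail <- function(field, msg) {
    rlang::abort(sprintf("invalid sim_config field `%s`: %s", field, msg),
                 class = "kampopreg_config_error")
  }
  if (!is.numeric(n_mothers) || length(n_mothers) != 1 || n_mothers < 1 ||
      n_mothers != floor(n_mothers)) {
    fail("n_mothers", "must be a single integer >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed)) {
    fail("seed", "must be a single integer")
  }
  probs <- c("p_delivery_entry_specific", "p_delivery_entry_other",
             "p_missing_dispense_date", "p_as_needed", "mcm_base_rate",
             "p_multiple_birth", "p_chromosomal_abnormality",
             "enrollment_churn")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      fail(p, "must be a probability in [0, 1]")
    }
  }
  if (cfg$p_delivery_entry_specific + cfg$p_delivery_entry_other > 1) {
    fail("p_delivery_entry_other",
         "delivery-entry probabilities must sum to at most 1")
  }
  if (!is.numeric(rx_repeats_lambda) || rx_repeats_lambda < 0) {
    fail("rx_repeats_lambda", "must be a non-negative rate")
  }
  if (any(covariate_prevalences < 0 | covariate_prevalences > 1)) {
    fail("covariate_prevalences", "all values must be probabilities in [0, 1]")
  }
  if (!(gestation_min_days <= gestation_max_days)) {
    fail("gestation_min_days", "must be <= gestation_max_days")
  }
  if (gestation_max_days > 294) {
    fail("gestation_max_days", "must be <= 294 (post-term cap)")
  }
  for (cl in names(rx_propensity)) {
    v <- rx_propensity[[cl]]
    if (!is.numeric(v) || length(v) != 3 || any(v < 0 | v > 1)) {
      fail("rx_propensity",
           sprintf("class %s needs 3 trimester probabilities in [0, 1]", cl))
    }
  }
  if (length(delivery_year_weights) != length(delivery_years) ||
      any(delivery_year_weights < 0)) {
    fail("delivery_year_weights",
         "must be non-negative, one weight per delivery year")
  }
  cfg$n_mothers <- as.integer(n_mothers)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_mothers, "mothers, seed", x$seed, "\n")
  cat("  gestation:", x$gestation_mean_days, "+/-", x$gestation_sd_days,
      "d, range [", x$gestation_min_days, ",", x$gestation_max_days, "]\n")
  cat("  true KRR log-OR:", x$true_log_or_krr, "\n")
  invisible(x)
}
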