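# Shared fixtures and independent oracles.

# A minimal one-mother bundle: datable pregnancy (266 days), full coverage,
# infant enrolled from birth month. Tests override individual tables.
tiny_tables <- function(delivery = as.Date("2016-03-10"), gestation = 266L) {
  onset <- delivery - gestation
  list(
    enrollment = tibble::tibble(
      person_id = c("M1", "I1"), family_id = "F1",
      role = c("mother", "infant"),
      coverage_start_month = c(format(onset - 200, "%Y-%m"),
                               format(delivery, "%Y-%m")),
      coverage_end_month = c(format(delivery + 90, "%Y-%m"),
                             format(delivery + 450, "%Y-%m")),
      birth_year_month = c("1982-12", format(delivery, "%Y-%m")),
      sex = c("F", "M")
    ),
    diagnoses = tibble::tibble(
      person_id = "M1", icd10_code = "Z34",
      diagnosis_date = onset + 7L * 12L, ga_weeks = 12L, ga_days = 0L
    ),
    prescriptions = tibble::tibble(
      person_id = character(), drug_code = character(),
      dispense_date = as.Date(character()),
      admission_date = as.Date(character()),
      claim_year_month = character(), days_of_supply = integer(),
      as_needed = logical()
    ),
    delivery_entries = tibble::tibble(
      person_id = "M1", entry_date = delivery,
      entry_kind = "specific_procedure"
    ),
    links = tibble::tibble(mother_id = "M1", infant_id = "I1",
                           family_id = "F1")
  )
}

bundle_from <- function(tbls) {
  kampopreg:::new_claims_bundle(
    enrollment = tbls$enrollment, diagnoses = tbls$diagnoses,
    prescriptions = tbls$prescriptions,
    delivery_entries = tbls$delivery_entries, links = tbls$links
  )
}

# Brute-force day-by-day trimester labelling: the oracle for window
# construction and interval overlap, independent of the episode arithmetic.
brute_trimester_days <- function(onset, delivery) {
  offsets <- 0:as.integer(delivery - onset)
  labels <- ifelse(offsets <= 97, "first",
                   ifelse(offsets <= 195, "second", "third"))
  tibble::tibble(date = onset + offsets, label = labels)
}

# Exact conditional (permutation-enumeration) Cochran-Armitage p-value for a
# 2x3 table, mid-p corrected, under the multivariate hypergeometric null.
exact_trend_p <- function(x, n, midp = TRUE) {
  stopifnot(length(x) == 3, length(n) == 3)
  tot <- sum(x)
  sc <- 1:3
  tobs <- sum(sc * (x - n * tot / sum(n)))
  p <- 0
  for (x1 in 0:min(n[1], tot)) {
    for (x2 in 0:min(n[2], tot - x1)) {
      x3 <- tot - x1 - x2
      if (x3 < 0 || x3 > n[3]) next
      pr <- exp(sum(lchoose(n, c(x1, x2, x3))) - lchoose(sum(n), tot))
      t0 <- sum(sc * (c(x1, x2, x3) - n * tot / sum(n)))
      if (abs(t0) > abs(tobs) + 1e-9) {
        p <- p + pr
      } else if (abs(abs(t0) - abs(tobs)) <= 1e-9) {
        p <- p + if (midp) pr / 2 else pr
      }
    }
  }
  p
}

# Individual-level analysis rows realising a 2x2 table (for checking the
# logistic fit against the closed-form odds ratio).
rows_from_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    krr = rep(c(TRUE, TRUE, FALSE, FALSE), c(a, b, c, d)),
    mcm = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c, d))
  )
}
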