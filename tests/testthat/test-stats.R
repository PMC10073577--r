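test_that("the crude odds ratio and Woolf interval reproduce known tables", {
  r <- crude_or(28, 422, 680, 9172)
  expect_equal(round(r$or_point, 3), 0.895)
  expect_equal(round(r$ci_low, 3), 0.606)
  expect_equal(round(r$ci_high, 3), 1.322)
  expect_equal(r$n, 10302)
  expect_equal(r$n_events, 708)

  expect_equal(crude_or(1, 1, 1, 1)$or_point, 1)
  expect_equal(crude_or(10, 90, 20, 80)$or_point, 4 / 9)
  expect_error(crude_or(0, 10, 5, 10), class = "kampopreg_zero_cell")
  # continuity correction is available but off by default
  r0 <- crude_or(0, 10, 5, 10, continuity = TRUE)
  expect_equal(r0$or_point, (0.5 * 10.5) / (10.5 * 5.5))
  expect_error(crude_or(-1, 1, 1, 1))
})

test_that("inverting exposure labels reciprocates the OR and swaps CI ends", {
  r <- crude_or(28, 422, 680, 9172)
  inv <- crude_or(680, 9172, 28, 422)
  expect_equal(inv$or_point, 1 / r$or_point)
  expect_equal(inv$ci_low, 1 / r$ci_high)
  expect_equal(inv$ci_high, 1 / r$ci_low)
})

test_that("an exposure-only logistic fit equals the Woolf crude OR", {
  for (cells in list(c(28, 422, 680, 9172), c(12, 88, 40, 360))) {
    rows <- rows_from_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(rows, covariates = character())
    woolf <- crude_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fit$adjusted_or$or_point, woolf$or_point, tolerance = 1e-6)
    expect_equal(fit$adjusted_or$ci_low, woolf$ci_low, tolerance = 1e-6)
    expect_equal(fit$adjusted_or$ci_high, woolf$ci_high, tolerance = 1e-6)
  }
})

test_that("degenerate covariates are dropped with a warning, separation errors", {
  rows <- rows_from_2x2(12, 88, 40, 360)
  rows$epilepsy <- FALSE  # constant column
  expect_warning(fit <- fit_logistic(rows, covariates = "epilepsy"),
                 "degenerate")
  expect_equal(fit$dropped, "epilepsy")
  expect_true(fit$converged)

  expect_error(fit_logistic(rows_from_2x2(0, 50, 40, 360),
                            covariates = character()),
               class = "kampopreg_separation")
})

test_that("the trend z-statistic squares to the 1-df trend chi-square", {
  cases <- list(
    list(c(10, 20, 30), c(100, 100, 100)),
    list(c(5, 9, 14), c(50, 60, 70)),
    list(c(11958, 17838, 19843), c(75398, 75398, 75224))
  )
  for (cs in cases) {
    mine <- cochran_armitage(cs[[1]], cs[[2]])
    ref <- suppressWarnings(stats::prop.trend.test(cs[[1]], cs[[2]]))
    expect_equal(mine$z_statistic^2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("flat prescription frequencies give no trend", {
  r <- cochran_armitage(c(25, 25, 25), c(200, 200, 200))
  expect_equal(r$z_statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$direction, "none")
  expect_error(cochran_armitage(c(1, 2, 3), c(10, 0, 10)))
  expect_error(cochran_armitage(c(11, 2, 3), c(10, 10, 10)))
})

test_that("the asymptotic trend p agrees with the exact enumeration oracle", {
  cases <- list(
    list(c(8, 12, 15), c(40, 40, 40)),
    list(c(5, 9, 14), c(50, 50, 50)),
    list(c(10, 10, 18), c(60, 60, 60))
  )
  for (cs in cases) {
    asym <- cochran_armitage(cs[[1]], cs[[2]])$p_value
    exact <- exact_trend_p(cs[[1]], cs[[2]])
    expect_lt(abs(asym - exact), 0.01)
  }
  # tiny counts: the normal approximation is rougher but same order
  asym <- cochran_armitage(c(1, 2, 3), c(10, 10, 10))$p_value
  exact <- exact_trend_p(c(1, 2, 3), c(10, 10, 10))
  expect_lt(abs(asym - exact), 0.05)
})

test_that("group comparison reproduces the preterm chi-square", {
  rows <- tibble::tibble(
    group = rep(c("group1_mgo", "group2_krr"), c(9852, 450)),
    preterm_birth = c(rep(c(TRUE, FALSE), c(1165, 9852 - 1165)),
                      rep(c(TRUE, FALSE), c(72, 450 - 72)))
  )
  tab <- compare_groups(rows, categorical = "preterm_birth",
                        continuous = character())
  expect_equal(tab$group1_n, 1165)
  expect_equal(tab$group1_pct, 11.8)
  expect_equal(tab$group2_pct, 16)
  expect_equal(round(tab$p_value, 4), 0.0077)
})

test_that("identical groups compare with p = 1 and empty groups error", {
  rows <- tibble::tibble(
    group = rep(c("group1_mgo", "group2_krr"), each = 200),
    diabetes = rep(rep(c(TRUE, FALSE), c(20, 180)), 2),
    maternal_age = rep(rnorm(200, 32, 4), 2)
  )
  tab <- compare_groups(rows, categorical = "diabetes",
                        continuous = "maternal_age")
  expect_equal(tab$p_value[tab$variable == "diabetes"], 1, tolerance = 1e-12)
  expect_equal(tab$p_value[tab$variable == "maternal_age"], 1,
               tolerance = 1e-12)
  expect_error(compare_groups(rows[rows$group == "group1_mgo", ]),
               "non-empty")
})

test_that("small expected cells are flagged unreliable", {
  rows <- tibble::tibble(
    group = rep(c("group1_mgo", "group2_krr"), c(500, 8)),
    obesity = c(rep(c(TRUE, FALSE), c(2, 498)), rep(FALSE, 8))
  )
  tab <- compare_groups(rows, categorical = "obesity",
                        continuous = character())
  expect_true(all(tab$unreliable))
})

test_that("prevalence counting matches a per-mother recount on a fixture", {
  # five mothers, same episode shape, hand-placed prescriptions
  deliveries <- as.Date("2016-03-10") + 0:4
  tbls_list <- lapply(1:5, function(i) {
    t <- tiny_tables(delivery = deliveries[i])
    for (nm in c("enrollment", "diagnoses", "delivery_entries")) {
      t[[nm]]$person_id <- gsub("1$", i, t[[nm]]$person_id)
    }
    t$enrollment$family_id <- paste0("F", i)
    t$links <- tibble::tibble(mother_id = paste0("M", i),
                              infant_id = paste0("I", i),
                              family_id = paste0("F", i))
    t
  })
  tbls <- tbls_list[[1]]
  for (nm in names(tbls)) {
    tbls[[nm]] <- do.call(rbind, lapply(tbls_list, `[[`, nm))
  }
  onset1 <- deliveries[1] - 266
  # M1: MgO in trimesters 1 and 2 (two fills); M2: KRR trimester 3;
  # M3: MgO as one interval straddling the day-97/98 boundary
  tbls$prescriptions <- tibble::tibble(
    person_id = c("M1", "M1", "M2", "M3"),
    drug_code = c("A02AA02", "A02AA02", "otsujito", "A02AA02"),
    dispense_date = c(onset1 + 10, onset1 + 120, deliveries[2] - 30,
                      (deliveries[3] - 266) + 90),
    admission_date = as.Date(NA),
    claim_year_month = format(c(onset1 + 10, onset1 + 120, deliveries[2] - 30,
                                (deliveries[3] - 266) + 90), "%Y-%m"),
    days_of_supply = c(14L, 14L, 14L, 14L),
    as_needed = FALSE
  )
  b <- bundle_from(tbls)
  ep <- estimate_episodes(b)
  tab <- prevalence_table(b, ep)

  all_row <- tab[tab$product == "all_laxatives", ]
  expect_equal(all_row$n_total, 3L)   # M1, M2, M3 each counted once
  expect_equal(all_row$n_t1, 2L)      # M1 and M3
  expect_equal(all_row$n_t2, 2L)      # M1 (second fill) and M3 (straddle)
  expect_equal(all_row$n_t3, 1L)      # M2
  mgo <- tab[tab$product == "MgO", ]
  expect_equal(c(mgo$n_total, mgo$n_t1, mgo$n_t2, mgo$n_t3),
               c(2L, 2L, 2L, 0L))
  expect_equal(tab$n_t3[tab$product == "KRR"], 1L)
  expect_equal(tab$pct_total[tab$product == "all_laxatives"],
               round(100 * 3 / 5, 2))
})

test_that("third-trimester denominators exclude pregnancies ending early", {
  t1 <- tiny_tables(gestation = 266L)
  t2 <- tiny_tables(gestation = 150L)  # never reaches day 196
  for (nm in c("enrollment", "diagnoses", "delivery_entries")) {
    t2[[nm]]$person_id <- gsub("1", "2", t2[[nm]]$person_id)
  }
  t2$links <- tibble::tibble(mother_id = "M2", infant_id = "I2",
                             family_id = "F1")
  tbls <- t1
  for (nm in names(tbls)) tbls[[nm]] <- rbind(t1[[nm]], t2[[nm]])
  onset1 <- as.Date("2016-03-10") - 266
  tbls$prescriptions <- tibble::tibble(
    person_id = "M1", drug_code = "A02AA02",
    dispense_date = onset1 + 200, admission_date = as.Date(NA),
    claim_year_month = format(onset1 + 200, "%Y-%m"),
    days_of_supply = 14L, as_needed = FALSE
  )
  b <- bundle_from(tbls)
  tab <- prevalence_table(b, estimate_episodes(b))
  mgo <- tab[tab$product == "MgO", ]
  expect_equal(mgo$pct_total, 50)  # 1 of 2 mothers
  expect_equal(mgo$pct_t3, 100)    # only M1's pregnancy reaches day 196
})

test_that("sensitivity subsets follow their defining rules", {
  base <- tibble::tibble(
    group = rep(c("group1_mgo", "group2_krr"), c(400, 100)),
    krr = rep(c(FALSE, TRUE), c(400, 100)),
    mcm = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 360, 10, 90)),
    teratogen_rx_t1 = FALSE,
    mgo_t1 = rep(c(TRUE, FALSE), c(400, 100)),
    krr_t1 = rep(c(FALSE, TRUE), c(400, 100)),
    index_t1_supply_days = 40L,
    index_all_as_needed = FALSE,
    maternal_age_band = sample(c("25-29", "30-34"), 500, replace = TRUE),
    delivery_year_band = "2013-2015",
    preterm_birth = FALSE, epilepsy = FALSE, diabetes = FALSE,
    obesity = FALSE
  )
  # variant 3 with no dual-exposed mothers is a no-op
  s3 <- suppressWarnings(run_sensitivity(base, 3))
  expect_equal(s3$n, 500)
  expect_equal(s3$crude$or_point,
               suppressWarnings(run_sensitivity(base, 1))$crude$or_point)

  # variant 2 boundary: exactly 30 supply days is out, 31 is in
  b30 <- base
  b30$index_t1_supply_days <- rep(c(30L, 31L), 250)
  s2 <- suppressWarnings(run_sensitivity(b30, 2))
  expect_equal(s2$n, 250)

  # variant 1 removes teratogen-exposed mothers (non-events in both groups)
  b1 <- base
  b1$teratogen_rx_t1[c(101:125, 451:475)] <- TRUE
  expect_equal(suppressWarnings(run_sensitivity(b1, 1))$n, 450)

  # variant 4 removes PRN-only mothers (non-events in both groups)
  b4 <- base
  b4$index_all_as_needed[c(101:130, 451:480)] <- TRUE
  expect_equal(suppressWarnings(run_sensitivity(b4, 4))$n, 440)

  # an emptied subset is an explicit error naming the variant
  b0 <- base
  b0$index_t1_supply_days <- 10L
  expect_error(run_sensitivity(b0, 2), "sensitivity analysis 2")
})
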