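test_that("exposure date resolution prefers dispensing, then admission, then mid-month", {
  rx <- tibble::tibble(
    dispense_date = as.Date(c("2015-02-03", NA, NA)),
    admission_date = as.Date(c("2015-02-01", "2015-02-01", NA)),
    claim_year_month = "2015-02"
  )
  out <- resolve_exposure_date(rx)
  expect_equal(out$exposure_date,
               as.Date(c("2015-02-03", "2015-02-01", "2015-02-15")))
  expect_equal(out$date_provenance, c("dispense", "admission", "month_15th"))
})

test_that("intervals span the days of supply and respect the dictionary", {
  rx <- tibble::tibble(
    person_id = c("M1", "M1", "M1"),
    drug_code = c("A02AA02", "unknown_drug", "mashiningan"),
    dispense_date = as.Date("2015-02-03"),
    admission_date = as.Date(NA),
    claim_year_month = "2015-02",
    days_of_supply = c(14L, 14L, 7L),
    as_needed = FALSE
  )
  iv <- build_intervals(rx)
  expect_equal(nrow(iv), 2L)  # the unknown code produces no interval
  mgo <- iv[iv$drug_class == "MgO", ]
  expect_equal(mgo$start_date, as.Date("2015-02-03"))
  expect_equal(mgo$end_date, as.Date("2015-02-16"))
  expect_equal(iv$drug_class[iv$product == "mashiningan"], "KRR")

  rx$days_of_supply <- c(0L, 14L, 7L)
  expect_warning(iv <- build_intervals(rx), "non-positive")
  expect_false("MgO" %in% iv$drug_class)
})

test_that("provenance counts partition the classified prescriptions", {
  sim <- generate_bundle(sim_config(n_mothers = 800, seed = 31,
                                    p_missing_dispense_date = 0.5))
  dict <- drug_dictionary()
  classified <- sim$bundle$prescriptions[
    !is.na(kampopreg:::classify_drug(sim$bundle$prescriptions$drug_code,
                                     dict)), ]
  iv <- build_intervals(classified, dict)
  expect_equal(nrow(iv), nrow(classified))
  expect_equal(sum(table(iv$date_provenance)), nrow(classified))
  expect_setequal(unique(iv$date_provenance),
                  c("dispense", "admission", "month_15th"))
})

test_that("trimester flags agree with a day-by-day membership oracle", {
  ep <- build_episode(as.Date("2014-09-08"), as.Date("2015-06-01"))
  onset <- ep$onset_date
  mk <- function(start_off, len, class = "MgO") {
    tibble::tibble(
      person_id = "M1", drug_class = class, product = class,
      start_date = onset + start_off, end_date = onset + start_off + len - 1L,
      date_provenance = "dispense", as_needed = FALSE,
      days_of_supply = as.integer(len)
    )
  }
  oracle_flags <- function(iv) {
    days <- seq(iv$start_date, iv$end_date, by = "day")
    labels <- assign_trimester(days, ep)
    c(any(labels == "first"), any(labels == "second"), any(labels == "third"))
  }
  set.seed(77)
  for (i in 1:60) {
    iv <- mk(sample(-30:280, 1), sample(1:60, 1))
    flags <- flag_trimester_exposure(iv, ep)
    expect_equal(flags$MgO, oracle_flags(iv),
                 info = sprintf("interval %s..%s", iv$start_date, iv$end_date))
  }
  # interval starting before onset but reaching into it counts as exposed
  flags <- flag_trimester_exposure(mk(-10L, 14L), ep)
  expect_true(flags$MgO[1])
  # entirely pre-pregnancy: no flag anywhere
  flags <- flag_trimester_exposure(mk(-40L, 14L), ep)
  expect_false(any(unlist(flags)))
  # straddling gestational days 95-100 flags both first and second
  flags <- flag_trimester_exposure(mk(95L, 6L), ep)
  expect_equal(flags$MgO, c(TRUE, TRUE, FALSE))
})

test_that("the dispense-date rule only looks at the interval start", {
  ep <- build_episode(as.Date("2014-09-08"), as.Date("2015-06-01"))
  iv <- tibble::tibble(
    person_id = "M1", drug_class = "MgO", product = "A02AA02",
    start_date = ep$onset_date + 95L, end_date = ep$onset_date + 120L,
    date_provenance = "dispense", as_needed = FALSE, days_of_supply = 26L
  )
  overlap <- flag_trimester_exposure(iv, ep, rule = "overlap")
  dispense <- flag_trimester_exposure(iv, ep, rule = "dispense_date")
  expect_equal(overlap$MgO, c(TRUE, TRUE, FALSE))
  expect_equal(dispense$MgO, c(TRUE, FALSE, FALSE))
})

test_that("group assignment passes the exhaustive truth table", {
  grid <- expand.grid(mgo = c(FALSE, TRUE), krr = c(FALSE, TRUE),
                      sg = c(FALSE, TRUE))
  got <- assign_group(grid$mgo, grid$krr, grid$sg)
  want <- ifelse(grid$sg, "excluded_sg",
                 ifelse(grid$krr, "group2_krr",
                        ifelse(grid$mgo, "group1_mgo", "unexposed")))
  expect_equal(got, want)
  # spot checks of the rules that matter most
  expect_equal(assign_group(TRUE, FALSE, FALSE), "group1_mgo")
  expect_equal(assign_group(TRUE, TRUE, FALSE), "group2_krr")
  expect_equal(assign_group(TRUE, TRUE, TRUE), "excluded_sg")
})

test_that("adding a prescription never clears an exposure flag", {
  ep <- build_episode(as.Date("2014-09-08"), as.Date("2015-06-01"))
  base_iv <- tibble::tibble(
    person_id = "M1", drug_class = "KRR", product = "otsujito",
    start_date = ep$onset_date + 10L, end_date = ep$onset_date + 23L,
    date_provenance = "dispense", as_needed = FALSE, days_of_supply = 14L
  )
  set.seed(99)
  before <- unlist(flag_trimester_exposure(base_iv, ep))
  for (i in 1:20) {
    extra <- base_iv
    extra$drug_class <- sample(c("MgO", "KRR", "SG", "daikenchuto"), 1)
    extra$start_date <- ep$onset_date + sample(-20:280, 1)
    extra$end_date <- extra$start_date + sample(1:40, 1)
    after <- unlist(flag_trimester_exposure(rbind(base_iv, extra), ep))
    expect_true(all(after >= before))
  }
})

test_that("per-mother profiles aggregate flags, supply days and PRN status", {
  tbls <- tiny_tables()
  onset <- as.Date("2016-03-10") - 266
  tbls$prescriptions <- tibble::tibble(
    person_id = "M1",
    drug_code = c("A02AA02", "A02AA02", "daiokanzoto"),
    dispense_date = c(onset + 5, onset + 40, onset + 120),
    admission_date = as.Date(NA),
    claim_year_month = format(c(onset + 5, onset + 40, onset + 120), "%Y-%m"),
    days_of_supply = c(14L, 30L, 14L),
    as_needed = c(TRUE, FALSE, FALSE)
  )
  b <- bundle_from(tbls)
  prof <- exposure_profiles(b, estimate_episodes(b))
  expect_equal(prof$group, "group1_mgo")  # KRR only in trimester 2
  expect_true(prof$mgo_t1 && !prof$krr_t1 && prof$krr_t2)
  expect_equal(prof$mgo_t1_supply_days, 44L)
  expect_false(prof$mgo_t1_all_as_needed)  # one scheduled fill among the two
  # a mother with only PRN fills in trimester 1 is marked all-as-needed
  tbls$prescriptions$as_needed <- c(TRUE, TRUE, FALSE)
  b <- bundle_from(tbls)
  prof <- exposure_profiles(b, estimate_episodes(b))
  expect_true(prof$mgo_t1_all_as_needed)
})

test_that("every mother lands in exactly one comparison group", {
  sim <- generate_bundle(sim_config(n_mothers = 2000, seed = 33))
  ep <- estimate_episodes(sim$bundle)
  prof <- exposure_profiles(sim$bundle, ep)
  expect_equal(nrow(prof), sum(ep$datable))
  expect_true(all(prof$group %in% c("group1_mgo", "group2_krr",
                                    "excluded_sg", "unexposed")))
})
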