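test_that("onset is the diagnosis date minus the annotated gestational age", {
  expect_equal(
    estimate_onset(data.frame(diagnosis_date = as.Date("2015-06-01"),
                              ga_weeks = 38L, ga_days = 0L)),
    as.Date("2014-09-08")
  )
  # zero-GA identity
  d <- as.Date("2017-01-20")
  expect_equal(
    estimate_onset(data.frame(diagnosis_date = d, ga_weeks = 0L, ga_days = 0L)),
    d
  )
  # missing days component counts as zero
  expect_equal(
    estimate_onset(data.frame(diagnosis_date = d, ga_weeks = 10L)),
    d - 70
  )
})

test_that("the most recent gestational-age annotation wins", {
  dx <- data.frame(
    diagnosis_date = as.Date(c("2015-01-05", "2015-06-01")),
    ga_weeks = c(8L, 38L), ga_days = 0L
  )
  expect_equal(estimate_onset(dx), as.Date("2014-09-08"))
  # recency dominance: prepending an even earlier visit changes nothing
  dx2 <- rbind(data.frame(diagnosis_date = as.Date("2014-11-01"),
                          ga_weeks = 5L, ga_days = 3L), dx)
  expect_equal(estimate_onset(dx2), estimate_onset(dx))
})

test_that("same-day conflicting annotations use the smaller GA with a warning", {
  dx <- data.frame(
    diagnosis_date = as.Date("2015-06-01"),
    ga_weeks = c(36L, 38L), ga_days = 0L
  )
  expect_warning(o <- estimate_onset(dx), "conflicting")
  expect_equal(o, as.Date("2015-06-01") - 7 * 36)
})

test_that("empty or absurd annotation lists are rejected", {
  expect_error(
    estimate_onset(data.frame(diagnosis_date = as.Date(character()),
                              ga_weeks = integer())),
    class = "kampopreg_undatable"
  )
  expect_error(estimate_onset(data.frame(diagnosis_date = Sys.Date(),
                                         ga_weeks = 50L)))
})

test_that("delivery estimation follows the entry tier with mid-month fallback", {
  specific <- data.frame(entry_date = as.Date("2016-03-10"),
                         entry_kind = "specific_procedure")
  other <- data.frame(entry_date = as.Date("2016-03-02"),
                      entry_kind = "other_delivery_related")

  est <- estimate_delivery(specific, "2016-03")
  expect_equal(est$delivery_date, as.Date("2016-03-10"))
  expect_equal(est$method, "specific_entry")

  est <- estimate_delivery(rbind(specific, other), "2016-03")
  expect_equal(est$method, "specific_entry")  # specific outranks other

  est <- estimate_delivery(other, "2016-03")
  expect_equal(est$delivery_date, as.Date("2016-03-02"))
  expect_equal(est$method, "other_entry")

  est <- estimate_delivery(specific[0, ], "2016-03")
  expect_equal(est$delivery_date, as.Date("2016-03-15"))
  expect_equal(est$method, "month_midpoint")

  # an entry far from the birth month is implausible: warned and ignored
  stale <- data.frame(entry_date = as.Date("2015-11-10"),
                      entry_kind = "specific_procedure")
  expect_warning(est <- estimate_delivery(stale, "2016-03"), "ignored")
  expect_equal(est$method, "month_midpoint")
})

test_that("episode windows match the day-offset oracle", {
  onset <- as.Date("2014-09-08")
  delivery <- as.Date("2015-06-01")
  ep <- build_episode(onset, delivery)
  expect_equal(ep$gestation_days, 266L)
  expect_false(ep$capped_294)

  oracle <- brute_trimester_days(onset, delivery)
  for (w in list(c("t1_start", "t1_end", "first"),
                 c("t2_start", "t2_end", "second"),
                 c("t3_start", "t3_end", "third"))) {
    days <- oracle$date[oracle$label == w[3]]
    expect_equal(ep[[w[1]]], min(days))
    expect_equal(ep[[w[2]]], max(days))
  }
  expect_equal(ep$t1_end, as.Date("2014-12-14"))
  expect_equal(ep$t2_start, as.Date("2014-12-15"))
  expect_equal(ep$t2_end, as.Date("2015-03-22"))
  expect_equal(ep$t3_start, as.Date("2015-03-23"))
  expect_equal(ep$t3_end, delivery)
})

test_that("gestation above 294 days moves onset back to the cap", {
  delivery <- as.Date("2016-05-20")
  ep <- build_episode(delivery - 300, delivery)
  expect_true(ep$capped_294)
  expect_equal(ep$onset_date, delivery - 294)
  expect_equal(ep$gestation_days, 294L)
  # idempotence: re-building from the capped onset changes nothing
  ep2 <- build_episode(ep$onset_date, delivery)
  expect_false(ep2$capped_294)
  expect_equal(ep2$onset_date, ep$onset_date)
  expect_equal(ep2$gestation_days, ep$gestation_days)
})

test_that("short pregnancies have an empty third (and second) window", {
  delivery <- as.Date("2016-05-20")
  ep <- build_episode(delivery - 150, delivery)
  expect_true(is.na(ep$t3_start))
  expect_equal(ep$t2_end, delivery)
  ep <- build_episode(delivery - 90, delivery)
  expect_true(is.na(ep$t2_start))
  expect_equal(ep$t1_end, delivery)
  expect_error(build_episode(delivery + 1, delivery),
               class = "kampopreg_invalid_episode")
})

test_that("assign_trimester labels boundaries at days 97/98 and 195/196", {
  ep <- build_episode(as.Date("2014-09-08"), as.Date("2015-06-01"))
  on <- ep$onset_date
  expect_equal(assign_trimester(on, ep), "first")
  expect_equal(assign_trimester(on + 97, ep), "first")
  expect_equal(assign_trimester(on + 98, ep), "second")
  expect_equal(assign_trimester(on + 195, ep), "second")
  expect_equal(assign_trimester(on + 196, ep), "third")
  expect_equal(assign_trimester(ep$delivery_date, ep), "third")
  expect_equal(assign_trimester(on - 1, ep), "pre_pregnancy")
  expect_equal(assign_trimester(ep$delivery_date + 1, ep), "post_delivery")
})

test_that("random episodes partition every gestational day exactly once", {
  set.seed(424)
  for (i in 1:50) {
    delivery <- as.Date("2015-01-01") + sample(0:1500, 1)
    gest <- sample(119:294, 1)
    ep <- build_episode(delivery - gest, delivery)
    days <- seq(ep$onset_date, ep$delivery_date, by = "day")
    labels <- assign_trimester(days, ep)
    expect_true(all(labels %in% c("first", "second", "third")))
    oracle <- brute_trimester_days(ep$onset_date, ep$delivery_date)
    expect_equal(labels, oracle$label)
    # windows jointly cover the episode without overlap
    in_windows <- (days >= ep$t1_start & days <= ep$t1_end) +
      (!is.na(ep$t2_start) & days >= ep$t2_start & days <= ep$t2_end) +
      (!is.na(ep$t3_start) & days >= ep$t3_start & days <= ep$t3_end)
    expect_true(all(in_windows == 1))
  }
})

test_that("vectorised episode estimation matches the scalar path", {
  tbls <- tiny_tables()
  ep <- estimate_episodes(bundle_from(tbls))
  expect_equal(nrow(ep), 1L)
  expect_true(ep$datable)
  expect_equal(ep$delivery_method, "specific_entry")
  expect_equal(ep$gestation_days, 266L)
  one <- build_episode(
    estimate_onset(tbls$diagnoses),
    estimate_delivery(tbls$delivery_entries, "2016-03")
  )
  expect_equal(ep$onset_date, one$onset_date)
  expect_equal(ep$t2_start, one$t2_start)
  expect_equal(ep$t3_end, one$t3_end)

  # a mother with no GA annotation is flagged undatable
  tbls$diagnoses$ga_weeks <- NA_integer_
  ep <- estimate_episodes(bundle_from(tbls))
  expect_false(ep$datable)
})
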