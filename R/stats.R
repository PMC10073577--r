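# The study's statistics: crude odds ratio with Woolf interval, adjusted
# odds ratio from multivariate logistic regression with a Wald interval,
# Cochran-Armitage trend test across trimesters, and the group-comparison
# table (chi-square / t-tests).

#' Crude odds ratio with Woolf 95% confidence interval
#'
#' For the 2x2 table (`a` exposed with outcome, `b` exposed without, `c`
#' comparator with outcome, `d` comparator without): OR = ad / bc, with the
#' Woolf interval exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param a,b,c,d non-negative cell counts.
#' @param continuity add 0.5 to every cell when one is zero (off by default;
#'   with it off a zero cell is an error).
#' @return A list of class `or_result`: `or_point`, `ci_low`, `ci_high`,
#'   `method = "woolf"`, `n`, `n_events`.
#' @export
#' @examples
#' r <- crude_or(28, 422, 680, 9172)
#' round(c(r$or_point, r$ci_low, r$ci_high), 3)  # 0.895 0.606 1.322
crude_or <- function(a, b, c, d, continuity = FALSE) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    rlang::abort("all four cell counts must be non-negative")
  }
  if (any(cells == 0)) {
    if (!continuity) {
      rlang::abort(paste(
        "zero cell in the 2x2 table; rerun with continuity = TRUE to apply",
        "a 0.5 continuity correction"
      ), class = "kampopreg_zero_cell")
    }
    cells <- cells + 0.5
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(0.975)
  structure(list(
    or_point = unname(or),
    ci_low = unname(exp(log(or) - z * se)),
    ci_high = unname(exp(log(or) + z * se)),
    method = "woolf",
    n = unname(sum(c(a, b, c, d))),
    n_events = unname(a + c)
  ), class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f) [%s, n=%d, events=%d]\n",
              x$or_point, x$ci_low, x$ci_high, x$method, x$n, x$n_events))
  invisible(x)
}

#' Covariate-adjusted odds ratio by logistic regression
#'
#' Fits a maximum-likelihood logistic model of the outcome on the exposure
#' indicator plus covariate terms; the adjusted odds ratio is the
#' exponentiated exposure coefficient with a Wald 95% interval
#' exp(estimate +/- 1.96 SE). Factor terms (age and delivery-year bands) use
#' the youngest / earliest band as reference. Degenerate covariate columns
#' (constant in the analysis set) are dropped with a warning; complete
#' separation on the exposure is an error.
#'
#' @param rows analysis rows: a data frame with a logical outcome column, a
#'   logical exposure column and the covariate columns.
#' @param outcome,exposure column names (default `mcm` and `krr`).
#' @param covariates character vector of covariate column names; the default
#'   is the study's adjustment set.
#' @return A list of class `logistic_model_result`: `coefficients` (tibble of
#'   term, estimate, std_error), `adjusted_or` (an `or_result` with
#'   `method = "logistic_wald"`), `converged`, `n`, `n_events`, `dropped`.
#' @export
fit_logistic <- function(rows, outcome = "mcm", exposure = "krr",
                         covariates = c("maternal_age_band",
                                        "delivery_year_band", "preterm_birth",
                                        "epilepsy", "diabetes", "obesity",
                                        "teratogen_rx_t1")) {
  rows <- as.data.frame(rows)
  y <- rows[[outcome]]
  if (sum(y) < 1 || sum(!y) < 1) {
    rlang::abort("need at least one event and one non-event")
  }
  dropped <- character()
  keep <- character()
  for (cv in covariates) {
    v <- rows[[cv]]
    if (length(unique(v[!is.na(v)])) < 2) {
      dropped <- c(dropped, cv)
    } else {
      keep <- c(keep, cv)
    }
  }
  if (length(dropped)) {
    rlang::warn(sprintf("dropping degenerate covariate(s): %s",
                        paste(dropped, collapse = ", ")))
  }
  for (cv in intersect(keep, c("maternal_age_band", "delivery_year_band"))) {
    lev <- if (cv == "maternal_age_band") AGE_BANDS else YEAR_BANDS
    rows[[cv]] <- factor(rows[[cv]], levels = lev)
  }
  fm <- stats::reformulate(c(exposure, keep), response = outcome)
  fit <- suppressWarnings(glm(fm, family = binomial(), data = rows,
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 50)))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  exp_term <- paste0(exposure, "TRUE")
  if (!exp_term %in% names(est)) exp_term <- exposure
  if (abs(est[[exp_term]]) > 15 || se[[exp_term]] > 100) {
    rlang::abort("separation on the exposure term: estimate unbounded",
                 class = "kampopreg_separation")
  }
  z <- qnorm(0.975)
  adj <- structure(list(
    or_point = unname(exp(est[[exp_term]])),
    ci_low = unname(exp(est[[exp_term]] - z * se[[exp_term]])),
    ci_high = unname(exp(est[[exp_term]] + z * se[[exp_term]])),
    method = "logistic_wald",
    n = nrow(rows),
    n_events = sum(y)
  ), class = "or_result")
  structure(list(
    coefficients = tibble::tibble(term = names(est), estimate = unname(est),
                                  std_error = unname(se)),
    adjusted_or = adj,
    converged = fit$converged,
    n = nrow(rows),
    n_events = sum(y),
    dropped = dropped
  ), class = "logistic_model_result")
}

#' Cochran-Armitage trend test across ordered categories
#'
#' Tests for a linear trend in proportions across ordered categories
#' (trimesters, scored 1, 2, 3 by default). The statistic is
#' z = T / sqrt(Var T) with T = sum s_i (x_i - n_i pbar); z^2 equals the
#' 1-df chi-square trend statistic. Two-sided p-value from the normal
#' approximation.
#'
#' @param counts numeric vector of event counts per category.
#' @param denominators numeric vector of totals per category.
#' @param scores category scores (default `seq_along(counts)`).
#' @return A list of class `trend_test_result`: `z_statistic`, `p_value`,
#'   `direction` (`increasing`, `decreasing` or `none`).
#' @export
#' @examples
#' cochran_armitage(c(10, 20, 30), c(100, 100, 100))
cochran_armitage <- function(counts, denominators,
                             scores = seq_along(counts)) {
  stopifnot(length(counts) == length(denominators),
            length(scores) == length(counts))
  if (any(denominators <= 0)) {
    rlang::abort("all category denominators must be positive")
  }
  if (any(counts < 0 | counts > denominators)) {
    rlang::abort("counts must lie in [0, denominator] per category")
  }
  N <- sum(denominators)
  pbar <- sum(counts) / N
  t_stat <- sum(scores * (counts - denominators * pbar))
  var_t <- pbar * (1 - pbar) *
    (sum(scores^2 * denominators) - sum(scores * denominators)^2 / N)
  if (var_t <= 0) {
    z <- 0
  } else {
    z <- t_stat / sqrt(var_t)
  }
  p <- 2 * pnorm(-abs(z))
  structure(list(
    z_statistic = z,
    p_value = min(p, 1),
    direction = if (p < 0.05 && z > 0) "increasing"
                else if (p < 0.05 && z < 0) "decreasing" else "none"
  ), class = "trend_test_result")
}

#' Compare the two exposure groups covariate by covariate
#'
#' Categorical covariates get a Pearson chi-square test (no continuity
#' correction) across the group-by-level contingency table; continuous
#' covariates a two-sample t-test. A chi-square with any expected cell below
#' 1 is flagged unreliable.
#'
#' @param rows analysis rows with a `group` column.
#' @param categorical,continuous covariate column names.
#' @param groups the two group labels to compare.
#' @return A tibble: one row per covariate level with per-group counts and
#'   percentages, plus the test p-value on the covariate's first row.
#' @export
compare_groups <- function(rows,
                           categorical = c("maternal_age_band",
                                           "delivery_year_band", "infant_sex",
                                           "hypertension", "diabetes",
                                           "obesity", "epilepsy",
                                           "phenylketonuria",
                                           "teratogen_rx_t1", "preterm_birth",
                                           "caesarean"),
                           continuous = "maternal_age",
                           groups = c("group1_mgo", "group2_krr")) {
  rows <- rows[rows$group %in% groups, , drop = FALSE]
  n1 <- sum(rows$group == groups[1])
  n2 <- sum(rows$group == groups[2])
  if (n1 == 0 || n2 == 0) {
    rlang::abort("both comparison groups must be non-empty")
  }
  out <- list()
  for (cv in intersect(categorical, names(rows))) {
    v <- rows[[cv]]
    if (is.logical(v)) v <- factor(v, levels = c(FALSE, TRUE))
    tab <- table(v, rows$group)[, groups, drop = FALSE]
    p <- NA_real_
    unreliable <- FALSE
    if (nrow(tab) >= 2 && all(rowSums(tab) > 0)) {
      expect <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      unreliable <- any(expect < 1)
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    lv <- rownames(tab)
    show <- if (is.logical(rows[[cv]])) "TRUE" else lv
    for (i in seq_along(lv)) {
      if (!lv[i] %in% show) next
      out[[length(out) + 1L]] <- tibble::tibble(
        variable = cv, level = lv[i],
        group1_n = tab[i, 1], group1_pct = round(100 * tab[i, 1] / n1, 1),
        group2_n = tab[i, 2], group2_pct = round(100 * tab[i, 2] / n2, 1),
        p_value = if (i == which(lv %in% show)[1]) p else NA_real_,
        test = "chi_square", unreliable = unreliable
      )
    }
  }
  for (cv in intersect(continuous, names(rows))) {
    g1 <- rows[[cv]][rows$group == groups[1]]
    g2 <- rows[[cv]][rows$group == groups[2]]
    p <- tryCatch(t.test(g1, g2)$p.value, error = function(e) NA_real_)
    out[[length(out) + 1L]] <- tibble::tibble(
      variable = cv, level = "mean",
      group1_n = NA_integer_, group1_pct = round(mean(g1, na.rm = TRUE), 1),
      group2_n = NA_integer_, group2_pct = round(mean(g2, na.rm = TRUE), 1),
      p_value = p, test = "t_test", unreliable = FALSE
    )
  }
  dplyr::bind_rows(out)
}

#' Prescription-prevalence table by drug class, product and trimester
#'
#' Counts mothers with at least one exposure interval of each class (and each
#' rhubarb-Kampo product) overall and per trimester, with the
#' Cochran-Armitage trend p across trimesters per class. The third-trimester
#' denominator is restricted to pregnancies reaching gestational day 196.
#'
#' @param bundle a `claims_bundle`.
#' @param episodes tibble from [estimate_episodes()] (datable rows used).
#' @param dict a [drug_dictionary()].
#' @return A tibble, one row per class / product, with `n_total`, `pct_total`,
#'   per-trimester counts and percentages, and `trend_p`.
#' @export
prevalence_table <- function(bundle, episodes, dict = drug_dictionary()) {
  ep <- episodes[episodes$datable, , drop = FALSE]
  n_all <- nrow(ep)
  n_t3 <- sum(ep$gestation_days >= 196L)
  iv <- build_intervals(
    bundle$prescriptions[bundle$prescriptions$person_id %in% ep$mother_id, ],
    dict
  ) |>
    dplyr::inner_join(ep, by = c("person_id" = "mother_id")) |>
    dplyr::mutate(
      in_t1 = .data$start_date <= .data$t1_end & .data$end_date >= .data$t1_start,
      in_t2 = !is.na(.data$t2_start) & .data$start_date <= .data$t2_end &
        .data$end_date >= .data$t2_start,
      in_t3 = !is.na(.data$t3_start) & .data$start_date <= .data$t3_end &
        .data$end_date >= .data$t3_start,
      in_any = .data$start_date <= .data$delivery_date &
        .data$end_date >= .data$onset_date
    )

  count_rows <- function(sub, label) {
    n_tot <- dplyr::n_distinct(sub$person_id[sub$in_any])
    n1 <- dplyr::n_distinct(sub$person_id[sub$in_t1])
    n2 <- dplyr::n_distinct(sub$person_id[sub$in_t2])
    n3 <- dplyr::n_distinct(sub$person_id[sub$in_t3])
    trend <- if (n_all > 0 && n_t3 > 0) {
      cochran_armitage(c(n1, n2, n3), c(n_all, n_all, n_t3))$p_value
    } else NA_real_
    tibble::tibble(
      product = label,
      n_total = n_tot, pct_total = round(100 * n_tot / n_all, 2),
      n_t1 = n1, pct_t1 = round(100 * n1 / n_all, 2),
      n_t2 = n2, pct_t2 = round(100 * n2 / n_all, 2),
      n_t3 = n3, pct_t3 = round(100 * n3 / n_t3, 2),
      trend_p = trend
    )
  }

  rows <- list(count_rows(iv, "all_laxatives"))
  for (cl in c("MgO", "SG", "daikenchuto", "KRR")) {
    rows[[length(rows) + 1L]] <- count_rows(iv[iv$drug_class == cl, ], cl)
  }
  for (pr in dict$krr_products) {
    sub <- iv[iv$product == pr, , drop = FALSE]
    if (nrow(sub)) {
      r <- count_rows(sub, pr)
      r$trend_p <- NA_real_  # per-product trends are not reported
      rows[[length(rows) + 1L]] <- r
    }
  }
  dplyr::bind_rows(rows)
}
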