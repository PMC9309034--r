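toy_cohort <- function(end, outcome, stratum = "fawn") {
  tibble::tibble(
    animal_id = as.character(seq_along(end)), stratum = stratum,
    start_day = 0L, end_day = as.integer(end), outcome = outcome
  )
}

test_that("hand-computable cohorts reproduce the product-limit recursion", {
  # no censoring: one death among four -> empirical proportion 1/4
  fit <- aalen_johansen(toy_cohort(c(2, 77, 77, 77),
                                   c("coyote", rep("survived", 3))))
  ms <- mortality_summary(fit)
  expect_equal(ms$incidence[ms$cause == "coyote"], 0.25)
  expect_equal(attr(ms, "total"), 0.25)
  expect_equal(sum(ms$incidence[!ms$cause %in% c("coyote", "total")]), 0)

  # censored day 1, death day 2 among the remaining two -> CIF = 1/2
  fit2 <- aalen_johansen(toy_cohort(c(1, 2, 77),
                                    c("censored", "bear", "survived")))
  expect_equal(fit2$surv[fit2$days == 1], 1)
  expect_equal(unname(fit2$cif[fit2$days == 2, "bear"]), 0.5)

  # no events at all
  fit3 <- aalen_johansen(toy_cohort(c(77, 77), c("survived", "censored")))
  expect_true(all(fit3$surv == 1))
  expect_true(all(fit3$cif == 0))
})

test_that("survival plus summed incidence is exactly one at every day", {
  set.seed(41)
  for (rep in 1:5) {
    hist <- random_cohort(n = 30, horizon = 10)
    fit <- aalen_johansen(hist, horizon = 10)
    expect_equal(fit$surv + rowSums(fit$cif), rep(1, 11), tolerance = 1e-12)
  }
})

test_that("with one cause and no censoring the CIF is the empirical CDF", {
  set.seed(42)
  days <- sample.int(10, 25, replace = TRUE)
  hist <- toy_cohort(c(days, rep(12, 15)),
                     c(rep("wolf", 25), rep("survived", 15)))
  fit <- aalen_johansen(hist, horizon = 12)
  ecdf_days <- vapply(fit$days, function(t) mean(c(days, rep(Inf, 15)) <= t),
                      numeric(1))
  expect_equal(unname(fit$cif[, "wolf"]), ecdf_days, tolerance = 1e-12)
})

test_that("the estimator matches a brute-force recursion on random cohorts", {
  set.seed(43)
  for (rep in 1:50) {
    hist <- random_cohort(n = sample(3:12, 1), horizon = 10)
    fit <- aalen_johansen(hist, horizon = 10)
    oracle <- oracle_aj(hist, 10)
    expect_equal(fit$surv, oracle$surv, tolerance = 1e-12)
    expect_equal(fit$cif, oracle$cif, tolerance = 1e-12)
  }
})

test_that("the estimator agrees with the survival package's multistate fit", {
  skip_if_not_installed("survival")
  set.seed(44)
  for (rep in 1:5) {
    hist <- random_cohort(n = 40, horizon = 10)
    fit <- aalen_johansen(hist, horizon = 10)
    ev <- factor(ifelse(hist$outcome %in% mortality_causes(), hist$outcome,
                        "censor"),
                 levels = c("censor", mortality_causes()))
    sf <- survival::survfit(survival::Surv(hist$end_day, ev) ~ 1)
    sm <- summary(sf, times = 0:10, extend = TRUE)
    causes_present <- colnames(sm$pstate)[-1]
    for (k in setdiff(causes_present, "(s0)")) {
      expect_equal(unname(fit$cif[, k]),
                   unname(sm$pstate[, k]), tolerance = 1e-10)
    }
  }
})

test_that("constant-hazard cohorts recover the closed-form incidence", {
  h <- 0.005
  spec <- cohort_spec(20000, c(coyote = h), daily_censor_prob = 0,
                      horizon_days = 78)
  fit <- aalen_johansen(gen_mortality_cohort(spec, seed = 45))
  ms <- mortality_summary(fit)
  expect_equal(ms$incidence[ms$cause == "coyote"], 1 - (1 - h)^78,
               tolerance = 0.015)
})

test_that("staggered entry is honoured through start_day", {
  hist <- tibble::tibble(
    animal_id = c("a", "b", "c"), stratum = "fawn",
    start_day = c(0L, 0L, 3L), end_day = c(5L, 10L, 10L),
    outcome = c("wolf", "survived", "survived")
  )
  fit <- aalen_johansen(hist, horizon = 10)
  # late entrant is at risk on day 5, so 3 at risk -> CIF 1/3
  expect_equal(unname(fit$cif[fit$days == 5, "wolf"]), 1 / 3)
})

test_that("bad cohort tables and empty strata are rejected", {
  expect_error(aalen_johansen(toy_cohort(1, "lightning")),
               class = "dielrisk_parse_error")
  expect_error(aalen_johansen(toy_cohort(1, "survived"), stratum = "adult"),
               class = "dielrisk_empty_selection")
  bad <- toy_cohort(c(3, 2), c("survived", "survived"))
  bad$start_day <- c(5L, 0L)
  expect_error(aalen_johansen(bad), class = "dielrisk_parse_error")
})

test_that("tidy output is long format and glance summarizes terminals", {
  fit <- aalen_johansen(toy_cohort(c(2, 77), c("coyote", "survived")))
  td <- tidy(fit)
  expect_named(td, c("stratum", "day", "measure", "cause", "value"))
  expect_setequal(unique(td$measure), c("surv", "cif", "n_at_risk"))
  gl <- glance(fit)
  expect_equal(gl$cif_coyote, 0.5)
  expect_equal(gl$cif_total, 0.5)
  expect_s3_class(autoplot(fit), "ggplot")
})
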