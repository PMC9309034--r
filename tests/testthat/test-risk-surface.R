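test_that("risk weights are the identified-cause mortality shares", {
  w <- compute_risk_weights(c(bear = 0.04, coyote = 0.04,
                              unidentified_predation = 0.02))
  expect_equal(w$weight[w$source == "bear"], 0.5)
  expect_equal(w$weight[w$source == "coyote"], 0.5)
  expect_equal(attr(w, "excluded_mass"), 0.02)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)

  # single identified cause takes all the weight
  w1 <- compute_risk_weights(c(wolf = 0.07, disease = 0.01))
  expect_equal(w1$weight[w1$source == "wolf"], 1)

  # a cause with 40% of known-cause mortality gets weight 0.4
  w4 <- compute_risk_weights(c(coyote = 0.4, bear = 0.3, vehicle = 0.3))
  expect_equal(w4$weight[w4$source == "coyote"], 0.4)
  # vehicle deaths are attributed to the human risk source
  expect_equal(w4$weight[w4$source == "human"], 0.3)
})

test_that("weights are scale-free and reject the all-zero case", {
  inc <- c(bear = 0.01, bobcat = 0.02, coyote = 0.04, wolf = 0.01,
           vehicle = 0.03, unknown = 0.02)
  w1 <- compute_risk_weights(inc)
  w2 <- compute_risk_weights(inc * 7.3)
  expect_equal(w1$weight, w2$weight, tolerance = 1e-12)
  expect_error(compute_risk_weights(c(disease = 0.05, unknown = 0.02)),
               class = "dielrisk_undefined_weights")
})

test_that("unidentified predation can be redistributed across carnivores", {
  inc <- c(coyote = 0.04, bear = 0.02, unidentified_predation = 0.03,
           vehicle = 0.03)
  w <- compute_risk_weights(inc, redistribute_unidentified = TRUE)
  # carnivore shares keep their 2:1 ratio and absorb the unidentified mass
  expect_equal(w$weight[w$source == "coyote"] / w$weight[w$source == "bear"],
               2, tolerance = 1e-9)
  expect_equal(attr(w, "excluded_mass"), 0)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)
  expect_equal(w$weight[w$source == "human"], 0.03 / 0.12, tolerance = 1e-9)
})

test_that("the risk index is the exact weighted sum of source densities", {
  set.seed(51)
  dens <- list(
    coyote = fit_circular_kde(rvonmises(200, 0.5, 2), kappa = 3),
    wolf = fit_circular_kde(rvonmises(200, 5.5, 2), kappa = 3)
  )
  w <- compute_risk_weights(c(coyote = 0.05, wolf = 0.05))
  idx <- compute_risk_index(dens, w)
  expect_equal(idx$index, 0.5 * dens$coyote$density + 0.5 * dens$wolf$density)
  # decomposition: index equals the sum of the per-source components
  expect_equal(idx$index, idx$coyote + idx$wolf)
  # pointwise arithmetic at theta = 0 (first grid angle)
  expect_equal(idx$index[1],
               mean(c(dens$coyote$density[1], dens$wolf$density[1])))
  # weights sum to 1 and densities integrate to 1 -> so does the index
  expect_equal(dielrisk:::circ_trapz(idx$theta_rad, idx$index), 1,
               tolerance = 1e-6)

  # single-source index reproduces that density exactly
  w1 <- compute_risk_weights(c(coyote = 0.1))
  idx1 <- compute_risk_index(dens["coyote"], w1)
  expect_equal(idx1$index, dens$coyote$density)

  # uniform sources give a flat index at 1 / (2 pi)
  set.seed(52)
  u <- lapply(c(coyote = 1, wolf = 2), function(s) {
    fit_circular_kde(runif(5000, 0, 2 * pi), kappa = 0.01)
  })
  idxu <- compute_risk_index(u, w)
  expect_lt(max(abs(idxu$index - 1 / (2 * pi))), 0.01)

  expect_error(compute_risk_index(dens["coyote"], w),
               class = "dielrisk_config_error")
  expect_s3_class(autoplot(idx), "ggplot")
})

make_dated_events <- function(dates, spec, n_per_day, seed) {
  set.seed(seed)
  tibble::tibble(
    date = rep(dates, each = n_per_day),
    time_of_day_rad = rmixture(length(dates) * n_per_day, spec)
  )
}

test_that("moving windows include day +/- 5 and respect the sample floor", {
  spec <- activity_mixture(pi, 2)
  days <- seq(as.Date("2019-07-15"), as.Date("2019-08-15"), by = "day")
  deer <- make_dated_events(days, spec, 30, seed = 53)
  carn <- make_dated_events(days, spec, 30, seed = 54)

  # boundary membership: exactly 5 days away included, 6 days excluded
  centre <- as.Date("2019-07-25")
  win <- moving_window_overlap(deer, carn, start_date = centre,
                               end_date = centre, half_window_days = 5)
  expect_equal(win$n_deer, 30 * 11)
  win0 <- moving_window_overlap(
    dplyr::filter(deer, date != centre), carn,
    start_date = centre, end_date = centre, half_window_days = 0
  )
  expect_equal(win0$n_deer, 0)

  # a window with no carnivores is missing but keeps its counts
  empty_carn <- dplyr::filter(carn, date > as.Date("2019-08-10"))
  wmiss <- moving_window_overlap(deer, empty_carn,
                                 start_date = as.Date("2019-07-20"),
                                 end_date = as.Date("2019-07-20"))
  expect_true(is.na(wmiss$delta))
  expect_equal(wmiss$n_carnivore, 0)
  expect_gt(wmiss$n_deer, 0)
})

test_that("stationary equal distributions give a high, stable overlap series", {
  spec <- activity_mixture(c(1.5, 5.5), c(2, 2), c(0.5, 0.5))
  days <- seq(as.Date("2019-07-15"), as.Date("2019-09-10"), by = "day")
  deer <- make_dated_events(days, spec, 50, seed = 55)
  carn <- make_dated_events(days, spec, 50, seed = 56)
  series <- moving_window_overlap(deer, carn,
                                  start_date = as.Date("2019-07-20"),
                                  end_date = as.Date("2019-09-05"))
  expect_true(all(!is.na(series$delta)))
  expect_true(all(series$delta > 0.8))
  # series mean tracks the whole-period overlap
  whole <- estimate_delta4(deer$time_of_day_rad, carn$time_of_day_rad)
  expect_lt(abs(mean(series$delta) - whole), 0.05)
  expect_s3_class(autoplot(series), "ggplot")
})

test_that("relative overlap changes reproduce printed-style percentages", {
  expect_equal(round_percent(relative_overlap_change(0.61, 0.86, "reduction")),
               29)
  expect_equal(round_percent(relative_overlap_change(0.71, 0.51, "increase")),
               39)
  expect_equal(relative_overlap_change(0.5, 0.5, "reduction"), 0)
  expect_error(relative_overlap_change(0.5, 0, "reduction"),
               class = "dielrisk_invalid_parameter")
  # round-half-away-from-zero
  expect_equal(round_percent(c(23.5, -23.5, 36.4)), c(24, -24, 36))
})
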