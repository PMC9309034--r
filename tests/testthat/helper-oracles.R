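# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain besselI / adaptive quadrature for overlap
# truth, and a from-scratch daily recursion for cumulative incidence.

# true overlap integral min(f1, f2) of two von Mises mixtures by adaptive
# quadrature (stats::integrate), components given as plain vectors
oracle_true_overlap <- function(mu1, k1, p1, mu2, k2, p2) {
  dmix <- function(theta, mu, k, p) {
    out <- 0
    for (i in seq_along(mu)) {
      out <- out + p[i] * exp(k[i] * cos(theta - mu[i])) /
        (2 * pi * besselI(k[i], 0))
    }
    out
  }
  stats::integrate(
    function(t) pmin(dmix(t, mu1, k1, p1), dmix(t, mu2, k2, p2)),
    lower = 0, upper = 2 * pi, subdivisions = 400L, rel.tol = 1e-8
  )$value
}

# brute-force Aalen-Johansen on a daily grid: recounts the risk set from the
# subject table at every day, deaths before censorings within a day
oracle_aj <- function(hist, horizon) {
  causes <- mortality_causes()
  surv <- numeric(horizon + 1)
  cif <- matrix(0, horizon + 1, length(causes), dimnames = list(NULL, causes))
  surv[1] <- 1
  s <- 1
  acc <- stats::setNames(rep(0, length(causes)), causes)
  for (t in seq_len(horizon)) {
    at_risk <- hist$start_day < t & hist$end_day >= t
    n_t <- sum(at_risk)
    d <- vapply(causes, function(k) {
      sum(hist$outcome == k & hist$end_day == t & at_risk)
    }, numeric(1))
    if (n_t > 0 && sum(d) > 0) {
      acc <- acc + s * d / n_t
      s <- s * (1 - sum(d) / n_t)
    }
    surv[t + 1] <- s
    cif[t + 1, ] <- acc
  }
  list(surv = surv, cif = cif)
}

# random small cohort for the incidence oracle sweeps
random_cohort <- function(n, horizon = 10) {
  outcome <- sample(c("survived", "censored", "coyote", "bear", "vehicle",
                      "unidentified_predation"),
                    n, replace = TRUE,
                    prob = c(0.25, 0.2, 0.2, 0.15, 0.1, 0.1))
  end <- ifelse(outcome == "survived", horizon,
                sample.int(horizon, n, replace = TRUE))
  tibble::tibble(
    animal_id = as.character(seq_len(n)), stratum = "fawn",
    start_day = 0L, end_day = as.integer(end), outcome = outcome
  )
}

# image-burst builder for detection tests
make_images <- function(times, site = "A", species = "deer",
                        f = 0L, m = 0L, y = 0L,
                        origin = "2019-07-20 00:00:00") {
  n <- length(times)
  tibble::tibble(
    site_id = rep_len(site, n), species = rep_len(species, n),
    datetime = as.POSIXct(origin, tz = "UTC") + times * 60,
    n_adult_female = rep_len(as.integer(f), n),
    n_adult_male = rep_len(as.integer(m), n),
    n_fawn = rep_len(as.integer(y), n)
  )
}
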