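#' Wrap angles onto the circle
#'
#' Maps arbitrary angles (radians) into `[0, 2*pi)`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector in `[0, 2*pi)`.
#' @export
wrap_circular <- function(theta) {
  out <- theta %% (2 * pi)
  out[out == 2 * pi] <- 0
  out
}

#' Clock time to circular time of day
#'
#' Converts timestamps to radians on the diel circle, with midnight at 0 and
#' noon at `pi`: `2*pi * seconds_since_midnight / 86400`. Local standard clock
#' time is used as-is (no solar-time transformation).
#'
#' @param x A `POSIXct` vector, or seconds since local midnight.
#' @return Numeric vector of radians in `[0, 2*pi)`.
#' @export
time_to_radians <- function(x) {
  if (inherits(x, "POSIXt")) {
    secs <- lubridate::hour(x) * 3600 + lubridate::minute(x) * 60 +
      lubridate::second(x)
  } else {
    secs <- as.numeric(x)
  }
  wrap_circular(2 * pi * secs / 86400)
}

# round half away from zero to `digits` decimals (Results-style percentages)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# trapezoidal integral of a periodic density sampled on an even grid over
# [0, 2pi): closes the circle by appending the first point at 2pi
circ_trapz <- function(grid, values) {
  g <- c(grid, grid[1] + 2 * pi)
  v <- c(values, values[1])
  sum(diff(g) * (v[-1] + v[-length(v)]) / 2)
}

stop_empty_selection <- function(what) {
  abort(paste0("No records left after filtering: ", what),
        class = "dielrisk_empty_selection")
}

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    abort(sprintf("`%s` must be a single finite number %s %s.",
                  name, if (strict) ">" else ">=", format(min)),
          class = "dielrisk_invalid_parameter")
  }
  invisible(x)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
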