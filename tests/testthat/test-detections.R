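test_that("bursts collapse into independent detections by site, species and gap", {
  # three images within chained 15-min gaps -> one detection at first image
  one <- collapse_detections(make_images(c(0, 5, 10), f = 1))
  expect_equal(nrow(one), 1)
  expect_equal(one$timestamp, as.POSIXct("2019-07-20 00:00:00", tz = "UTC"))
  expect_equal(one$n_images, 3L)

  # gap > 15 min splits
  two <- collapse_detections(make_images(c(0, 20), f = 1))
  expect_equal(nrow(two), 2)

  # a gap of exactly 15 minutes stays within the detection
  exact <- collapse_detections(make_images(c(0, 15), f = 1))
  expect_equal(nrow(exact), 1)

  # chaining: consecutive gaps <= 15 keep one detection spanning > 15 min
  chain <- collapse_detections(make_images(c(0, 10, 20, 30), f = 1))
  expect_equal(nrow(chain), 1)

  # sites and species are independent streams
  sites <- collapse_detections(dplyr::bind_rows(
    make_images(0, site = "A", f = 1), make_images(5, site = "B", f = 1)
  ))
  expect_equal(nrow(sites), 2)
  species <- collapse_detections(dplyr::bind_rows(
    make_images(0, species = "coyote"), make_images(5, species = "wolf")
  ))
  expect_equal(nrow(species), 2)
})

test_that("deer class counts combine as per-image maxima and fawns dominate", {
  # fawn only on the middle image still makes the detection a nursery group
  imgs <- make_images(c(0, 5, 10), f = 1)
  imgs$n_fawn <- c(0L, 2L, 0L)
  ev <- collapse_detections(imgs)
  expect_equal(ev$group, "nursery_group")
  expect_equal(ev$n_fawn, 2L)
  expect_equal(ev$n_adult_female, 1L)
})

test_that("deer demographic classification follows fawn > female > male priority", {
  cases <- tibble::tribble(
    ~f, ~m, ~y, ~expected,
    1L, 0L, 2L, "nursery_group",
    1L, 0L, 0L, "adult_female",
    0L, 1L, 1L, "nursery_group",
    0L, 1L, 0L, "adult_male",
    0L, 0L, 0L, NA_character_
  )
  expect_equal(classify_deer_group(cases$f, cases$m, cases$y), cases$expected)
})

test_that("clock times map to diel radians", {
  expect_equal(time_to_radians(6 * 3600), pi / 2)
  expect_equal(time_to_radians(0), 0)
  expect_equal(time_to_radians(12 * 3600), pi)
  expect_equal(time_to_radians(18 * 3600), 3 * pi / 2)
  ev <- collapse_detections(make_images(6 * 60, f = 1))
  expect_equal(ev$time_of_day_rad, pi / 2)
})

test_that("collapsing is idempotent, monotone in the gap, and partitions images", {
  set.seed(11)
  imgs <- dplyr::bind_rows(lapply(1:4, function(s) {
    make_images(sort(runif(60, 0, 600)), site = LETTERS[s],
                species = sample(c("deer", "coyote"), 1), f = 1)
  }))
  ev <- collapse_detections(imgs, gap_minutes = 15)

  # partition: every image in exactly one detection
  expect_equal(sum(ev$n_images), nrow(imgs))

  # idempotence: re-collapsing one-image-per-event output is a no-op
  as_images <- ev |>
    dplyr::transmute(site_id = .data$site_id, species = .data$species,
                     datetime = .data$timestamp,
                     n_adult_female = .data$n_adult_female,
                     n_adult_male = .data$n_adult_male, n_fawn = .data$n_fawn)
  reev <- collapse_detections(as_images, gap_minutes = 15)
  expect_equal(reev$timestamp, ev$timestamp)
  expect_equal(reev$group, ev$group)

  # monotonicity: detection count non-increasing in the gap
  counts <- vapply(c(0, 2, 5, 15, 60, 600), function(g) {
    nrow(collapse_detections(imgs, gap_minutes = g))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detections can span midnight within one stream", {
  imgs <- make_images(c(-5, 5), f = 1) # 23:55 and 00:05
  ev <- collapse_detections(imgs)
  expect_equal(nrow(ev), 1)
  # detection keeps the first image's (pre-midnight) clock time
  expect_equal(ev$time_of_day_rad, time_to_radians((24 * 60 - 5) * 60))
})

test_that("malformed image tables are rejected with record identification", {
  bad_time <- make_images(c(0, 5), f = 1)
  bad_time$datetime <- c("2019-07-20 00:00:00", "not-a-time")
  expect_error(collapse_detections(bad_time), class = "dielrisk_parse_error")
  expect_error(collapse_detections(bad_time), "row 2")

  bad_sp <- make_images(0)
  bad_sp$species <- "moose"
  expect_error(collapse_detections(bad_sp), class = "dielrisk_parse_error")

  bad_count <- make_images(0)
  bad_count$n_fawn <- -1L
  expect_error(collapse_detections(bad_count), class = "dielrisk_parse_error")

  # empty input is an empty table, not an error
  expect_equal(nrow(collapse_detections(make_images(numeric(0)))), 0)
})

test_that("circular time extraction filters by species and group", {
  ev <- collapse_detections(dplyr::bind_rows(
    make_images(c(0, 30), f = 1, y = 1),
    make_images(c(60, 90), species = "coyote"),
    make_images(120, species = "human")
  ))
  expect_length(to_circular_times(ev, species = "coyote"), 2)
  expect_length(to_circular_times(ev, species = "deer",
                                  group = "nursery_group"), 2)
  expect_length(to_circular_times(ev, species = carnivore_species()), 2)
  expect_error(to_circular_times(ev, species = "wolf"),
               class = "dielrisk_empty_selection")
})
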