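# Correlated-random-walk simulator: degenerate limits, confinement,
# distributional checks against numerical oracles, determinism.

big_region <- function() region(c(-5e5, -5e5), 1e6, 1e6, 0)

test_that("zero-noise walk is a straight line with exact step lengths", {
  p <- movement_params("deg", mean_step_m = 10, sd_step_m = 0,
                       sd_turn_deg = 0, steps_per_month = 100,
                       home_range_km2 = 1e6)  # disc never binds
  tr <- simulate_trajectory(p, c(0, 0), survey_start(), 1, rng_seed = 5)
  pos <- rbind(c(0, 0), tr$positions)
  steps <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  expect_equal(nrow(tr$positions), 100)
  expect_equal(steps, rep(10, 100), tolerance = 1e-12)
  # collinear: total displacement equals the summed step length
  expect_equal(sqrt(sum(tr$positions[100, ]^2)), 1000, tolerance = 1e-9)
})

test_that("trajectories are reproducible and individuals are sub-seeded", {
  p <- quick_params()
  reg <- big_region()
  a <- simulate_trajectory(p, c(10, 20), survey_start(), 2, rng_seed = 99)
  b <- simulate_trajectory(p, c(10, 20), survey_start(), 2, rng_seed = 99)
  expect_identical(a$positions, b$positions)
  pa <- simulate_population(5, p, reg, survey_start(), 1, rng_seed = 7)
  pb <- simulate_population(5, p, reg, survey_start(), 1, rng_seed = 7)
  expect_identical(lapply(pa, `[[`, "positions"),
                   lapply(pb, `[[`, "positions"))
  # an individual re-simulated alone from its sub-seed matches the population
  centers <- draw_home_centers(5, reg, sub_seed(7, 0L))
  solo <- simulate_trajectory(p, centers[3, ], survey_start(), 1,
                              rng_seed = sub_seed(7, 3L), region = reg)
  expect_identical(solo$positions, pa[[3]]$positions)
})

test_that("empty and invalid population sizes are handled", {
  p <- quick_params()
  expect_length(simulate_population(0, p, big_region(), survey_start(), 1, 1),
                0)
  expect_equal(nrow(draw_home_centers(0, big_region(), 1)), 0)
  expect_error(draw_home_centers(-1, big_region(), 1), "non-negative")
  expect_error(simulate_population(-2, p, big_region(), survey_start(), 1, 1),
               "non-negative")
  expect_error(simulate_trajectory(p, c(0, 0), survey_start(), 0, 1), ">= 1")
  expect_error(movement_params("x", NaN, 1, 1, 100, 1), "finite")
})

test_that("home centres are uniform over the region", {
  side <- sqrt(10 * 1e6)  # 10 km2 square
  reg <- region(c(0, 0), side, side, 0)
  centers <- draw_home_centers(1000, reg, rng_seed = 42)
  expect_identical(centers, draw_home_centers(1000, reg, rng_seed = 42))
  expect_lt(abs(mean(centers[, 1]) - side / 2), 0.05 * side)
  expect_lt(abs(mean(centers[, 2]) - side / 2), 0.05 * side)
  expect_true(all(centers >= 0 & centers <= side))
})

test_that("all positions stay inside the home-range disc", {
  p <- movement_params("conf", 13.18, 17.31, 26.31,
                       steps_per_month = 10000, home_range_km2 = 2)
  r <- sqrt(2e6 / pi)  # ~798 m
  tr <- simulate_trajectory(p, c(500, -200), survey_start(), 1, rng_seed = 3)
  d <- sqrt((tr$positions[, 1] - 500)^2 + (tr$positions[, 2] + 200)^2)
  expect_equal(nrow(tr$positions), 10000)
  expect_true(all(d <= r + 1e-9))
})

test_that("a tiny home range pins the walk to its centre", {
  p <- movement_params("pin", 13.18, 17.31, 26.31, 500,
                       home_range_km2 = 1e-6)
  tr <- simulate_trajectory(p, c(7, 7), survey_start(), 1, rng_seed = 1)
  d <- sqrt((tr$positions[, 1] - 7)^2 + (tr$positions[, 2] - 7)^2)
  expect_true(all(d <= sqrt(1 / pi) + 1e-9))
})

test_that("realized step lengths match the truncated-normal mean", {
  p <- fox_params()
  tr <- simulate_trajectory(movement_params(p$species_label, p$mean_step_m,
                                            p$sd_step_m, p$sd_turn_deg,
                                            5000, 1e6),
                            c(0, 0), survey_start(), 1, rng_seed = 11)
  pos <- rbind(c(0, 0), tr$positions)
  steps <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2)
  mu <- truncnorm_mean(13.18, 17.31)
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - mu), 3 * se)
})

test_that("turning-angle SD matches the configured deflection", {
  p <- movement_params("turn", 13.18, 17.31, 26.31, 10000, 1e6)
  tr <- simulate_trajectory(p, c(0, 0), survey_start(), 1, rng_seed = 8)
  pos <- rbind(c(0, 0), tr$positions)
  head_deg <- atan2(diff(pos[, 2]), diff(pos[, 1])) * 180 / pi
  turn <- diff(head_deg)
  turn <- ((turn + 180) %% 360) - 180  # wrap to (-180, 180]
  se <- 26.31 / sqrt(2 * (length(turn) - 1))
  expect_lt(abs(sd(turn) - 26.31), 3 * se)
})

test_that("step counts and timestamps follow the calendar", {
  p <- quick_params(steps = 100)
  tr <- simulate_trajectory(p, c(0, 0), survey_start(), 13, rng_seed = 2)
  expect_equal(nrow(tr$positions), 13 * 100)
  expect_length(tr$timestamps, 13 * 100)
  expect_true(all(diff(as.numeric(tr$timestamps)) > 0))
  expect_true(all(tr$timestamps >= as.POSIXct("2021-03-01", tz = "UTC")))
  expect_true(all(tr$timestamps < as.POSIXct("2022-04-01", tz = "UTC")))
  # even spacing within one month
  tt <- step_times(survey_start(), 1, 100)
  expect_equal(length(unique(round(diff(as.numeric(tt)), 6))), 1)
})

test_that("a 13-month fox population has 65,000 positions per individual", {
  pop <- simulate_population(2, fox_params(), big_region(), survey_start(),
                             13, rng_seed = 4)
  expect_true(all(vapply(pop, function(tr) nrow(tr$positions), 0L) == 65000))
})

test_that("trajectory export round-trips through CSV", {
  p <- quick_params(steps = 50)
  pop <- simulate_population(2, p, big_region(), survey_start(), 1, 9)
  path <- tempfile(fileext = ".csv")
  df <- trajectories_to_df(pop, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 100)
  expect_equal(back$x_m, df$x_m, tolerance = 1e-12)
  unlink(path)
})
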