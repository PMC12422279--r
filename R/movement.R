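# Correlated random walk simulation of home-range-confined movement.

#' Step timestamps for a simulated survey
#'
#' Steps are spread evenly within each calendar month: month `m` of the
#' survey contributes `steps_per_month` steps at times
#' `month_start + (k - 0.5) / steps_per_month * month_length`. Diel activity
#' is not modelled. Times are naive local clock times represented in UTC.
#'
#' @param start survey start `Date` (first day of the first month).
#' @param months number of calendar months simulated.
#' @param steps_per_month steps walked per month.
#' @return `POSIXct` vector of length `months * steps_per_month`.
#' @export
step_times <- function(start, months, steps_per_month) {
  start <- as.Date(start)
  bounds <- as.numeric(as.POSIXct(seq(start, by = "month",
                                      length.out = months + 1), tz = "UTC"))
  k <- (seq_len(steps_per_month) - 0.5) / steps_per_month
  t_sec <- as.vector(vapply(seq_len(months), function(m) {
    bounds[m] + k * (bounds[m + 1] - bounds[m])
  }, numeric(steps_per_month)))
  as.POSIXct(t_sec, origin = "1970-01-01", tz = "UTC")
}

#' Draw home-range centres uniformly over a region
#'
#' Centres are uniform over the buffered rectangle, so individuals whose home
#' ranges only partially overlap the camera grid are included in proportion
#' to the area they could occupy.
#'
#' @param n number of individuals (>= 0).
#' @param region a [region()] object.
#' @param rng_seed integer seed; a fixed seed reproduces the draw exactly.
#' @return `n x 2` numeric matrix of (x, y) coordinates in metres.
#' @export
draw_home_centers <- function(n, region, rng_seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("'n' must be a single non-negative number", call. = FALSE)
  n <- as.integer(n)
  b <- region_bounds(region)
  if (n == 0L)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  set.seed(rng_seed)
  cbind(x = runif(n, b["xmin"], b["xmax"]),
        y = runif(n, b["ymin"], b["ymax"]))
}

#' Simulate one home-range-confined correlated random walk
#'
#' Starting at the home centre with a uniform initial heading, each step turns
#' by a centred normal deviate with standard deviation `sd_turn_deg` and
#' travels a step length drawn from a normal distribution truncated at zero.
#' A proposed step leaving the home-range disc (or the region, if supplied)
#' is rejected and redrawn — fresh turn and length — up to 100 times, after
#' which the heading is pointed at the home centre and the step capped at the
#' distance to it. Step times come from [step_times()].
#'
#' @param params a [movement_params()] object.
#' @param home_center numeric length-2 (x, y) home-range centre, metres.
#' @param start survey start `Date`.
#' @param months number of calendar months to walk (>= 1).
#' @param rng_seed integer seed.
#' @param region optional [region()]; when given, positions are additionally
#'   confined to its buffered rectangle.
#' @param individual_id identifier stored in the trajectory.
#' @return An object of class `trajectory`: list with `individual_id`,
#'   `species`, `home_center`, `positions` (an `n x 2` matrix of step
#'   endpoints, one row per step) and `timestamps` (`POSIXct`, same length).
#' @examples
#' fox <- movement_params("fox", 13.18, 17.31, 26.31, 5000, 5.31)
#' tr <- simulate_trajectory(fox, c(0, 0), as.Date("2021-03-01"), 1, 42)
#' nrow(tr$positions)  # 5000
#' @export
simulate_trajectory <- function(params, home_center, start, months, rng_seed,
                                region = NULL, individual_id = 1L) {
  stopifnot(inherits(params, "movement_params"))
  if (!is.numeric(months) || length(months) != 1L || months < 1)
    stop("'months' must be >= 1", call. = FALSE)
  months <- as.integer(months)
  if (length(home_center) != 2L || any(!is.finite(home_center)))
    stop("'home_center' must be two finite coordinates", call. = FALSE)
  b <- if (is.null(region)) c(xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf)
       else region_bounds(region)
  n_steps <- months * params$steps_per_month
  r <- home_range_radius(params)
  set.seed(rng_seed)
  pos <- crw_walk_cpp(n_steps, params$mean_step_m, params$sd_step_m,
                      params$sd_turn_deg * pi / 180,
                      home_center[1], home_center[2], r * r,
                      b["xmin"], b["xmax"], b["ymin"], b["ymax"])
  colnames(pos) <- c("x", "y")
  structure(
    list(individual_id = individual_id, species = params$species_label,
         home_center = as.numeric(home_center), positions = pos,
         timestamps = step_times(start, months, params$steps_per_month)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of individual %s (%s): %d steps, %s to %s\n",
              x$individual_id, x$species, nrow(x$positions),
              format(x$timestamps[1]), format(x$timestamps[length(x$timestamps)])))
  invisible(x)
}

#' Simulate a population of independent individuals
#'
#' Home centres are drawn uniformly over the buffered region; each individual
#' then walks an independent confined correlated random walk. Per-individual
#' seeds are derived from `rng_seed` with [sub_seed()], so the population is
#' reproducible and any single individual can be re-simulated alone.
#'
#' @param n number of individuals (>= 0).
#' @inheritParams simulate_trajectory
#' @param region a [region()] confining home centres and movement.
#' @return List of `n` `trajectory` objects.
#' @export
simulate_population <- function(n, params, region, start, months, rng_seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0)
    stop("'n' must be a single non-negative number", call. = FALSE)
  n <- as.integer(n)
  centers <- draw_home_centers(n, region, sub_seed(rng_seed, 0L))
  lapply(seq_len(n), function(i) {
    simulate_trajectory(params, centers[i, ], start, months,
                        rng_seed = sub_seed(rng_seed, i),
                        region = region, individual_id = i)
  })
}

#' Export trajectories to a data frame or CSV
#'
#' @param trajectories list of `trajectory` objects.
#' @param path optional CSV path; when given, the table is also written.
#' @return Data frame with `individual_id`, `step_index`, `x_m`, `y_m`,
#'   `timestamp` (ISO-8601).
#' @export
trajectories_to_df <- function(trajectories, path = NULL) {
  out <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(individual_id = tr$individual_id,
               step_index = seq_len(nrow(tr$positions)),
               x_m = tr$positions[, 1], y_m = tr$positions[, 2],
               timestamp = format(tr$timestamps, "%Y-%m-%dT%H:%M:%S"))
  }))
  if (is.null(out))
    out <- data.frame(individual_id = integer(), step_index = integer(),
                      x_m = numeric(), y_m = numeric(),
                      timestamp = character())
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
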