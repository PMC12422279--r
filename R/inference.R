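# Simulation-matching density inference: abundance-labelled simulations ->
# random-forest regression of abundance on per-camera event counts ->
# density with a percentile CI from the per-tree predictions.

#' Simulation configuration for the training set
#'
#' @param abundance_grid candidate numbers of individuals; default 1..20,
#'   a gradient of population densities.
#' @param replicates_per_abundance simulated surveys per abundance level.
#' @param months survey length in calendar months.
#' @param start survey start `Date`.
#' @param base_seed integer seed governing all simulation randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(abundance_grid = 1:20, replicates_per_abundance = 100,
                       months = 13, start = as.Date("2021-03-01"),
                       base_seed = 1L) {
  if (!length(abundance_grid) || any(abundance_grid < 0) ||
      is.unsorted(abundance_grid, strictly = TRUE))
    stop("abundance_grid must be non-empty, strictly increasing, all >= 0",
         call. = FALSE)
  if (replicates_per_abundance < 1)
    stop("replicates_per_abundance must be >= 1", call. = FALSE)
  structure(list(abundance_grid = as.integer(abundance_grid),
                 replicates_per_abundance = as.integer(replicates_per_abundance),
                 months = as.integer(months), start = as.Date(start),
                 base_seed = as.integer(base_seed)),
            class = "sim_config")
}

#' Random-forest configuration
#'
#' Defaults follow the survey-analysis convention for this estimator: 5,000
#' trees (raised from the package default 500 for stable per-tree prediction
#' quantiles) and `mtry = floor(sqrt(p))` where `p` is the number of cameras.
#'
#' @param n_trees number of trees (>= 1).
#' @param vars_per_split variables tried at each split; `NULL` means
#'   `floor(sqrt(#cameras))`, resolved at fit time.
#' @param seed integer seed for forest fitting.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 5000, vars_per_split = NULL, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (!is.null(vars_per_split) && vars_per_split < 1)
    stop("vars_per_split must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 vars_per_split = vars_per_split, seed = as.integer(seed)),
            class = "rf_config")
}

#' Effective sampling area of a camera grid
#'
#' The area over which a simulated abundance converts to a density: the
#' camera-grid bounding box buffered on every side by the home-range disc
#' radius. The same rectangle defines the simulation region, so abundance
#' and density are self-consistent by construction.
#'
#' @param grid a `camera_grid`.
#' @param params a [movement_params()] (supplies the home-range radius).
#' @return Area in km2.
#' @examples
#' fox <- movement_params("fox", 13.18, 17.31, 26.31, 5000, 2)
#' g <- make_camera_grid()
#' effective_area(g, fox)  # ~14.53 km2 for a 4 x 1 km grid, 798 m buffer
#' @export
effective_area <- function(grid, params) {
  region_area_km2(region_from_grid(grid, params))
}

#' Simulation region induced by a camera grid and a species' home range
#'
#' @inheritParams effective_area
#' @return A [region()]: the grid bounding box buffered by the home-range
#'   radius.
#' @export
region_from_grid <- function(grid, params) {
  if (!inherits(grid, "camera_grid")) grid <- as_camera_grid(grid)
  w <- diff(range(grid$x_m))
  h <- diff(range(grid$y_m))
  region(origin = c(min(grid$x_m), min(grid$y_m)),
         width_m = max(w, 1e-9), height_m = max(h, 1e-9),
         buffer_m = home_range_radius(params))
}

#' Build the abundance-labelled training set
#'
#' For each abundance `n` in the grid and each replicate: simulate a
#' population of `n` individuals, scan trajectories against the cameras,
#' reduce the simulated records with the same independence filter applied to
#' observed data, and count events per camera. One feature row per simulated
#' survey, labelled with its abundance. Cameras with unrecorded azimuths are
#' re-randomized each replicate. Deterministic for a fixed `base_seed`.
#'
#' @param params a [movement_params()] object.
#' @param grid a `camera_grid`.
#' @param sim a [sim_config()].
#' @param window_min independence window (minutes) applied to simulated
#'   records; set `Inf`-like behaviour with `filter_sim = FALSE`.
#' @param filter_sim apply the independence filter to simulated records
#'   (default `TRUE`, keeping simulated and observed counts commensurate).
#' @return A `training_set`: list with `features` (matrix, rows = simulated
#'   surveys, columns = cameras), `labels` (abundance per row), `camera_ids`,
#'   and the configs used.
#' @export
build_training <- function(params, grid, sim, window_min = 60,
                           filter_sim = TRUE) {
  if (!inherits(grid, "camera_grid")) grid <- as_camera_grid(grid)
  reg <- region_from_grid(grid, params)
  n_rep <- sim$replicates_per_abundance
  rows <- length(sim$abundance_grid) * n_rep
  features <- matrix(0L, nrow = rows, ncol = nrow(grid),
                     dimnames = list(NULL, grid$camera_id))
  labels <- integer(rows)
  row <- 0L
  run <- 0L
  for (n in sim$abundance_grid) {
    for (rep in seq_len(n_rep)) {
      run <- run + 1L
      g <- randomize_facings(grid, sub_seed(sim$base_seed, 2L * run))
      pop <- simulate_population(n, params, reg, sim$start, sim$months,
                                 rng_seed = sub_seed(sim$base_seed,
                                                     2L * run + 1L))
      recs <- detect(pop, g)
      if (filter_sim) recs <- filter_independent(recs, window_min)
      et <- count_events(recs, g, params$species_label, window_min)
      row <- row + 1L
      features[row, ] <- et$counts
      labels[row] <- n
    }
  }
  structure(list(features = features, labels = labels,
                 camera_ids = grid$camera_id, params = params, sim = sim,
                 window_min = window_min, filter_sim = filter_sim),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(paste0("Training set: %d simulated surveys x %d cameras, ",
                     "abundances %d..%d (%d replicates each)\n"),
              nrow(x$features), ncol(x$features), min(x$labels),
              max(x$labels), x$sim$replicates_per_abundance))
  invisible(x)
}

#' Fit the random-forest abundance matcher
#'
#' Regression forest of abundance label on the per-camera event counts.
#' Kept separate from [predict_density()] so one fitted forest can score
#' many observed surveys (as the parameter-recovery experiment does).
#'
#' @param training a `training_set` from [build_training()].
#' @param rf an [rf_config()].
#' @return A `density_forest` wrapping the `randomForest` fit.
#' @export
fit_forest <- function(training, rf = rf_config()) {
  mtry <- rf$vars_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(training$features))))
  set.seed(rf$seed)
  fit <- withCallingHandlers(
    randomForest::randomForest(x = training$features,
                               y = as.numeric(training$labels),
                               ntree = rf$n_trees, mtry = mtry),
    warning = function(w) {
      # a coarse abundance grid legitimately yields few unique labels
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, camera_ids = training$camera_ids,
                 rf = rf, mtry = mtry), class = "density_forest")
}

#' Predict density for one observed event table
#'
#' The forest predicts abundance for the observed per-camera count vector;
#' the point estimate is the forest mean and the 95% CI the 2.5th/97.5th
#' percentiles of the per-tree predictions, all divided by the effective
#' sampling area.
#'
#' @param forest a `density_forest` from [fit_forest()].
#' @param observed an `event_table` (camera ordering must match training).
#' @param area_km2 effective sampling area (see [effective_area()]).
#' @param min_events reliability threshold on total independent events.
#' @return A `density_estimate`; see [check_reliability()] for the flags.
#' @export
predict_density <- function(forest, observed, area_km2, min_events = 100) {
  if (!identical(names(observed$counts), forest$camera_ids))
    stop("observed camera ordering does not match the training columns",
         call. = FALSE)
  newx <- matrix(as.numeric(observed$counts), nrow = 1,
                 dimnames = list(NULL, forest$camera_ids))
  pr <- predict(forest$fit, newdata = newx, predict.all = TRUE)
  trees <- as.numeric(pr$individual)
  n_hat <- as.numeric(pr$aggregate)
  ci <- unname(quantile(trees, c(0.025, 0.975), type = 7))
  est <- structure(
    list(species = observed$species, site = paste(observed$site,
                                                  collapse = "/"),
         n_hat = n_hat, density = n_hat / area_km2,
         ci_low = ci[1] / area_km2, ci_high = ci[2] / area_km2,
         tree_predictions = trees, effective_area_km2 = area_km2,
         n_events = sum(observed$counts), reliable = NA, reasons = character()),
    class = "density_estimate")
  check_reliability(est, n_events = est$n_events, min_events = min_events)
}

#' Estimate density from a training set and an observed event table
#'
#' Convenience wrapper: [fit_forest()] then [predict_density()].
#'
#' @inheritParams fit_forest
#' @inheritParams predict_density
#' @return A `density_estimate`.
#' @export
estimate_density <- function(training, observed, rf = rf_config(), area_km2,
                             min_events = 100) {
  predict_density(fit_forest(training, rf), observed, area_km2, min_events)
}

#' Reliability diagnostics for a density estimate
#'
#' An estimate is flagged reliable when (i) the 95% CI is entirely above
#' zero, (ii) the per-tree prediction distribution is bell-shaped — proxied
#' by a unimodality check: a 20-bin histogram smoothed with a 3-bin moving
#' average must have exactly one local maximum — and (iii) the observed
#' survey has at least `min_events` independent records (several hundred are
#' generally sufficient; very small samples flatten the prediction
#' distribution and push the CI below zero).
#'
#' @param estimate a `density_estimate`.
#' @param n_events total independent events in the observed survey.
#' @param min_events minimum events required (default 100).
#' @return The estimate with `reliable` and `reasons` filled in.
#' @export
check_reliability <- function(estimate, n_events = estimate$n_events,
                              min_events = 100) {
  reasons <- character()
  if (!is.na(estimate$ci_low) && estimate$ci_low <= 0)
    reasons <- c(reasons, "CI lower bound <= 0")
  if (!is_unimodal(estimate$tree_predictions))
    reasons <- c(reasons, "tree-prediction distribution not bell-shaped")
  if (n_events < min_events)
    reasons <- c(reasons, "insufficient events")
  estimate$n_events <- n_events
  estimate$reliable <- length(reasons) == 0L
  estimate$reasons <- reasons
  estimate
}

# Unimodality proxy for "bell-shaped": 20-bin histogram, 3-bin moving
# average, then count local maxima on the run-length-collapsed profile.
# Maxima below 5% of the tallest bin are sampling noise in a thin tail,
# not a second mode, and are ignored.
is_unimodal <- function(x, bins = 20) {
  x <- x[is.finite(x)]
  if (!length(x)) return(FALSE)
  if (diff(range(x)) == 0) return(TRUE)
  h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                      plot = FALSE)
  counts <- h$counts
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[1] <- mean(counts[1:2])
  sm[length(sm)] <- mean(counts[(length(counts) - 1):length(counts)])
  r <- rle(sm)$values  # collapse plateaus so a flat top is one mode
  if (length(r) == 1L) return(TRUE)
  rising <- c(TRUE, diff(r) > 0)   # profile rises into each position
  falling <- c(diff(r) < 0, TRUE)  # and falls out of it (edges count)
  peaks <- r[rising & falling]
  sum(peaks >= 0.05 * max(sm)) == 1L
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("Density of %s at %s\n", x$species, x$site))
  cat(sprintf("  %.2f individuals/km2 (95%% CI %.2f, %.2f); n_hat = %.2f over %.2f km2\n",
              x$density, x$ci_low, x$ci_high, x$n_hat, x$effective_area_km2))
  cat(sprintf("  %d independent events; reliable: %s%s\n", x$n_events,
              x$reliable,
              if (length(x$reasons)) paste0(" (", paste(x$reasons,
                                                        collapse = "; "), ")")
              else ""))
  invisible(x)
}
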