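# Readers and writers for the plain-text interchange formats, plus the
# parameter-recovery experiment driver.

# Multi-format timestamp parser that yields NA (not an error) on bad input,
# so callers can report offending rows.
parse_timestamps <- function(x, formats = c("%Y-%m-%dT%H:%M:%OS",
                                            "%Y-%m-%d %H:%M:%OS",
                                            "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (f in formats) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], f, tz = "UTC"))
  }
  out
}

#' Read a photo-record table
#'
#' Expects columns `site`, `camera_id`, `species`, `timestamp` (ISO-8601);
#' deposited tables with other headers are adapted with `column_map`.
#' Timestamps are parsed as naive local clock times (one timezone, no DST
#' arithmetic). Unparseable timestamps abort with the offending row numbers.
#'
#' @param path CSV file.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g.
#'   `c(camera_id = "Station", timestamp = "DateTime")`.
#' @param pooling species-pooling map applied after reading (see
#'   [pool_species()]); `NULL` to skip.
#' @param grid optional `camera_grid`; when given, records referencing
#'   unknown cameras abort with a validation report.
#' @return Photo-record data frame (`site`, `camera_id`, `species`,
#'   `timestamp`).
#' @export
read_photo_records <- function(path, column_map = NULL,
                               pooling = lycalopex_pooling(), grid = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "camera_id", "species", "timestamp")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("mapped column '", src, "' not found in ", path, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("photo-record file is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ts <- parse_timestamps(raw$timestamp)
  bad <- which(is.na(ts) & !is.na(raw$timestamp) & nzchar(raw$timestamp))
  if (length(bad))
    stop("unparseable timestamp(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  out <- data.frame(site = as.character(raw$site),
                    camera_id = as.character(raw$camera_id),
                    species = as.character(raw$species),
                    timestamp = ts, stringsAsFactors = FALSE)
  if (!is.null(pooling)) out <- pool_species(out, pooling)
  if (!is.null(grid)) {
    unknown <- setdiff(unique(out$camera_id), grid$camera_id)
    if (length(unknown))
      stop("records reference cameras not in the deployment table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write photo records to CSV (ISO-8601 timestamps)
#'
#' @param records photo-record data frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_photo_records <- function(records, path) {
  out <- records[, c("site", "camera_id", "species", "timestamp")]
  out$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a camera deployment table
#'
#' Expects `site`, `camera_id`, `x_m`, `y_m`, `active_start`, `active_end`;
#' `facing_deg` (blank = unrecorded, randomized at simulation time),
#' `detect_radius_m` (default 20) and `sector_halfwidth_deg` (default 22.5)
#' are optional.
#'
#' @param path CSV file.
#' @param column_map optional renaming map, as in [read_photo_records()].
#' @return A `camera_grid`.
#' @export
read_deployments <- function(path, column_map = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("mapped column '", src, "' not found in ", path, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"facing_deg" %in% names(raw)) raw$facing_deg <- NA_real_
  if (!"detect_radius_m" %in% names(raw)) raw$detect_radius_m <- 20
  if (!"sector_halfwidth_deg" %in% names(raw)) raw$sector_halfwidth_deg <- 22.5
  raw$facing_deg <- suppressWarnings(as.numeric(raw$facing_deg))
  raw$active_start <- parse_timestamps(raw$active_start)
  raw$active_end <- parse_timestamps(raw$active_end)
  bad <- which(is.na(raw$active_start) | is.na(raw$active_end))
  if (length(bad))
    stop("unparseable active date(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  # a bare end date means "active through that day"
  end_midnight <- format(raw$active_end, "%H:%M:%S") == "00:00:00"
  raw$active_end[end_midnight] <- raw$active_end[end_midnight] + 86399
  as_camera_grid(raw)
}

#' Write a deployment table to CSV
#'
#' @param grid a `camera_grid` (or compatible data frame).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_deployments <- function(grid, path) {
  out <- as.data.frame(grid)
  out$active_start <- format(out$active_start, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$active_end <- format(out$active_end, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Parameter-recovery experiment
#'
#' Simulates surveys with known true abundance, runs the full estimator on
#' each, and summarizes bias, RMSE and empirical 95%-CI coverage — the
#' validation a simulation-matching estimator owes its users. One training
#' set and one fitted forest are built per call and shared across the
#' replicate truth surveys (each run re-simulates only the observed study),
#' so coverage is conditional on that training realization.
#'
#' @param params a [movement_params()].
#' @param grid a `camera_grid`.
#' @param true_n vector of true abundances to recover.
#' @param n_runs replicate truth surveys per abundance.
#' @param sim a [sim_config()] for the training set.
#' @param rf an [rf_config()].
#' @param seed master seed for the whole experiment.
#' @param min_events reliability threshold passed through.
#' @return A `recovery_report`: list with `runs` (one row per truth survey:
#'   true abundance/density, estimate, CI, coverage flag), `summary` (per
#'   true abundance: mean estimate, relative bias, RMSE, coverage) and
#'   `manifest` (seeds, configs, package version).
#' @export
run_recover <- function(params, grid, true_n = c(4, 8, 16), n_runs = 20,
                        sim = sim_config(replicates_per_abundance = 50),
                        rf = rf_config(n_trees = 500), seed = 1L,
                        min_events = 100) {
  if (!inherits(grid, "camera_grid")) grid <- as_camera_grid(grid)
  sim$base_seed <- sub_seed(seed, 1L)
  rf$seed <- sub_seed(seed, 2L)
  training <- build_training(params, grid, sim)
  forest <- fit_forest(training, rf)
  area <- effective_area(grid, params)
  reg <- region_from_grid(grid, params)
  rows <- list()
  run <- 0L
  for (n_star in true_n) {
    d_true <- n_star / area
    for (r in seq_len(n_runs)) {
      run <- run + 1L
      g <- randomize_facings(grid, sub_seed(seed, 100000L + 2L * run))
      pop <- simulate_population(n_star, params, reg, sim$start, sim$months,
                                 rng_seed = sub_seed(seed,
                                                     100000L + 2L * run + 1L))
      recs <- filter_independent(detect(pop, g), training$window_min)
      obs <- count_events(recs, g, params$species_label, training$window_min)
      est <- predict_density(forest, obs, area, min_events)
      covered <- if (n_star == 0) est$ci_low <= 0
                 else est$ci_low <= d_true && d_true <= est$ci_high
      rows[[run]] <- data.frame(
        true_n = n_star, true_density = d_true, n_hat = est$n_hat,
        density = est$density, ci_low = est$ci_low, ci_high = est$ci_high,
        n_events = est$n_events, reliable = est$reliable, covered = covered)
    }
  }
  runs <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(runs$true_n), function(n_star) {
    sub <- runs[runs$true_n == n_star, ]
    data.frame(true_n = n_star,
               mean_n_hat = mean(sub$n_hat),
               rel_bias = if (n_star > 0) mean(sub$n_hat - n_star) / n_star
                          else NA_real_,
               rmse = sqrt(mean((sub$n_hat - n_star)^2)),
               coverage = mean(sub$covered))
  }))
  structure(list(runs = runs, summary = summ,
                 manifest = run_manifest(seed = seed, sim = sim, rf = rf,
                                         n_events = sum(runs$n_events))),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter-recovery experiment\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Snapshot of a run's configuration and seeds
#'
#' Enough to re-run an estimate bit-identically on the same platform RNG:
#' the master seed, the configs, the package version and a timestamp.
#'
#' @param ... named items to record alongside the defaults.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(...) {
  structure(c(list(package = "crwdensity",
                   version = as.character(packageVersion("crwdensity")),
                   r_version = R.version.string,
                   rng_kind = paste(RNGkind(), collapse = "/"),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
              list(...)),
            class = "run_manifest")
}
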