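# Synthetic camera-trap studies with known true density, emulating a
# three-site, ten-cameras-per-site survey design.

#' Study design template for synthetic surveys
#'
#' Defaults emulate the survey the package targets: 3 sites, 10 cameras per
#' site in a regular 2 x 5 grid at 1,000 m spacing, cameras active
#' 2021-03-01 to 2022-03-31 (13 calendar months).
#'
#' @param n_sites number of sites.
#' @param cameras_per_site cameras per site (laid out 2 x `n/2`).
#' @param spacing_m camera spacing, metres.
#' @param site_area_ha nominal site area, hectares (metadata; the simulation
#'   arena is the grid bounding box buffered by the home-range radius).
#' @param survey_start,survey_end survey window (`Date`).
#' @param species_true_density named numeric vector, individuals/km2 per
#'   species.
#' @param seed integer seed.
#' @return A `study_template` list.
#' @export
study_template <- function(n_sites = 3, cameras_per_site = 10,
                           spacing_m = 1000, site_area_ha = 1000,
                           survey_start = as.Date("2021-03-01"),
                           survey_end = as.Date("2022-03-31"),
                           species_true_density = c("Lycalopex spp." = 0.5),
                           seed = 1L) {
  stopifnot(n_sites >= 1, cameras_per_site >= 1, spacing_m > 0)
  survey_start <- as.Date(survey_start)
  survey_end <- as.Date(survey_end)
  if (survey_start >= survey_end) stop("survey_start must precede survey_end",
                                       call. = FALSE)
  if (any(species_true_density < 0)) stop("densities must be >= 0",
                                          call. = FALSE)
  structure(list(n_sites = as.integer(n_sites),
                 cameras_per_site = as.integer(cameras_per_site),
                 spacing_m = spacing_m, site_area_ha = site_area_ha,
                 survey_start = survey_start, survey_end = survey_end,
                 species_true_density = species_true_density,
                 seed = as.integer(seed)),
            class = "study_template")
}

# Number of calendar months whose first day lies in [start, end].
months_between <- function(start, end) {
  s <- as.POSIXlt(as.Date(start))
  e <- as.POSIXlt(as.Date(end))
  12L * (e$year - s$year) + (e$mon - s$mon) + 1L
}

#' Generate a complete synthetic study with known truth
#'
#' For each site and species, `n = round(density x effective_area)`
#' individuals are simulated over the survey window, detections are scanned,
#' and the *raw* (unfiltered) photo records are returned, so a downstream
#' analysis exercises the independence filter end-to-end. Camera azimuths are
#' drawn per site from the template seed; the deployment table reports them
#' as missing (as field deployments do) while the truth list records the
#' values used.
#'
#' @param template a [study_template()].
#' @param params_by_species named list of [movement_params()], covering every
#'   species in the template's density map.
#' @param outdir optional directory; when given, writes `deployments.csv`,
#'   `photo_records.csv` and `truth.json`.
#' @param emit_filtered also pass the records through the independence filter
#'   before returning/writing (mimics an event-level deposited table).
#' @param window_min filter window when `emit_filtered = TRUE`.
#' @return List with `deployments` (facings blanked), `records`, `truth`
#'   (per site x species: true n, density, effective area, facings, seeds),
#'   and `grids` (the concrete grids actually used, facings filled).
#' @export
generate_study <- function(template, params_by_species, outdir = NULL,
                           emit_filtered = FALSE, window_min = 60) {
  species <- names(template$species_true_density)
  miss <- setdiff(species, names(params_by_species))
  if (length(miss))
    stop("missing movement parameters for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  months <- months_between(template$survey_start, template$survey_end)
  cols <- ceiling(template$cameras_per_site / 2)
  rows <- ceiling(template$cameras_per_site / cols)
  all_recs <- list()
  all_deps <- list()
  grids <- list()
  truth <- list()
  for (s in seq_len(template$n_sites)) {
    site <- sprintf("site%d", s)
    grid <- make_camera_grid(site = site, rows = rows, cols = cols,
                             spacing_m = template$spacing_m,
                             active_start = template$survey_start,
                             active_end = template$survey_end)
    grid <- grid[seq_len(template$cameras_per_site), , drop = FALSE]
    grid <- as_camera_grid(grid)
    grid <- randomize_facings(grid, sub_seed(template$seed, 1000L * s))
    grids[[site]] <- grid
    dep <- grid
    dep$facing_deg <- NA_real_  # unrecorded in the field
    all_deps[[site]] <- dep
    truth[[site]] <- list()
    for (k in seq_along(species)) {
      sp <- species[k]
      pars <- params_by_species[[sp]]
      area <- effective_area(grid, pars)
      n_true <- round(template$species_true_density[[sp]] * area)
      pop_seed <- sub_seed(template$seed, 1000L * s + k)
      reg <- region_from_grid(grid, pars)
      pop <- simulate_population(n_true, pars, reg, template$survey_start,
                                 months, rng_seed = pop_seed)
      recs <- detect(pop, grid)
      recs$species <- rep_len(sp, nrow(recs))
      all_recs[[paste(site, sp)]] <- recs
      truth[[site]][[sp]] <- list(
        n_true = n_true, effective_area_km2 = area,
        density_true = if (area > 0) n_true / area else 0,
        true_density_requested = template$species_true_density[[sp]],
        pop_seed = pop_seed, facings_deg = grid$facing_deg)
    }
  }
  records <- do.call(rbind, all_recs)
  if (is.null(records))
    records <- data.frame(site = character(), camera_id = character(),
                          species = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          individual_id = integer())
  records <- records[order(records$site, records$camera_id,
                           records$timestamp), , drop = FALSE]
  rownames(records) <- NULL
  if (emit_filtered) records <- filter_independent(records, window_min)
  deployments <- do.call(rbind, all_deps)
  rownames(deployments) <- NULL
  out <- list(deployments = deployments, records = records, truth = truth,
              grids = grids, months = months, template = template)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_deployments(deployments, file.path(outdir, "deployments.csv"))
    write_photo_records(records, file.path(outdir, "photo_records.csv"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Named edge-case photo-record fixtures
#'
#' Small hand-constructed record sets that exercise the independence filter's
#' boundary behaviour: an empty study, a single photo, a 3-second burst
#' lasting an hour (one independent event), photos exactly 60 minutes apart
#' (merged under the strict ">" rule), and a two-species study exercising
#' the fox pooling map.
#'
#' @return Named list of photo-record data frames.
#' @export
generate_edge_cases <- function() {
  t0 <- as.POSIXct("2021-03-15 12:00:00", tz = "UTC")
  rec <- function(ts, species = "Lycalopex spp.", camera = "site1_C01") {
    data.frame(site = "site1", camera_id = camera, species = species,
               timestamp = ts, stringsAsFactors = FALSE)
  }
  empty <- rec(t0)[0, , drop = FALSE]
  list(
    empty = empty,
    single_photo = rec(t0),
    burst = rec(t0 + seq(0, 3600, by = 3)),
    boundary_60min = rec(t0 + c(0, 3600)),
    pooling = rbind(
      rec(t0 + c(0, 7200, 14400) * 1.0, species = "Lycalopex griseus"),
      rec(t0 + c(86400, 93600), species = "Lycalopex culpaeus"))
  )
}
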