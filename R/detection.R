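# Camera detection geometry: radius + angular sector in front of each camera.

#' Build a camera deployment grid
#'
#' Lays cameras out in a regular `rows x cols` grid at fixed spacing — the
#' reproducible default for survey designs with ten cameras 1,000 m apart.
#' Each camera watches a circular sector: `detect_radius_m` deep and
#' `2 * sector_halfwidth_deg` wide, centred on `facing_deg` (compass azimuth,
#' 0 = north = +y, clockwise). `facing_deg = NA` means the azimuth was not
#' recorded and is randomized per simulation replicate.
#'
#' @param site site label.
#' @param rows,cols grid layout; default 2 x 5 (ten cameras).
#' @param spacing_m distance between neighbouring cameras, metres.
#' @param origin (x, y) of the first camera, metres.
#' @param facing_deg azimuth(s) the cameras face, degrees, recycled; `NA` to
#'   randomize at simulation time.
#' @param detect_radius_m detection radius, metres (default 20).
#' @param sector_halfwidth_deg half-width of the detection sector, degrees
#'   (default 22.5, i.e. a 45-degree sector).
#' @param active_start,active_end camera active window (`Date` or `POSIXct`).
#' @return A `camera_grid`: data frame with one row per camera and columns
#'   `site`, `camera_id`, `x_m`, `y_m`, `facing_deg`, `detect_radius_m`,
#'   `sector_halfwidth_deg`, `active_start`, `active_end`.
#' @export
make_camera_grid <- function(site = "site1", rows = 2, cols = 5,
                             spacing_m = 1000, origin = c(0, 0),
                             facing_deg = NA_real_, detect_radius_m = 20,
                             sector_halfwidth_deg = 22.5,
                             active_start = as.Date("2021-03-01"),
                             active_end = as.Date("2022-03-31")) {
  xy <- expand.grid(x = origin[1] + (seq_len(cols) - 1) * spacing_m,
                    y = origin[2] + (seq_len(rows) - 1) * spacing_m)
  n <- nrow(xy)
  grid <- data.frame(
    site = site,
    camera_id = sprintf("%s_C%02d", site, seq_len(n)),
    x_m = xy$x, y_m = xy$y,
    facing_deg = rep_len(as.numeric(facing_deg), n),
    detect_radius_m = rep_len(as.numeric(detect_radius_m), n),
    sector_halfwidth_deg = rep_len(as.numeric(sector_halfwidth_deg), n),
    active_start = as.POSIXct(active_start, tz = "UTC"),
    active_end = as.POSIXct(active_end, tz = "UTC") + 86399,
    stringsAsFactors = FALSE)
  as_camera_grid(grid)
}

#' Validate and class a camera deployment table
#'
#' @param grid data frame with the `camera_grid` columns (see
#'   [make_camera_grid()]).
#' @return The validated `camera_grid`.
#' @export
as_camera_grid <- function(grid) {
  need <- c("site", "camera_id", "x_m", "y_m", "facing_deg",
            "detect_radius_m", "sector_halfwidth_deg",
            "active_start", "active_end")
  miss <- setdiff(need, names(grid))
  if (length(miss))
    stop("camera grid is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(grid) < 1L) stop("camera grid must have >= 1 camera", call. = FALSE)
  if (anyDuplicated(paste(grid$site, grid$camera_id)))
    stop("camera ids must be unique within site", call. = FALSE)
  if (any(grid$detect_radius_m <= 0))
    stop("detect_radius_m must be > 0", call. = FALSE)
  if (any(grid$sector_halfwidth_deg <= 0 | grid$sector_halfwidth_deg > 180))
    stop("sector_halfwidth_deg must be in (0, 180]", call. = FALSE)
  if (any(as.numeric(grid$active_end) <= as.numeric(grid$active_start)))
    stop("active_start must precede active_end", call. = FALSE)
  class(grid) <- unique(c("camera_grid", class(grid)))
  grid
}

#' Fill unrecorded camera azimuths with random directions
#'
#' Field deployments aimed at trails rarely record the compass azimuth; for
#' simulation the unknown orientation is marginalized by drawing it uniformly
#' on [0, 360) per camera, reproducibly from a seed.
#'
#' @param grid a `camera_grid`.
#' @param rng_seed integer seed.
#' @return The grid with every `NA` `facing_deg` replaced by a uniform draw.
#' @export
randomize_facings <- function(grid, rng_seed) {
  na <- is.na(grid$facing_deg)
  if (any(na)) {
    set.seed(rng_seed)
    grid$facing_deg[na] <- runif(sum(na), 0, 360)
  }
  grid
}

#' Test points against a camera's detection zone
#'
#' A point is in the zone iff its distance to the camera is at most
#' `detect_radius_m` and the compass bearing from camera to point is within
#' `sector_halfwidth_deg` of `facing_deg` (circular arithmetic). Both
#' boundaries are inclusive and a point exactly at the camera is inside.
#'
#' @param x,y point coordinates, metres (vectorized).
#' @param camera one row of a `camera_grid`.
#' @return Logical vector.
#' @export
in_detection_zone <- function(x, y, camera) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite", call. = FALSE)
  dx <- x - camera$x_m
  dy <- y - camera$y_m
  inside_r <- dx * dx + dy * dy <= camera$detect_radius_m^2
  bearing <- atan2(dx, dy) * 180 / pi  # compass: 0 = +y, clockwise
  d <- (bearing - camera$facing_deg) %% 360
  d <- pmin(d, 360 - d)
  at_cam <- dx == 0 & dy == 0
  inside_r & (at_cam | d <= camera$sector_halfwidth_deg)
}

#' Convert trajectories into simulated photo records
#'
#' Every trajectory step whose endpoint falls inside an active camera's
#' detection zone yields one photo record. Detection is evaluated at step
#' endpoints, not along the segment between them; with step lengths of the
#' same order as the 20 m radius this is a mild, constant undercount that is
#' absorbed by the simulation-matching step (the same rule generates the
#' training data and the observed-data analogue).
#'
#' @param trajectories list of `trajectory` objects.
#' @param grid a `camera_grid` with concrete (non-`NA`) facings; see
#'   [randomize_facings()].
#' @return Photo-record data frame with columns `site`, `camera_id`,
#'   `species`, `timestamp`, `individual_id`, sorted by camera then time.
#' @export
detect <- function(trajectories, grid) {
  if (!inherits(grid, "camera_grid")) grid <- as_camera_grid(grid)
  if (any(is.na(grid$facing_deg)))
    stop("grid has NA facings; call randomize_facings() first", call. = FALSE)
  recs <- lapply(trajectories, function(tr) {
    hits <- detect_scan_cpp(tr$positions, as.numeric(tr$timestamps),
                            grid$x_m, grid$y_m, grid$facing_deg,
                            grid$detect_radius_m, grid$sector_halfwidth_deg,
                            as.numeric(grid$active_start),
                            as.numeric(grid$active_end))
    if (!length(hits$step)) return(NULL)
    data.frame(site = grid$site[hits$camera],
               camera_id = grid$camera_id[hits$camera],
               species = tr$species,
               timestamp = tr$timestamps[hits$step],
               individual_id = tr$individual_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(site = character(), camera_id = character(),
                      species = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      individual_id = integer(), stringsAsFactors = FALSE)
  out[order(out$camera_id, out$timestamp), , drop = FALSE]
}
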