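#' Species movement parameters for the correlated random walk
#'
#' Bundles the per-species simulation parameters: the mean and standard
#' deviation of the (zero-truncated normal) step length, the standard
#' deviation of the angular deflection between consecutive steps, the number
#' of steps walked per month, and the home-range area. The home range is
#' modelled as a disc of the stated area centred on the individual's home
#' centre; its radius in metres is `sqrt(home_range_km2 * 1e6 / pi)`.
#'
#' @param species_label species name the parameters belong to.
#' @param mean_step_m mean step length, metres (>= 0).
#' @param sd_step_m standard deviation of step length, metres (>= 0).
#' @param sd_turn_deg standard deviation of the turning angle, degrees (>= 0).
#' @param steps_per_month number of steps walked in one calendar month (>= 1).
#' @param home_range_km2 home-range area, square kilometres (> 0).
#' @return An object of class `movement_params`.
#' @seealso [default_species_params()] for the shipped carnivore defaults.
#' @examples
#' fox <- movement_params("Lycalopex spp.", 13.18, 17.31, 26.31, 5000, 5.31)
#' home_range_radius(fox)
#' @export
movement_params <- function(species_label, mean_step_m, sd_step_m,
                            sd_turn_deg, steps_per_month, home_range_km2) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  mean_step_m <- num1(mean_step_m, "mean_step_m")
  sd_step_m <- num1(sd_step_m, "sd_step_m")
  sd_turn_deg <- num1(sd_turn_deg, "sd_turn_deg")
  steps_per_month <- num1(steps_per_month, "steps_per_month")
  home_range_km2 <- num1(home_range_km2, "home_range_km2")
  if (mean_step_m < 0 || sd_step_m < 0 || sd_turn_deg < 0)
    stop("step and turn parameters must be >= 0", call. = FALSE)
  if (steps_per_month < 1) stop("steps_per_month must be >= 1", call. = FALSE)
  if (home_range_km2 <= 0) stop("home_range_km2 must be > 0", call. = FALSE)
  structure(
    list(species_label = as.character(species_label),
         mean_step_m = mean_step_m, sd_step_m = sd_step_m,
         sd_turn_deg = sd_turn_deg,
         steps_per_month = as.integer(round(steps_per_month)),
         home_range_km2 = home_range_km2),
    class = "movement_params")
}

#' @export
print.movement_params <- function(x, ...) {
  cat("Movement parameters for", x$species_label, "\n")
  cat(sprintf("  step length: %.2f m (sd %.2f m), turning sd %.2f deg\n",
              x$mean_step_m, x$sd_step_m, x$sd_turn_deg))
  cat(sprintf("  %d steps/month, home range %.2f km2 (disc radius %.0f m)\n",
              x$steps_per_month, x$home_range_km2, home_range_radius(x)))
  invisible(x)
}

#' Home-range disc radius in metres
#'
#' @param params a [movement_params()] object.
#' @return Radius in metres of the disc with area `home_range_km2`.
#' @export
home_range_radius <- function(params) {
  sqrt(params$home_range_km2 * 1e6 / pi)
}

#' Shipped movement-parameter defaults for Chilean carnivores
#'
#' Default correlated-random-walk parameters for the three focal
#' mesocarnivores. Step-length and turning parameters are footprint-chain
#' averages from ecologically matched surrogate species; home ranges are
#' means of published estimates ("Lycalopex spp." pools culpeo and gray fox:
#' mean of 3.5, 4.65, 6, 6.5, 9.2 and 2 km2 = 5.31 km2; "Leopardus guigna":
#' mean of 1.25, 1.5 and 11.8 km2 = 4.85 km2; "Conepatus chinga": mean of
#' 1.09, 1.63, 1.67, 1.78 and 1.9 km2 = 1.61 km2).
#'
#' @param path optional YAML file to read instead of the shipped one.
#' @return Named list of [movement_params()], keyed by species label.
#' @export
default_species_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "species_params.yaml",
                        package = "crwdensity", mustWork = TRUE)
  read_species_params(path)
}

#' Read species movement parameters from a YAML config
#'
#' The file maps species labels to the six `movement_params` fields; see
#' `inst/extdata/species_params.yaml` for the shipped example.
#'
#' @param path YAML file path.
#' @return Named list of [movement_params()].
#' @export
read_species_params <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    movement_params(
      species_label = if (!is.null(p$species_label)) p$species_label else nm,
      mean_step_m = p$mean_step_m, sd_step_m = p$sd_step_m,
      sd_turn_deg = p$sd_turn_deg, steps_per_month = p$steps_per_month,
      home_range_km2 = p$home_range_km2)
  })
  names(out) <- names(raw)
  out
}

#' Rectangular simulation region
#'
#' The arena over which home centres are placed and movement is confined:
#' a core rectangle (typically the camera-grid bounding box) plus a buffer on
#' all sides (typically the home-range disc radius, so that individuals whose
#' home ranges overlap the grid but whose centres lie outside it are
#' represented).
#'
#' @param origin numeric length-2, (x, y) of the core rectangle's lower-left
#'   corner, metres.
#' @param width_m,height_m core rectangle dimensions, metres (> 0).
#' @param buffer_m buffer added on every side, metres (>= 0).
#' @return An object of class `region`.
#' @export
region <- function(origin = c(0, 0), width_m, height_m, buffer_m = 0) {
  stopifnot(length(origin) == 2L, is.numeric(origin), all(is.finite(origin)))
  if (!is.numeric(width_m) || !is.numeric(height_m) ||
      width_m <= 0 || height_m <= 0)
    stop("width_m and height_m must be > 0", call. = FALSE)
  if (buffer_m < 0) stop("buffer_m must be >= 0", call. = FALSE)
  structure(list(origin = as.numeric(origin), width_m = as.numeric(width_m),
                 height_m = as.numeric(height_m),
                 buffer_m = as.numeric(buffer_m)),
            class = "region")
}

# Buffered bounds (xmin, xmax, ymin, ymax) of a region.
region_bounds <- function(reg) {
  c(xmin = reg$origin[1] - reg$buffer_m,
    xmax = reg$origin[1] + reg$width_m + reg$buffer_m,
    ymin = reg$origin[2] - reg$buffer_m,
    ymax = reg$origin[2] + reg$height_m + reg$buffer_m)
}

#' Total (buffered) region area in square kilometres
#'
#' @param reg a [region()] object.
#' @return Area of the buffered rectangle, km2.
#' @export
region_area_km2 <- function(reg) {
  (reg$width_m + 2 * reg$buffer_m) * (reg$height_m + 2 * reg$buffer_m) / 1e6
}
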