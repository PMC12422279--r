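# Independence filtering: raw photo records -> independent events ->
# per-camera count vectors. The one transformation shared verbatim by
# observed and simulated data.

#' Default species-pooling map
#'
#' The two native foxes are nearly indistinguishable in night photographs and
#' are analysed jointly, so both labels map to `"Lycalopex spp."`.
#'
#' @return Named character vector mapping raw labels to analysis labels.
#' @export
lycalopex_pooling <- function() {
  c("Lycalopex griseus" = "Lycalopex spp.",
    "Lycalopex culpaeus" = "Lycalopex spp.")
}

#' Apply a species-pooling map to photo records
#'
#' @param records photo-record data frame.
#' @param pooling named character vector (`raw label -> pooled label`).
#' @return Records with `species` relabelled; unlisted labels pass through.
#' @export
pool_species <- function(records, pooling = lycalopex_pooling()) {
  hit <- records$species %in% names(pooling)
  records$species[hit] <- unname(pooling[records$species[hit]])
  records
}

#' Reduce photo records to independent events
#'
#' Within each (site, camera, species) group, records are walked in time
#' order and one is kept iff it is the group's first or its timestamp exceeds
#' the previously *kept* record's by strictly more than `window_min` minutes
#' (`anchor = "last_kept"`, the greedy convention; records exactly
#' `window_min` apart are merged). `anchor = "last_raw"` instead measures the
#' gap from the previous raw record, so a burst photographing steadily every
#' few seconds never closes an event. Independence is per camera and species;
#' records of the same species at different cameras are never merged.
#'
#' @param records photo-record data frame (`site`, `camera_id`, `species`,
#'   `timestamp`); ties in time are broken by input order.
#' @param window_min independence window in minutes (default 60).
#' @param anchor `"last_kept"` (default) or `"last_raw"`.
#' @return The subset of `records` that are independent events, in
#'   (camera, time) order.
#' @examples
#' r <- data.frame(site = "s", camera_id = "c", species = "sp",
#'                 timestamp = as.POSIXct("2021-03-01", tz = "UTC") +
#'                   c(0, 30, 61, 200) * 60)
#' nrow(filter_independent(r))  # 3
#' @export
filter_independent <- function(records, window_min = 60,
                               anchor = c("last_kept", "last_raw")) {
  anchor <- match.arg(anchor)
  if (nrow(records) == 0L) return(records)
  key <- paste(records$site, records$camera_id, records$species, sep = "\r")
  ord <- order(key, as.numeric(records$timestamp),
               seq_len(nrow(records)))  # ties by input order
  t_min <- as.numeric(records$timestamp[ord]) / 60
  key <- key[ord]
  keep <- logical(length(ord))
  last <- -Inf
  prev_key <- NA_character_
  for (i in seq_along(ord)) {
    if (!identical(key[i], prev_key) || t_min[i] - last > window_min) {
      keep[i] <- TRUE
      prev_key <- key[i]
      last <- t_min[i]
    } else if (anchor == "last_raw") {
      last <- t_min[i]
    }
  }
  out <- records[sort(ord[keep]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count independent events per camera
#'
#' Builds the per-camera event-count vector — the feature vector of the
#' random-forest matching step — for one species, with zeros for cameras
#' that recorded nothing.
#'
#' @param records independence-filtered photo records.
#' @param grid the `camera_grid` the records come from.
#' @param species species label to count.
#' @param window_min the window used in filtering (carried as metadata).
#' @return An `event_table`: list with `site`, `species`, `counts` (named
#'   integer vector ordered like `grid$camera_id`) and `window_min`.
#' @export
count_events <- function(records, grid, species, window_min = 60) {
  if (!inherits(grid, "camera_grid")) grid <- as_camera_grid(grid)
  records <- records[records$species == species, , drop = FALSE]
  unknown <- setdiff(unique(records$camera_id), grid$camera_id)
  if (length(unknown))
    stop("records reference cameras not in the grid: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tab <- table(factor(records$camera_id, levels = grid$camera_id))
  structure(list(site = unique(grid$site), species = species,
                 counts = setNames(as.integer(tab), grid$camera_id),
                 window_min = window_min),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Independent events (> %g min apart) for %s at %s: %d total\n",
              x$window_min, x$species, paste(x$site, collapse = "/"),
              sum(x$counts)))
  print(x$counts)
  invisible(x)
}
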