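# Shared fixtures and independent oracles used across the suite.

fox_params <- function() {
  movement_params("Lycalopex spp.", 13.18, 17.31, 26.31, 5000, 5.31)
}

# Small/fast walker for fixtures where realism is irrelevant.
quick_params <- function(species = "testsp", steps = 300, hr = 5.31,
                         mean_step = 13.18, sd_step = 17.31, sd_turn = 26.31) {
  movement_params(species, mean_step, sd_step, sd_turn, steps, hr)
}

survey_start <- function() as.Date("2021-03-01")

rec_df <- function(minutes, species = "sp", camera = "c1", site = "s1",
                   t0 = as.POSIXct("2021-03-15 00:00:00", tz = "UTC")) {
  n <- length(minutes)
  data.frame(site = rep_len(site, n), camera_id = rep_len(camera, n),
             species = rep_len(species, n), timestamp = t0 + minutes * 60,
             stringsAsFactors = FALSE)
}

# Independence filter re-derived naively: split into groups, walk each group
# in time order keeping a record when the gap from the last kept one exceeds
# the window. Structurally independent of filter_independent().
naive_filter <- function(records, window_min = 60) {
  if (nrow(records) == 0L) return(records)
  groups <- split(seq_len(nrow(records)),
                  paste(records$site, records$camera_id, records$species))
  keep <- integer(0)
  for (idx in groups) {
    idx <- idx[order(as.numeric(records$timestamp[idx]))]
    kept_t <- -Inf
    for (i in idx) {
      t <- as.numeric(records$timestamp[i]) / 60
      if (t - kept_t > window_min) {
        keep <- c(keep, i)
        kept_t <- t
      }
    }
  }
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random photo-record fixture with clustered times so the window rule bites.
random_records <- function(n, n_cameras = 3, n_species = 2, span_min = 2000) {
  rec_df(sort(runif(n, 0, span_min)),
         species = sample(paste0("sp", seq_len(n_species)), n, replace = TRUE),
         camera = sample(paste0("c", seq_len(n_cameras)), n, replace = TRUE))
}

# Exhaustive step x camera detection scan, plain R trigonometry.
brute_detect <- function(trajectories, grid) {
  rows <- list()
  k <- 0L
  for (tr in trajectories) {
    for (i in seq_len(nrow(tr$positions))) {
      for (j in seq_len(nrow(grid))) {
        dx <- tr$positions[i, 1] - grid$x_m[j]
        dy <- tr$positions[i, 2] - grid$y_m[j]
        if (sqrt(dx^2 + dy^2) > grid$detect_radius_m[j]) next
        t <- as.numeric(tr$timestamps[i])
        if (t < as.numeric(grid$active_start[j]) ||
            t > as.numeric(grid$active_end[j])) next
        if (dx != 0 || dy != 0) {
          bearing <- (atan2(dx, dy) * 180 / pi) %% 360
          d <- abs(bearing - grid$facing_deg[j] %% 360)
          d <- min(d, 360 - d)
          if (d > grid$sector_halfwidth_deg[j]) next
        }
        k <- k + 1L
        rows[[k]] <- data.frame(camera_id = grid$camera_id[j],
                                timestamp = tr$timestamps[i],
                                individual_id = tr$individual_id)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(camera_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      individual_id = integer())
  out[order(out$camera_id, out$timestamp, out$individual_id), , drop = FALSE]
}

# Mean of a normal(mu, sigma) truncated to [0, Inf), by numerical
# integration (oracle for the realized mean step length).
truncnorm_mean <- function(mu, sigma) {
  z <- integrate(function(x) dnorm(x, mu, sigma), 0, Inf)$value
  integrate(function(x) x * dnorm(x, mu, sigma) / z, 0, Inf)$value
}

# 1-nearest-neighbour abundance prediction (oracle for the zero-noise
# simulation-matching fixture).
knn1_predict <- function(features, labels, newx) {
  d2 <- rowSums(sweep(features, 2, newx)^2)
  labels[which.min(d2)]
}
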