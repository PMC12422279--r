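# Simulation-matching estimator: training-set construction, forest
# prediction, CI and reliability rules, effective-area arithmetic.

test_that("effective area is the buffered bounding box", {
  p2 <- movement_params("f", 13.18, 17.31, 26.31, 5000, 2)
  g <- make_camera_grid()  # 2 x 5 at 1000 m: 4 x 1 km bounding box
  r_km <- sqrt(2e6 / pi) / 1000
  expect_equal(effective_area(g, p2), (4 + 2 * r_km) * (1 + 2 * r_km),
               tolerance = 1e-12)
  # limit: single camera, vanishing home range
  g1 <- as_camera_grid(g[1, , drop = FALSE])
  tiny <- movement_params("t", 1, 1, 1, 100, 1e-9)
  expect_lt(effective_area(g1, tiny), 1e-4)
  # monotone in home range
  p_big <- movement_params("f", 13.18, 17.31, 26.31, 5000, 6)
  expect_gt(effective_area(g, p_big), effective_area(g, p2))
  # the simulation region and the density conversion share one rectangle
  expect_equal(region_area_km2(region_from_grid(g, p2)),
               effective_area(g, p2))
})

test_that("config validators reject degenerate setups", {
  expect_error(sim_config(abundance_grid = integer(0)), "non-empty")
  expect_error(sim_config(abundance_grid = c(5, 3)), "increasing")
  expect_error(sim_config(replicates_per_abundance = 0), ">= 1")
  expect_error(rf_config(n_trees = 0), ">= 1")
})

test_that("training sets have one labelled row per simulated survey", {
  p <- quick_params(steps = 200, hr = 2)
  g <- make_camera_grid(rows = 2, cols = 2, spacing_m = 500,
                        detect_radius_m = 60)
  sim <- sim_config(abundance_grid = c(0, 3), replicates_per_abundance = 4,
                    months = 1, base_seed = 5)
  tr <- build_training(p, g, sim)
  expect_equal(dim(tr$features), c(8, 4))
  expect_equal(tr$labels, rep(c(0L, 3L), each = 4))
  expect_identical(colnames(tr$features), g$camera_id)
  # no animals, no detections
  expect_true(all(tr$features[tr$labels == 0, ] == 0))
  # deterministic for a fixed base seed
  tr2 <- build_training(p, g, sim)
  expect_identical(tr$features, tr2$features)
})

test_that("a constant-label forest predicts the constant", {
  set.seed(1)
  feats <- matrix(rpois(200, 3), ncol = 4,
                  dimnames = list(NULL, paste0("c", 1:4)))
  training <- structure(list(features = feats, labels = rep(7, 50),
                             camera_ids = paste0("c", 1:4),
                             sim = sim_config(), window_min = 60,
                             filter_sim = TRUE),
                        class = "training_set")
  forest <- fit_forest(training, rf_config(n_trees = 100, seed = 2))
  obs <- structure(list(site = "s", species = "sp",
                        counts = setNames(c(1L, 0L, 5L, 2L), paste0("c", 1:4)),
                        window_min = 60), class = "event_table")
  est <- predict_density(forest, obs, area_km2 = 1)
  expect_equal(est$n_hat, 7, tolerance = 1e-12)
  expect_equal(est$ci_low, 7, tolerance = 1e-12)
  expect_equal(est$ci_high, 7, tolerance = 1e-12)
})

test_that("widely separated abundance classes are recovered exactly", {
  # zero-noise fixture: each abundance n produces the same feature vector
  # n * (10, 0, 5, 1); the forest must match an observed training row to
  # its class, agreeing with a 1-NN oracle.
  ns <- c(2, 8, 16)
  base <- c(10, 0, 5, 1)
  feats <- do.call(rbind, lapply(ns, function(n)
    matrix(rep(n * base, 15), nrow = 15, byrow = TRUE)))
  colnames(feats) <- paste0("c", 1:4)
  labels <- rep(ns, each = 15)
  training <- structure(list(features = feats, labels = labels,
                             camera_ids = paste0("c", 1:4),
                             sim = sim_config(), window_min = 60,
                             filter_sim = TRUE),
                        class = "training_set")
  forest <- fit_forest(training, rf_config(n_trees = 300, seed = 4))
  for (n in ns) {
    obs <- structure(list(site = "s", species = "sp",
                          counts = setNames(as.integer(n * base),
                                            paste0("c", 1:4)),
                          window_min = 60), class = "event_table")
    est <- predict_density(forest, obs, area_km2 = 2)
    expect_equal(est$n_hat, n, tolerance = 1e-8)
    expect_equal(knn1_predict(feats, labels, n * base), n)
    expect_equal(est$density, n / 2, tolerance = 1e-8)
  }
})

test_that("camera-order mismatches are refused", {
  feats <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  training <- structure(list(features = feats, labels = c(1, 2),
                             camera_ids = c("a", "b"), sim = sim_config(),
                             window_min = 60, filter_sim = TRUE),
                        class = "training_set")
  forest <- fit_forest(training, rf_config(n_trees = 10, seed = 1))
  obs <- structure(list(site = "s", species = "sp",
                        counts = setNames(c(0L, 0L), c("b", "a")),
                        window_min = 60), class = "event_table")
  expect_error(predict_density(forest, obs, 1), "ordering")
})

test_that("reliability rules match the refusal conventions", {
  set.seed(9)
  mk <- function(trees, ci_low, n_events) {
    structure(list(species = "sp", site = "s", n_hat = mean(trees),
                   density = mean(trees), ci_low = ci_low,
                   ci_high = max(trees), tree_predictions = trees,
                   effective_area_km2 = 1, n_events = n_events,
                   reliable = NA, reasons = character()),
              class = "density_estimate")
  }
  bell <- rnorm(5000, 10, 1)
  # CI dipping below zero is refused
  est <- check_reliability(mk(bell, -0.1, 500))
  expect_false(est$reliable)
  expect_true(any(grepl("CI lower bound", est$reasons)))
  # too few independent records is refused
  est <- check_reliability(mk(bell, 2, 38))
  expect_false(est$reliable)
  expect_true(any(grepl("insufficient events", est$reasons)))
  # clean unimodal case with positive CI passes
  est <- check_reliability(mk(bell, 2, 500))
  expect_true(est$reliable)
  expect_length(est$reasons, 0)
  # a clearly bimodal prediction distribution is flagged
  bimodal <- c(rnorm(2500, 2, 0.3), rnorm(2500, 12, 0.3))
  est <- check_reliability(mk(bimodal, 1, 500))
  expect_false(est$reliable)
  expect_true(any(grepl("bell-shaped", est$reasons)))
})

test_that("CI brackets the point estimate and scales with area", {
  set.seed(3)
  feats <- matrix(rpois(300, 4), ncol = 3,
                  dimnames = list(NULL, paste0("c", 1:3)))
  labels <- rowSums(feats) + rnorm(100, 0, 0.5)
  training <- structure(list(features = feats, labels = labels,
                             camera_ids = paste0("c", 1:3),
                             sim = sim_config(), window_min = 60,
                             filter_sim = TRUE),
                        class = "training_set")
  forest <- fit_forest(training, rf_config(n_trees = 200, seed = 7))
  obs <- structure(list(site = "s", species = "sp",
                        counts = setNames(c(4L, 4L, 4L), paste0("c", 1:3)),
                        window_min = 60), class = "event_table")
  e1 <- predict_density(forest, obs, area_km2 = 1)
  e2 <- predict_density(forest, obs, area_km2 = 4)
  expect_lte(e1$ci_low, e1$density)
  expect_gte(e1$ci_high, e1$density)
  expect_equal(e1$density / 4, e2$density, tolerance = 1e-12)
  expect_equal(e1$n_hat, e2$n_hat, tolerance = 1e-12)  # abundance unchanged
})

test_that("unimodality proxy separates bells from mixtures", {
  set.seed(5)
  expect_true(crwdensity:::is_unimodal(rnorm(3000)))
  expect_true(crwdensity:::is_unimodal(rexp(3000)))  # mode at the edge
  expect_false(crwdensity:::is_unimodal(c(rnorm(1500, 0, 0.2),
                                          rnorm(1500, 5, 0.2))))
  expect_true(crwdensity:::is_unimodal(rep(3, 100)))  # degenerate spike
  expect_false(crwdensity:::is_unimodal(numeric(0)))
})
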