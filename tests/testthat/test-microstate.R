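test_that("GFP matches its closed form and reference invariance", {
  expect_equal(compute_gfp(matrix(c(1, -1), 2, 1)), 1, tolerance = 1e-12)
  expect_equal(compute_gfp(matrix(5, 4, 3)), rep(0, 3), tolerance = 1e-12)
  m <- matrix(rnorm(6 * 20), 6)
  expect_equal(compute_gfp(m), compute_gfp(m + 3), tolerance = 1e-12)
  expect_true(all(compute_gfp(m) >= 0))
  expect_error(compute_gfp(matrix(1, 1, 5)), "2 channels")
})

test_that("spatial correlation is signed and normalised", {
  v <- rnorm(16)
  expect_equal(spatial_correlation(v, v), 1, tolerance = 1e-12)
  expect_equal(spatial_correlation(v, -v), -1, tolerance = 1e-12)
  a <- c(1, -1, 0, 0)
  b <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation(a, b), 0, tolerance = 1e-12)
  # adding a channel-constant offset changes nothing (average reference)
  expect_equal(spatial_correlation(v + 2, v), 1, tolerance = 1e-12)
})

test_that("K-means separates maps drawn exactly from orthogonal templates", {
  tpl <- cbind(c(1, -1, 0, 0, 1, -1), c(0, 0, 1, -1, -1, 1))
  tpl <- apply(tpl, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  amp <- runif(40, 0.5, 2)
  lab <- rep(1:2, each = 20)
  maps <- t(tpl[, lab]) * amp
  km <- kmeans_microstates(maps, 2, n_restarts = 5, seed = 1)
  mt <- match_templates(km$maps, tpl)
  expect_equal(mt$correlations, c(1, 1), tolerance = 1e-9)
  expect_error(kmeans_microstates(maps[1:3, ], 4), "exceeds")
})

test_that("K-means recovers generator templates and ascends its objective", {
  sim <- tiny_simulation(seed = 31, snr = Inf, n_channels = 24,
                         n_templates = 4)
  maps <- do.call(rbind, lapply(c("Neg", "Neu", "Rea"), function(cc) {
    t(average_erp(sim$epochs, cc)$data)
  }))
  km <- kmeans_microstates(maps, 4, n_restarts = 10, seed = 2)
  mt <- match_templates(km$maps, sim$templates)
  expect_equal(mt$mean, 1, tolerance = 1e-6)
  expect_equal(km$gev, 1, tolerance = 1e-6)
  # per-iteration GEV trace of the winning restart is non-decreasing
  expect_true(all(diff(km$gev_trace) >= -1e-12))

  # noisy default conditions: matched correlation still > 0.95
  simn <- tiny_simulation(seed = 32, snr = 5, n_channels = 24,
                          n_templates = 4)
  mapsn <- do.call(rbind, lapply(c("Neg", "Neu", "Rea"), function(cc) {
    t(average_erp(simn$epochs, cc)$data)
  }))
  kmn <- kmeans_microstates(mapsn, 4, n_restarts = 10, seed = 3)
  expect_gt(match_templates(kmn$maps, simn$templates)$mean, 0.95)
})

test_that("GEV equals its closed-form extremes and is nested-monotone", {
  tpl <- cbind(c(1, -1, 1, -1), c(1, 1, -1, -1)) / 1
  tpl <- scale(tpl, scale = FALSE)
  maps <- t(tpl[, c(1, 2, 1)]) * c(2, 1, 3)
  expect_equal(compute_gev(maps, tpl, c(1, 2, 1)), 1, tolerance = 1e-12)
  expect_equal(compute_gev(maps, tpl, c(2, 1, 2)), 0, tolerance = 1e-12)

  # optimally fitted GEV never decreases when templates are added
  set.seed(5)
  maps2 <- matrix(rnorm(30 * 12), 30)
  tpl3 <- t(maps2[1:3, ])
  tpl5 <- t(maps2[1:5, ])
  lab3 <- backfit(tpl3, t(maps2))$labels
  lab5 <- backfit(tpl5, t(maps2))$labels
  expect_gte(compute_gev(maps2, tpl5, lab5), compute_gev(maps2, tpl3, lab3))
})

test_that("back-fitting equals the per-sample brute-force argmax", {
  set.seed(9)
  tpl <- matrix(rnorm(16 * 4), 16)
  erp <- matrix(rnorm(16 * 200), 16)
  seg <- backfit(tpl, erp)
  brute <- vapply(seq_len(ncol(erp)), function(t) {
    r <- vapply(seq_len(ncol(tpl)), function(j) {
      cor(erp[, t] - mean(erp[, t]), tpl[, j] - mean(tpl[, j]))
    }, numeric(1))
    which.max(r)
  }, integer(1))
  expect_identical(seg$labels, brute)
  # ERP equal to template j at all samples -> all labels j, correlation 1
  const <- tpl[, 3][rep(1, 50)]
  seg3 <- backfit(tpl, matrix(tpl[, 3], 16, 50))
  expect_true(all(seg3$labels == 3))
  expect_equal(seg3$correlation, rep(1, 50), tolerance = 1e-12)
})

test_that("durations partition the epoch", {
  sim <- tiny_simulation(seed = 41, snr = Inf)
  erp <- average_erp(sim$epochs, "Neu")
  seg <- backfit(sim$templates, erp)
  d <- microstate_durations(seg)
  expect_equal(sum(d), length(seg$labels) * 1000 / erp$sampling_rate)
  expect_true(all(d >= 0))

  # single-class segmentation: 1300 samples at 250 Hz -> 5200 ms
  seg1 <- seg
  seg1$labels <- rep(1L, 1300)
  seg1$sampling_rate <- 250
  seg1$k <- 3L
  d1 <- microstate_durations(seg1)
  expect_equal(unname(d1), c(5200, 0, 0))
})

test_that("permutation alignment recovers scrambled template orders", {
  tpl <- make_template_set(24, 4, seed = 6)
  perms <- list(c(2, 4, 1, 3), c(3, 1, 4, 2), c(1, 2, 3, 4), c(4, 3, 2, 1))
  sets <- lapply(perms, function(p) tpl[, p])
  ali <- align_templates(sets)
  # global mean equals the common set up to class order
  mt <- match_templates(ali$global$maps, tpl)
  expect_equal(mt$correlations, rep(1, 4), tolerance = 1e-9)
  # permutations are mutually consistent: participant i's class matched to
  # global class j must be the same underlying template for every i
  recovered <- vapply(seq_along(sets), function(i) {
    perms[[i]][ali$permutations[i, ]]
  }, numeric(4))
  expect_true(all(apply(recovered, 1, function(x) length(unique(x)) == 1)))
  expect_error(align_templates(list(tpl, tpl[, 1:3])), "same number")
})

test_that("matching honours polarity: a sign flip is not the same class", {
  tpl <- make_template_set(16, 2, seed = 8)
  flipped <- cbind(-tpl[, 1], tpl[, 2])
  mt <- match_templates(flipped, tpl)
  # the unflipped class still matches at +1, but the flipped class can only
  # be paired at a strongly negative signed correlation: polarity-invariant
  # matching would report +1 for both
  expect_equal(max(mt$correlations), 1, tolerance = 1e-9)
  expect_lt(min(mt$correlations), -0.9)
  expect_lt(mt$mean, 0.5)
})

test_that("cross-validation selects the true number of classes", {
  # small cohort of 8 participants, 3 true templates, moderate noise
  tpl <- make_template_set(20, 3, seed = 12)
  cfg <- tiny_config(snr = 5)
  cfg$n_channels <- 20L
  erps <- lapply(1:8, function(i) {
    sch <- make_trial_schedule(cfg, seed = 100 + i)
    sim <- simulate_erp(tpl, sch, cfg, seed = 200 + i)
    lapply(c("Neg", "Neu", "Rea"), function(cc) average_erp(sim$epochs, cc))
  })
  cv <- cross_validate_k(erps, k_range = 2:6, n_repeats = 8, n_restarts = 5,
                         seed = 13)
  expect_equal(cv$k, 3)
  expect_equal(nrow(cv$scores), 5 * 8)   # k_range length x n_repeats
  # deterministic selection under a fixed seed
  cv2 <- cross_validate_k(erps, k_range = 2:6, n_repeats = 1, n_restarts = 2,
                          seed = 14)
  cv3 <- cross_validate_k(erps, k_range = 2:6, n_repeats = 1, n_restarts = 2,
                          seed = 14)
  expect_identical(cv2$scores, cv3$scores)
  expect_error(cross_validate_k(erps[1:3]), "at least 4")
})
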