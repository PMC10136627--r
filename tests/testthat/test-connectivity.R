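test_that("instantaneous phase matches analytic closed forms", {
  fs <- 250
  n <- 1000
  t <- (0:(n - 1)) / fs
  dat <- array(0, dim = c(1, 2, n))
  dat[1, 1, ] <- cos(2 * pi * 10 * t)
  dat[1, 2, ] <- sin(2 * pi * 10 * t)
  ep <- as_epochs(dat, sampling_rate = fs)
  ph <- instantaneous_phase(ep, edge_trim = 0.1)
  # unwrapped phase slope of a pure tone = 2*pi*f rad/s within 1%
  dp <- diff(ph$phase[1, 1, ])
  dp <- atan2(sin(dp), cos(dp))
  cen <- 150:850
  expect_equal(mean(dp[cen]) * fs, 2 * pi * 10, tolerance = 0.01)
  # cos vs sin of the same frequency: constant quadrature lag pi/2
  dphi <- ph$phase[1, 1, cen] - ph$phase[1, 2, cen]
  dphi <- atan2(sin(dphi), cos(dphi))
  expect_equal(mean(dphi), pi / 2, tolerance = 0.01)
  expect_lt(sd(dphi), 0.02)

  expect_error(instantaneous_phase(as_epochs(array(0, dim = c(1, 2, 100)))),
               "zero signal")
})

test_that("PLV formula extremes and invariances", {
  # identical phases across channels: PLV exactly 1 for any trial count
  ep <- simulate_phase_coupled_epochs(100, 1, 64, seed = 1)
  ph <- instantaneous_phase(ep, edge_trim = 0)
  expect_equal(plv_timecourse(ph, c(1, 2)), rep(1, 64), tolerance = 1e-9)

  # two trials with phase differences 0 and pi cancel: PLV = 0
  ph2 <- ph
  ph2$phase <- array(0, dim = c(2, 2, 4))
  ph2$phase[2, 2, ] <- pi
  ph2$valid <- rep(TRUE, 4)
  expect_equal(plv_timecourse(ph2, c(1, 2)), rep(0, 4), tolerance = 1e-12)

  # single trial: modulus of one unit vector is always 1
  ph1 <- ph2
  ph1$phase <- ph2$phase[1, , , drop = FALSE]
  ph1$phase[1, , ] <- matrix(runif(8, -pi, pi), 2)
  expect_equal(plv_timecourse(ph1, c(1, 2)), rep(1, 4), tolerance = 1e-12)

  # common phase offset added to both channels leaves PLV unchanged
  set.seed(3)
  phr <- ph2
  phr$phase <- array(runif(5 * 2 * 6, -pi, pi), dim = c(5, 2, 6))
  base <- plv_timecourse(phr, c(1, 2))
  shifted <- phr
  shifted$phase <- shifted$phase + 1.3
  expect_equal(plv_timecourse(shifted, c(1, 2)), base, tolerance = 1e-12)
  expect_true(all(base >= 0 & base <= 1))
})

test_that("microstate gating averages PLV by label", {
  set.seed(4)
  phase <- array(runif(6 * 3 * 8, -pi, pi), dim = c(6, 3, 8))
  ph <- instantaneous_phase(as_epochs(array(rnorm(6 * 3 * 8),
                                            dim = c(6, 3, 8))), edge_trim = 0)
  ph$phase <- phase
  seg <- backfit(matrix(rnorm(3 * 2), 3), matrix(rnorm(3 * 8), 3))
  seg$labels <- c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L)
  seg$k <- 2L
  nets <- microstate_gated_plv(ph, seg)

  # brute-force per-label averaging oracle
  pair_plv <- function(i, j, t) Mod(mean(exp(1i * (phase[, i, t] -
                                                     phase[, j, t]))))
  for (cls in 1:2) {
    idx <- which(seg$labels == cls)
    for (i in 1:2) for (j in (i + 1):3) {
      expected <- mean(vapply(idx, function(t) pair_plv(i, j, t), numeric(1)))
      expect_equal(nets[[cls]]$adjacency[i, j], expected, tolerance = 1e-12)
      expect_equal(nets[[cls]]$adjacency[j, i], expected, tolerance = 1e-12)
    }
  }
  expect_true(all(diag(nets[[1]]$adjacency) == 0))

  # one class covering all samples equals the plain time mean
  seg_all <- seg
  seg_all$labels <- rep(1L, 8)
  net_all <- microstate_gated_plv(ph, seg_all)
  expect_false(net_all[[1]]$empty)
  expect_true(net_all[[2]]$empty)
  expect_equal(net_all[[2]]$n_samples, 0L)

  # gated adjacency lies between the per-sample min and max
  arr_range <- range(vapply(1:8, function(t) pair_plv(1, 2, t), numeric(1)))
  expect_gte(nets[[1]]$adjacency[1, 2], arr_range[1] - 1e-12)
  expect_lte(nets[[1]]$adjacency[1, 2], arr_range[2] + 1e-12)

  seg_bad <- seg
  seg_bad$labels <- seg$labels[1:5]
  expect_error(microstate_gated_plv(ph, seg_bad), "time axes")
})

test_that("clustering coefficient matches hand results and a brute force", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(clustering_coefficient(tri, "binary")$cp_per_node, rep(1, 3))
  star <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))
  expect_equal(clustering_coefficient(star, "binary")$cp_per_node, rep(0, 4))

  # weighted toy matrix against exhaustive triple enumeration
  set.seed(7)
  w <- matrix(runif(16, 0.1, 1), 4)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  got <- clustering_coefficient(w, "weighted")$cp_per_node
  wn <- w / max(w)
  brute <- vapply(1:4, function(i) {
    others <- setdiff(1:4, i)
    tot <- 0
    for (j in others) for (h in others) {
      if (j != h) tot <- tot + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    }
    deg <- sum(w[i, ] > 0)
    tot / (deg * (deg - 1))
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_error(clustering_coefficient(-w), "nonnegative")
})

test_that("characteristic path length matches hand results and a brute force", {
  n <- 5
  cmplt <- matrix(1, n, n) - diag(n)
  expect_equal(characteristic_path_length(cmplt, "binary")$lp, 1)

  path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(characteristic_path_length(path3, "binary")$lp, 4 / 3)

  # weighted 5-node toy vs exhaustive path enumeration (all simple paths)
  set.seed(11)
  w <- matrix(runif(25, 0.2, 1), 5)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  got <- characteristic_path_length(w, "weighted")
  len <- ifelse(w > 0, 1 / w, Inf)
  perms_of <- function(s) {
    if (length(s) <= 1) return(list(s))
    out <- list()
    for (z in seq_along(s)) {
      for (rest in perms_of(s[-z])) out <- c(out, list(c(s[z], rest)))
    }
    out
  }
  all_paths_dist <- function(i, j) {
    # shortest simple path by enumerating every intermediate-node ordering
    best <- Inf
    nodes <- setdiff(1:5, c(i, j))
    for (m in 0:3) {
      mids <- if (m == 0) list(integer()) else {
        unlist(lapply(combn(nodes, m, simplify = FALSE), perms_of),
               recursive = FALSE)
      }
      for (mid in mids) {
        route <- c(i, mid, j)
        d <- sum(len[cbind(route[-length(route)], route[-1])])
        best <- min(best, d)
      }
    }
    best
  }
  brute <- mean(vapply(1:5, function(i) {
    mean(vapply(setdiff(1:5, i), function(j) all_paths_dist(i, j),
                numeric(1)))
  }, numeric(1)))
  expect_equal(got$lp, brute, tolerance = 1e-12)

  # adding edges to a binary graph never increases Lp
  sparse <- path3
  denser <- path3
  denser[1, 3] <- denser[3, 1] <- 1
  expect_lte(characteristic_path_length(denser, "binary")$lp,
             characteristic_path_length(sparse, "binary")$lp)
  expect_error(characteristic_path_length(matrix(0, 1, 1)), "2 nodes")
})
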