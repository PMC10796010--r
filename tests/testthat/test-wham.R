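test_that("an unbiased single window reduces to Boltzmann inversion", {
  set.seed(61)
  q <- rnorm(20000, 0.5, 0.1)
  win <- umbrella_window(center = 0.5, spring = 0, samples = q)
  cfg <- wham_config(n_bins = 20, range = c(0.2, 0.8))
  prof <- solve_wham_1d(win, cfg)
  expect_true(prof$converged)
  # direct histogram inversion, same anchoring
  idx <- floor((q - 0.2) / 0.6 * 20) + 1
  idx[q == 0.8] <- 20
  h <- tabulate(idx[idx >= 1 & idx <= 20], 20)
  Fd <- ifelse(h > 0, -cfg$kT * log(h / sum(h)), Inf)
  Fd <- Fd - min(Fd[h > 0])
  expect_equal(prof$F, Fd, tolerance = 1e-9)
  expect_equal(prof$counts, h)
  # anchoring: sampled minimum is exactly 0
  expect_equal(min(prof$F[is.finite(prof$F)]), 0)
})

test_that("WHAM recovers the analytic harmonic free energy from biased windows", {
  pot <- potential_spec("harmonic")
  wins <- data.frame(center = seq(0.2, 0.8, length.out = 12), spring = 200)
  uw <- sample_potential(pot, wins, 5000, generator_config(seed = 11))
  cfg <- wham_config(n_bins = 50, range = c(0, 1))
  prof <- solve_wham_1d(uw, cfg)
  expect_true(prof$converged)
  keep <- prof$counts >= 100
  diffs <- prof$F[keep] - pot$energy(prof$bin_centers[keep])
  diffs <- diffs - mean(diffs)
  expect_lt(sqrt(mean(diffs^2)), 0.15)
  # self-consistency residual below tol at the returned constants
  beta <- 1 / cfg$kT
  U <- t(sapply(uw, function(w) 0.5 * w$spring * (prof$bin_centers - w$center)^2))
  N_w <- sapply(uw, function(w) length(w$samples))
  p <- ifelse(prof$counts > 0,
              prof$counts /
                colSums(N_w * exp(beta * prof$window_constants) * exp(-beta * U)),
              0)
  f_next <- -cfg$kT * log(exp(-beta * U) %*% p)
  f_next <- as.numeric(f_next - f_next[1])
  expect_lt(max(abs(f_next - prof$window_constants)), cfg$tol)
  # window-order invariance
  prof2 <- solve_wham_1d(rev(uw), cfg)
  expect_equal(prof2$F, prof$F, tolerance = 1e-8)
  # doubling samples does not hurt accuracy on average (3 seed pairs)
  rms_for <- function(n, seed) {
    u <- sample_potential(pot, wins, n, generator_config(seed = seed))
    pr <- suppressWarnings(solve_wham_1d(u, cfg))  # sparse tails may gap
    k <- pr$counts >= 100
    d <- pr$F[k] - pot$energy(pr$bin_centers[k])
    sqrt(mean((d - mean(d))^2))
  }
  r1 <- mean(sapply(1:3, function(s) rms_for(2000, 100 + s)))
  r2 <- mean(sapply(1:3, function(s) rms_for(4000, 200 + s)))
  expect_lte(r2, r1 * 1.25)
})

test_that("double-well barrier is recovered within tolerance", {
  pot <- potential_spec("double_well")
  expect_equal(pot$barrier / 0.593, 3)
  wins <- data.frame(center = seq(0.1, 0.9, length.out = 13), spring = 1000)
  errs <- sapply(1:3, function(s) {
    uw <- sample_potential(pot, wins, 4000, generator_config(seed = 300 + s))
    prof <- solve_wham_1d(uw, wham_config(n_bins = 60, range = c(0.05, 0.95)))
    b <- barrier_height(prof, c(0.2, 0.42), c(0.58, 0.8))
    b / 0.593 - 3
  })
  expect_lt(abs(mean(errs)), 0.3)
})

test_that("barrier_height follows hand-computed profile topology", {
  cfg <- wham_config(n_bins = 10, range = c(0, 1))
  prof <- structure(list(
    bin_centers = seq(0.05, 0.95, by = 0.1),
    F = c(4, 3, 2, 1, 0, 1, 2, 3, 4, 5),
    counts = rep(10L, 10), converged = TRUE, iterations = 1L,
    window_constants = 0, n_dropped = 0L, connectivity_warning = FALSE,
    config = cfg), class = "fe_profile")
  # basins on the two walls of a V: barrier from a's min up to b's min
  expect_equal(barrier_height(prof, c(0, 0.2), c(0.8, 1.0)), 4 - 3)
  expect_equal(barrier_height(prof, c(0.4, 0.6), c(0.8, 1.0)), 4)
  expect_equal(barrier_height(prof, c(0.4, 0.6), c(0.4, 0.6)), 0)
  prof$F[6] <- Inf
  expect_error(barrier_height(prof, c(0, 0.4), c(0.8, 1.0)), "unsampled")
  expect_error(barrier_height(prof, c(-1, -0.5), c(0.8, 1)), "no sampled")
})

test_that("2D reweighting is consistent with the 1D profile and separability", {
  # aux == primary: diagonal marginal reproduces the 1D profile
  pot <- potential_spec("harmonic")
  wins <- data.frame(center = seq(0.25, 0.75, length.out = 8), spring = 200)
  uw <- sample_potential(pot, wins, 3000, generator_config(seed = 21))
  uw <- lapply(uw, function(w)
    umbrella_window(w$center, w$spring, w$samples, aux_samples = w$samples))
  cfg <- wham_config(n_bins = 30, range = c(0.1, 0.9))
  prof <- solve_wham_1d(uw, cfg)
  surf <- reweight_2d(uw, prof, cfg, bins2 = 30, range2 = c(0.1, 0.9))
  pm <- rowSums(exp(-surf$F / cfg$kT) * is.finite(surf$F))
  Fm <- ifelse(pm > 0, -cfg$kT * log(pm), Inf)
  keep <- prof$counts >= 50 & is.finite(Fm)
  d <- Fm[keep] - prof$F[keep]
  expect_lt(sd(d), 0.08)
  # separable potential: conditional F(y | q) is the same parabola per q bin
  pot2 <- potential_spec("separable_2d")
  uw2 <- sample_potential(pot2, wins, 4000, generator_config(seed = 23))
  prof2 <- solve_wham_1d(uw2, cfg)
  surf2 <- reweight_2d(uw2, prof2, cfg, bins2 = 15, range2 = c(60, 120))
  ky <- pot2$params$ky; y0 <- pot2$params$y0
  ref_par <- 0.5 * ky * (surf2$aux_centers - y0)^2
  devs <- c()
  for (iq in seq_along(surf2$q_centers)) {
    row_ok <- surf2$counts[iq, ] >= 100
    if (sum(row_ok) < 5) next
    d <- surf2$F[iq, row_ok] - ref_par[row_ok]
    devs <- c(devs, d - mean(d))
  }
  expect_gt(length(devs), 20)
  expect_lt(sqrt(mean(devs^2)) / 0.593, 0.3)
  expect_error(reweight_2d(sample_potential(pot, wins, 200,
                                            generator_config(seed = 1)),
                           prof, cfg, 10, c(0, 1)), "aux_samples")
})

test_that("a two-basin 2D fixture yields both free-energy minima", {
  pot <- potential_spec("two_basin_2d")
  wins <- data.frame(center = seq(0.2, 0.95, length.out = 12), spring = 150)
  uw <- sample_potential(pot, wins, 4000, generator_config(seed = 29),
                         step = 0.15, step_y = 25)
  cfg <- wham_config(n_bins = 24, range = c(0.15, 1.0))
  prof <- solve_wham_1d(uw, cfg)
  surf <- reweight_2d(uw, prof, cfg, bins2 = 18, range2 = c(0, 180))
  # local minima of the surface among well-sampled cells
  finite <- is.finite(surf$F) & surf$counts >= 50
  vals <- surf$F; vals[!finite] <- Inf
  is_min <- matrix(FALSE, nrow(vals), ncol(vals))
  for (i in 2:(nrow(vals) - 1)) for (j in 2:(ncol(vals) - 1))
    if (finite[i, j])
      is_min[i, j] <- vals[i, j] <= min(vals[(i - 1):(i + 1), (j - 1):(j + 1)])
  mins <- which(is_min, arr.ind = TRUE)
  locs <- cbind(surf$q_centers[mins[, 1]], surf$aux_centers[mins[, 2]])
  near <- function(q, y) any(abs(locs[, 1] - q) < 0.12 &
                               abs(locs[, 2] - y) < 25)
  expect_true(near(0.8, 140))
  expect_true(near(0.35, 40))
})

test_that("window files round-trip through the TSV metadata format", {
  uw <- list(umbrella_window(0.3, 100, c(0.28, 0.31, 0.29)),
             umbrella_window(0.5, 100, c(0.49, 0.52, 0.51),
                             aux_samples = c(10, 20, 30)))
  dir <- tempfile(); meta <- write_windows(uw, dir)
  back <- read_windows(meta)
  expect_length(back, 2L)
  expect_equal(back[[1]]$samples, uw[[1]]$samples)
  expect_equal(back[[2]]$aux_samples, uw[[2]]$aux_samples)
  expect_equal(back[[2]]$center, 0.5)
  expect_null(back[[1]]$aux_samples)
})
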