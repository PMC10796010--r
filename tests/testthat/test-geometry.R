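test_that("Kabsch recovers rigid transforms exactly and stays proper", {
  set.seed(1)
  for (trial in 1:20) {
    X <- matrix(rnorm(30, sd = 5), ncol = 3)
    Y <- rigid_transform(X)
    sp <- superpose_kabsch(X, Y)
    expect_lt(sp$rmsd, 1e-9)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(apply_superposition(sp, X), Y, tolerance = 1e-8)
    # symmetry of the minimised RMSD
    Z <- X + matrix(rnorm(30, sd = 0.5), ncol = 3)
    expect_equal(superpose_kabsch(X, Z)$rmsd, superpose_kabsch(Z, X)$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("Kabsch agrees with a rotation-grid brute-force oracle", {
  set.seed(7)
  for (trial in 1:3) {
    X <- matrix(rnorm(15, sd = 3), ncol = 3)
    Y <- matrix(rnorm(15, sd = 3), ncol = 3)
    expect_equal(superpose_kabsch(X, Y)$rmsd, oracle_min_rmsd(X, Y),
                 tolerance = 1e-3)
  }
  # the spec's 3-point displaced case
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  Y <- X; Y[3, ] <- Y[3, ] + c(0, 0, 1)
  expect_equal(superpose_kabsch(X, Y)$rmsd, oracle_min_rmsd(X, Y),
               tolerance = 1e-3)
})

test_that("Kabsch agrees with an established reference implementation", {
  set.seed(99)
  X <- matrix(rnorm(36, sd = 4), ncol = 3)
  Y <- X + matrix(rnorm(36, sd = 1), ncol = 3)
  ours <- superpose_kabsch(X, Y)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("mirror images are never matched by an improper rotation", {
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mirror <- chiral %*% diag(c(-1, 1, 1))
  sp <- superpose_kabsch(mirror, chiral)
  expect_gt(sp$rmsd, 0.1)      # det = -1 would give 0
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
})

test_that("rmsd_series is zero for rigidly moving frames and sized checks hold", {
  set.seed(3)
  ref <- matrix(rnorm(30, sd = 5), ncol = 3)
  frames <- c(list(ref), lapply(1:4, function(i) rigid_transform(ref)))
  expect_equal(rmsd_series(frames, ref), rep(0, 5), tolerance = 1e-9)
  # single displaced atom: rmsd in (0, d], exact value vs direct formula
  d <- 2
  disp <- ref; disp[4, ] <- disp[4, ] + c(0, 0, d)
  r <- rmsd_series(list(disp), ref)
  expect_gt(r, 0); expect_lte(r, d)
  expect_equal(r, oracle_min_rmsd(disp, ref), tolerance = 1e-3)
  expect_error(rmsd_series(list(ref[1:5, ]), ref), "point count")
})

test_that("RMSF matches the closed form for isotropic jitter and removes rigid motion", {
  set.seed(11)
  base <- make_ideal_helix(60)     # large enough that the 6 rigid degrees
  s <- 0.8                         # of freedom absorbed by alignment are
  frames <- lapply(1:4000, function(i)   # negligible per residue
    base + matrix(rnorm(180, sd = s), ncol = 3))
  prof <- rmsf_profile(frames, align_to = "first")
  expect_equal(prof, rep(s * sqrt(3), 60), tolerance = 0.05)
  # rigid motion only: zero everywhere after alignment
  rigid <- lapply(1:30, function(i) rigid_transform(base))
  expect_equal(rmsf_profile(rigid, "mean"), rep(0, 60), tolerance = 1e-8)
  # locality: jitter on one residue elevates only that residue
  frames2 <- lapply(1:400, function(i) {
    f <- base; f[5, ] <- f[5, ] + rnorm(3, sd = 1); f
  })
  prof2 <- rmsf_profile(frames2, "first")
  expect_equal(which.max(prof2), 5L)
  expect_gt(prof2[5], 5 * max(prof2[-5]))
  expect_error(rmsf_profile(list(base)), "at least 2")
})

test_that("radius of gyration matches analytic cases and the direct formula", {
  two <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  a <- 3.1
  tri <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0))
  expect_equal(radius_of_gyration(tri), a / sqrt(3), tolerance = 1e-12)
  set.seed(5)
  X <- matrix(rnorm(150), ncol = 3)
  direct <- sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2)))
  expect_equal(radius_of_gyration(X), direct, tolerance = 1e-12)
  # rigid-motion invariance, mass weighting sanity
  expect_equal(radius_of_gyration(rigid_transform(X)),
               radius_of_gyration(X), tolerance = 1e-9)
  expect_error(radius_of_gyration(X, masses = rep(-1, 50)), "non-negative")
})

test_that("helix axis fitting is oriented N-to-C and accurate on ideal helices", {
  line <- cbind(seq(0, 10, length.out = 8), 0, 0)
  ax <- fit_helix_axis(line)
  expect_equal(ax$direction, c(1, 0, 0), tolerance = 1e-9)
  helix <- make_ideal_helix(12)
  ax2 <- fit_helix_axis(helix)
  expect_lt(interhelix_angle(ax2, c(0, 0, 1)), 2)
  # reversed traversal flips the orientation
  ax3 <- fit_helix_axis(helix[12:1, ])
  expect_lt(interhelix_angle(ax3, c(0, 0, -1)), 2)
  # termini mode
  ax4 <- fit_helix_axis(helix, method = "termini")
  expect_lt(interhelix_angle(ax4, c(0, 0, 1)), 15)
  expect_error(fit_helix_axis(matrix(1, 5, 3)), "coincide")
  expect_error(fit_helix_axis(line[1:2, ]), "at least 3")
})

test_that("interhelix angle spans [0, 180] with exact complementarity", {
  u <- c(0, 0, 1)
  expect_equal(interhelix_angle(u, u), 0)
  expect_equal(interhelix_angle(u, -u), 180)
  set.seed(13)
  for (i in 1:25) {
    a <- rnorm(3); b <- rnorm(3)
    th <- interhelix_angle(a, b)
    expect_gte(th, 0); expect_lte(th, 180)
    expect_equal(interhelix_angle(a, -b), 180 - th, tolerance = 1e-9)
  }
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and oracle-consistent", {
  set.seed(17)
  base <- matrix(rnorm(24, sd = 4), ncol = 3)
  frames <- list(base, rigid_transform(base),
                 base + matrix(rnorm(24), ncol = 3),
                 base + matrix(rnorm(24, sd = 2), ncol = 3))
  M <- pairwise_rmsd_matrix(frames)
  expect_equal(M, t(M))
  expect_equal(diag(M), rep(0, 4))
  expect_lt(M[1, 2], 1e-9)             # rigid copy
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(M[i, j], superpose_kabsch(frames[[i]], frames[[j]])$rmsd,
                 tolerance = 1e-12)
})

test_that("conformational clustering recovers planted structure", {
  expect_equal(cluster_conformations(matrix(0, 5, 5))$labels, rep(1L, 5))
  # two tight groups 20 A apart, 0.5 A internal spread
  set.seed(23)
  base <- matrix(rnorm(30, sd = 5), ncol = 3)
  far <- base + matrix(rnorm(30, sd = 8), ncol = 3)
  grp <- c(lapply(1:4, function(i) base + matrix(rnorm(30, sd = 0.3), ncol = 3)),
           lapply(1:4, function(i) far + matrix(rnorm(30, sd = 0.3), ncol = 3)))
  M <- pairwise_rmsd_matrix(grp)
  cl <- cluster_conformations(M, cutoff = 5)
  expect_length(cl$medoids, 2L)
  expect_equal(cl$labels[1:4], rep(cl$labels[1], 4))
  expect_equal(cl$labels[5:8], rep(cl$labels[5], 4))
  expect_true(all(cl$labels[1:4] != cl$labels[5:8]))
  # medoids belong to their clusters
  expect_equal(cl$labels[cl$medoids], seq_along(cl$medoids))
  # singletons below min distance
  D <- matrix(10, 4, 4); diag(D) <- 0
  expect_length(cluster_conformations(D, cutoff = 1)$medoids, 4L)
  # label partition invariant to frame reordering
  perm <- c(3, 7, 1, 5, 2, 8, 4, 6)
  cl2 <- cluster_conformations(M[perm, perm], cutoff = 5)
  expect_equal(cl2$labels == cl2$labels[1], cl$labels[perm] == cl$labels[perm][1])
  expect_error(cluster_conformations(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
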