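# Synthetic-data generators with known ground truth.
#
# These stand in for the molecular-dynamics ensembles a folding study
# would produce: ideal helices and two-helix dimers built at a chosen
# crossing angle (axis/angle fixtures), Gaussian-perturbed conformational
# ensembles (Q/RMSD/RMSF/clustering fixtures), Metropolis samples from
# analytic potentials under harmonic umbrella biases (WHAM fixtures with
# analytic free energies), and sequence pairs with planted head-tail
# hydrophobic symmetry.  Every generator is a pure function of its
# arguments and seed.

#' Generator configuration
#'
#' Canonical alpha-helix geometry (1.5 Angstrom rise, 2.3 Angstrom
#' radius, 100 degrees twist per residue) and a master seed.
#'
#' @param seed Integer master seed.
#' @param helix_rise Rise per residue (Angstrom).
#' @param helix_radius Helix radius (Angstrom).
#' @param helix_twist Twist per residue (degrees).
#' @param kT Thermal energy used by the Metropolis sampler (kcal/mol).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, helix_rise = 1.5,
                             helix_radius = 2.3, helix_twist = 100,
                             kT = 0.593) {
  structure(list(seed = as.integer(seed), helix_rise = helix_rise,
                 helix_radius = helix_radius, helix_twist = helix_twist,
                 kT = kT), class = "generator_config")
}

# rotation taking +z onto unit vector `axis` (Rodrigues)
rotation_z_to <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  c_ <- sum(z * axis)
  if (sqrt(sum(v^2)) < 1e-12)
    return(if (c_ > 0) diag(3) else diag(c(1, -1, -1)))
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

#' Ideal alpha-helix C-alpha trace
#'
#' @param n_res Number of residues (>= 4).
#' @param axis Length-3 direction for the helix axis (N to C), default
#'   +z.
#' @param cfg A [generator_config()] (helix geometry).
#' @return n x 3 coordinate matrix.
#' @export
make_ideal_helix <- function(n_res, axis = c(0, 0, 1),
                             cfg = generator_config()) {
  n_res <- as.integer(n_res)
  if (n_res < 4L) stop("an ideal helix needs at least 4 residues")
  i <- seq_len(n_res) - 1L
  th <- i * cfg$helix_twist * pi / 180
  base <- cbind(cfg$helix_radius * cos(th), cfg$helix_radius * sin(th),
                cfg$helix_rise * i)
  base <- sweep(base, 2L, colMeans(base))
  base %*% t(rotation_z_to(as.numeric(axis)))
}

#' Two-helix dimer at a prescribed crossing angle
#'
#' Builds two ideal helices (chains A and B, polyalanine) whose N-to-C
#' axis directions are separated by `angle_deg`, displaced laterally so
#' that no inter-chain C-alpha pair comes closer than 4 Angstrom.
#'
#' @param angle_deg Crossing angle in degrees, in \[0, 180\].
#' @param n_res Residues per helix (default 20).
#' @param cfg A [generator_config()].
#' @param separation Initial centre-to-centre offset (Angstrom,
#'   default 10); increased automatically on clash.
#' @return A two-chain [ca_structure()].
#' @export
make_two_helix_dimer <- function(angle_deg, n_res = 20L,
                                 cfg = generator_config(),
                                 separation = 10) {
  if (angle_deg < 0 || angle_deg > 180)
    stop("'angle_deg' must be in [0, 180]")
  a <- angle_deg * pi / 180
  u <- c(0, 0, 1)
  v <- c(sin(a), 0, cos(a))
  ha <- make_ideal_helix(n_res, u, cfg)
  hb <- make_ideal_helix(n_res, v, cfg)
  for (d in separation + 0:20) {
    ca <- sweep(ha, 2L, c(-d / 2, 0, 0), `+`)
    cb <- sweep(hb, 2L, c(d / 2, 0, 0), `+`)
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * ca %*% t(cb)
    dmin <- min(sqrt(pmax(d2, 0)))
    if (is.finite(dmin) && dmin >= 4) {
      codes <- rep("A", n_res)
      return(ca_structure(list(chain_record("A", codes, ca),
                               chain_record("B", codes, cb)),
                          name = sprintf("two_helix_%gdeg", angle_deg)))
    }
  }
  stop("could not place the two helices without a clash")
}

#' Gaussian-perturbed conformational ensemble
#'
#' Adds i.i.d. isotropic Gaussian displacements (per-coordinate standard
#' deviation `amplitude`) to every atom of the reference, independently
#' per frame.
#'
#' @param reference A `ca_structure`.
#' @param n_frames Number of frames (>= 1).
#' @param amplitude Per-coordinate noise standard deviation in
#'   Angstrom (non-negative).
#' @param cfg A [generator_config()]; `cfg$seed` makes the ensemble
#'   reproducible.
#' @return List of `ca_structure` frames (frame_index 0-based).
#' @export
perturb_ensemble <- function(reference, n_frames, amplitude,
                             cfg = generator_config()) {
  stopifnot(inherits(reference, "ca_structure"), n_frames >= 1L,
            amplitude >= 0)
  with_seed(cfg$seed, lapply(seq_len(n_frames), function(fr) {
    chs <- lapply(reference$chains, function(ch) {
      noise <- matrix(rnorm(3L * nrow(ch$ca_coords), sd = amplitude),
                      ncol = 3L)
      chain_record(ch$chain_id, ch$residue_codes, ch$ca_coords + noise,
                   ch$author_numbers)
    })
    ca_structure(chs, name = reference$name, frame_index = fr - 1L)
  }))
}

#' Analytic test potentials
#'
#' * `harmonic`: `U(q) = a (q - q0)^2`; defaults `a = 20` kcal/mol,
#'   `q0 = 0.5`.
#' * `double_well`: `U(q) = B [((q - c)/w)^2 - 1]^2`; minima at
#'   `c - w` and `c + w`, barrier exactly `B` at `q = c`.  Defaults
#'   `B = 3 * 0.593` kcal/mol (3 kT at 300 K), `c = 0.5`, `w = 0.2`.
#' * `separable_2d`: `U(q, y) = a (q - q0)^2 + 0.5 ky (y - y0)^2`;
#'   defaults as above plus `ky = 0.005` kcal/mol/deg^2, `y0 = 90`.
#' * `two_basin_2d`: equal-depth Gaussian-mixture potential
#'   `U = -A ln(g1 + g2)` with basins at `(0.8, 140)` and `(0.35, 40)`
#'   in (Q-like, angle-like) coordinates, widths `(0.07, 12)`,
#'   `A = 1` kcal/mol — a fixture mimicking a native/inverted two-basin
#'   topology.
#'
#' @param name Potential name.
#' @param params Named list overriding the defaults above.
#' @return An object of class `potential_spec`: `name`, `dim` (1 or 2),
#'   `params`, `energy` (function of `q` or `(q, y)`), and for
#'   `double_well` the analytic `barrier` (kcal/mol) and `minima`.
#' @export
potential_spec <- function(name = c("harmonic", "double_well",
                                    "separable_2d", "two_basin_2d"),
                           params = list()) {
  name <- match.arg(name)
  p <- switch(name,
    harmonic = list(a = 20, q0 = 0.5),
    double_well = list(B = 3 * 0.593, c = 0.5, w = 0.2),
    separable_2d = list(a = 20, q0 = 0.5, ky = 0.005, y0 = 90),
    two_basin_2d = list(A = 1, q1 = 0.8, y1 = 140, q2 = 0.35, y2 = 40,
                        sq = 0.07, sy = 12))
  p[names(params)] <- params
  spec <- switch(name,
    harmonic = list(dim = 1L, energy = function(q, y = NULL)
      p$a * (q - p$q0)^2),
    double_well = list(dim = 1L, energy = function(q, y = NULL)
      p$B * (((q - p$c) / p$w)^2 - 1)^2,
      barrier = p$B, minima = c(p$c - p$w, p$c + p$w)),
    separable_2d = list(dim = 2L, energy = function(q, y)
      p$a * (q - p$q0)^2 + 0.5 * p$ky * (y - p$y0)^2),
    two_basin_2d = list(dim = 2L, energy = function(q, y) {
      g1 <- exp(-(q - p$q1)^2 / (2 * p$sq^2) - (y - p$y1)^2 / (2 * p$sy^2))
      g2 <- exp(-(q - p$q2)^2 / (2 * p$sq^2) - (y - p$y2)^2 / (2 * p$sy^2))
      -p$A * log(g1 + g2 + 1e-300)
    }))
  structure(c(list(name = name, params = p), spec),
            class = "potential_spec")
}

#' Metropolis samples from a potential under umbrella biases
#'
#' Runs one Metropolis chain per window on
#' `U(q[, y]) + 0.5 spring (q - center)^2`, discarding a burn-in during
#' which the proposal step is tuned towards 30-50% acceptance, then
#' recording `n_samples` values at the given thinning stride.  For 2D
#' potentials the auxiliary coordinate is sampled jointly (unbiased) and
#' stored in `aux_samples`.
#'
#' @param potential A [potential_spec()].
#' @param windows Data frame (or list of length-2 vectors) with columns
#'   `center`, `spring`.
#' @param n_samples Samples to record per window (>= 100).
#' @param cfg A [generator_config()]; supplies `kT` and the seed.
#' @param stride Thinning stride in Metropolis steps (default 2).
#' @param step Initial proposal step for q (default 0.1; auto-tuned).
#' @param step_y Initial proposal step for the auxiliary coordinate
#'   (default 10; auto-tuned).
#' @return List of [umbrella_window()]s, one per row of `windows`.
#' @export
sample_potential <- function(potential, windows, n_samples,
                             cfg = generator_config(), stride = 2L,
                             step = 0.1, step_y = 10) {
  stopifnot(inherits(potential, "potential_spec"))
  if (is.list(windows) && !is.data.frame(windows))
    windows <- do.call(rbind, lapply(windows, function(w)
      data.frame(center = w[[1L]], spring = w[[2L]])))
  n_samples <- as.integer(n_samples)
  if (n_samples < 100L) stop("'n_samples' must be at least 100 per window")
  beta <- 1 / cfg$kT
  two_d <- potential$dim == 2L
  y0 <- if (two_d) potential$params$y0 %||% potential$params$y1 else NULL
  with_seed(cfg$seed, lapply(seq_len(nrow(windows)), function(w) {
    center <- windows$center[w]; spring <- windows$spring[w]
    etot <- function(q, y) potential$energy(q, y) +
      0.5 * spring * (q - center)^2
    q <- center
    y <- y0
    sq <- step; sy <- step_y
    e <- etot(q, y)
    n_burn <- max(500L, ceiling(0.1 * n_samples * stride))
    acc_win <- 0L
    # burn-in with step adaptation every 100 steps
    for (t in seq_len(n_burn)) {
      qp <- q + runif(1, -sq, sq)
      yp <- if (two_d) y + runif(1, -sy, sy) else NULL
      ep <- etot(qp, yp)
      if (log(runif(1)) < -beta * (ep - e)) {
        q <- qp; y <- yp; e <- ep; acc_win <- acc_win + 1L
      }
      if (t %% 100L == 0L) {
        rate <- acc_win / 100
        if (rate > 0.5) { sq <- sq * 1.25; sy <- sy * 1.25 }
        if (rate < 0.3) { sq <- sq / 1.25; sy <- sy / 1.25 }
        acc_win <- 0L
      }
    }
    qs <- numeric(n_samples)
    ys <- if (two_d) numeric(n_samples) else NULL
    acc <- 0L
    for (k in seq_len(n_samples)) {
      for (t in seq_len(stride)) {
        qp <- q + runif(1, -sq, sq)
        yp <- if (two_d) y + runif(1, -sy, sy) else NULL
        ep <- etot(qp, yp)
        if (log(runif(1)) < -beta * (ep - e)) {
          q <- qp; y <- yp; e <- ep; acc <- acc + 1L
        }
      }
      qs[k] <- q
      if (two_d) ys[k] <- y
    }
    if (acc / (n_samples * stride) < 0.01)
      stop(sprintf(
        "window %d: acceptance %.2f%% below 1%%; adjust 'step' (now %.3g)",
        w, 100 * acc / (n_samples * stride), sq))
    umbrella_window(center, spring, qs, ys)
  }))
}

#' Sequence pair with planted head-tail hydrophobic symmetry
#'
#' Draws sequence `a` uniformly over the 20-letter alphabet, then builds
#' `b` so that each hydrophobic position of `a` is, with probability
#' `strength`, mirrored (same residue) at the reversed position of `b`.
#' Every other position of `b` is drawn uniformly over the 20-letter
#' alphabet with probability `1 - strength` and uniformly over the
#' non-hydrophobic letters with probability `strength`, so the pair
#' interpolates between an independent uniform partner (`strength = 0`)
#' and a perfect hydrophobic mirror with no spurious hydrophobic
#' positions (`strength = 1`, where the symmetry score is exactly 1 by
#' construction); in between, the realised symmetric fraction tracks
#' `strength` closely.
#'
#' @param length Sequence length (>= 10).
#' @param strength Planting probability in \[0, 1\].
#' @param cfg A [generator_config()] (seed).
#' @param hydrophobic_set Residues counted as hydrophobic.
#' @return List with `a`, `b` (both N-to-C order) and `planted_score`,
#'   the realised both-hydrophobic fraction over hydrophobic-bearing
#'   positions of the gapless (a, reverse(b)) pairing — the ground truth
#'   the alignment-based score should approach.
#' @export
make_symmetric_pair <- function(length, strength,
                                cfg = generator_config(),
                                hydrophobic_set = default_hydrophobic_set()) {
  length <- as.integer(length)
  if (length < 10L) stop("'length' must be at least 10")
  if (strength < 0 || strength > 1) stop("'strength' must be in [0, 1]")
  aa20 <- setdiff(aa_alphabet(), "X")
  polar <- setdiff(aa20, hydrophobic_set)
  with_seed(cfg$seed, {
    a <- sample(aa20, length, replace = TRUE)
    b_rev <- sample(aa20, length, replace = TRUE)
    avoid <- runif(length) < strength
    b_rev[avoid] <- sample(polar, sum(avoid), replace = TRUE)
    hyd_a <- a %in% hydrophobic_set
    mirror <- hyd_a & (runif(length) < strength)
    b_rev[mirror] <- a[mirror]
    hyd_b <- b_rev %in% hydrophobic_set
    either <- hyd_a | hyd_b
    planted <- if (any(either)) sum(hyd_a & hyd_b) / sum(either) else 0
    list(a = paste(a, collapse = ""),
         b = paste(rev(b_rev), collapse = ""),
         planted_score = planted)
  })
}
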