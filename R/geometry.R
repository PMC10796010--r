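# Rigid-body superposition and trajectory geometry.
#
# All operations act on n x 3 C-alpha coordinate matrices (Angstrom);
# `ca_structure` objects are accepted anywhere a coordinate matrix is and
# are flattened with coords().

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (weighted)
#' RMSD of `mobile` onto `target`.  The rotation is computed by SVD of
#' the weighted covariance matrix with a sign correction on the smallest
#' singular vector, so the result is always a proper rotation
#' (determinant +1); mirror solutions are never returned.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @param weights Optional non-negative weights, not all zero.
#' @return An object of class `superposition`: list with `rotation`
#'   (3 x 3, coordinates-as-rows convention: `fitted = mobile %*% rotation`
#'   then translated), `translation` (length-3), and `rmsd` (Angstrom).
#' @export
superpose_kabsch <- function(mobile, target, weights = NULL) {
  P <- as_coords(mobile, "mobile"); Q <- as_coords(target, "target")
  if (nrow(P) != nrow(Q)) stop("'mobile' and 'target' differ in point count")
  if (nrow(P) < 3L) stop("superposition needs at least 3 points")
  w <- weights %||% rep(1, nrow(P))
  if (length(w) != nrow(P) || any(w < 0) || sum(w) == 0)
    stop("'weights' must be non-negative, same length as points, not all zero")
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  H <- t(P0 * w) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P0 %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Q0)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sp A `superposition`.
#' @param x n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, x) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as_coords(x) %*% sp$rotation, 2L, -sp$translation)
}

as_frame_list <- function(frames) {
  if (inherits(frames, "ca_structure")) frames <- list(frames)
  frames <- lapply(frames, as_coords, arg = "frames")
  ns <- vapply(frames, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("frames differ in point count: ", paste(unique(ns), collapse = ", "))
  frames
}

#' RMSD of each frame to a reference
#'
#' Each frame is optimally superposed onto the reference before the RMSD
#' is taken, so rigid motion contributes nothing.
#'
#' @param frames List of n x 3 coordinate matrices (or `ca_structure`s).
#' @param reference n x 3 reference coordinates.
#' @return Numeric vector of RMSDs (Angstrom), one per frame.
#' @export
rmsd_series <- function(frames, reference) {
  frames <- as_frame_list(frames)
  reference <- as_coords(reference, "reference")
  if (nrow(frames[[1L]]) != nrow(reference))
    stop("frames and reference differ in point count")
  vapply(frames, function(f) superpose_kabsch(f, reference)$rmsd, 1.0)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are first superposed onto a common reference: either the first
#' frame, or (default) the mean structure obtained by two passes of
#' align-then-average.  RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2).
#'
#' @param frames List of >= 2 equally sized n x 3 coordinate matrices.
#' @param align_to `"mean"` (iterative mean structure, default) or
#'   `"first"`.
#' @return Numeric vector of per-residue RMSFs (Angstrom).
#' @export
rmsf_profile <- function(frames, align_to = c("mean", "first")) {
  align_to <- match.arg(align_to)
  frames <- as_frame_list(frames)
  if (length(frames) < 2L) stop("RMSF needs at least 2 frames")
  ref <- frames[[1L]]
  passes <- if (align_to == "mean") 2L else 1L
  for (p in seq_len(passes)) {
    aligned <- lapply(frames, function(f)
      apply_superposition(superpose_kabsch(f, ref), f))
    if (align_to == "mean") ref <- Reduce(`+`, aligned) / length(aligned)
  }
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  msf <- Reduce(`+`, lapply(aligned, function(f)
    rowSums((f - mean_xyz)^2))) / length(aligned)
  sqrt(msf)
}

#' Radius of gyration
#'
#' @param x n x 3 coordinate matrix or `ca_structure`.
#' @param masses Optional non-negative weights (unit by default).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(x, masses = NULL) {
  x <- as_coords(x)
  w <- masses %||% rep(1, nrow(x))
  if (any(w < 0)) stop("'masses' must be non-negative")
  if (length(w) != nrow(x)) stop("'masses' length must match point count")
  w <- w / sum(w)
  ctr <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2L, ctr)^2)))
}

#' Fit a helix axis
#'
#' Fits a direction to a run of C-alpha positions, oriented from the N-
#' to the C-terminal end (the convention under which native and inverted
#' handshake dimers have complementary crossing angles).  The default
#' method takes the dominant principal axis of the centred coordinates;
#' to keep the estimate unbiased for short segments spanning a
#' non-integer number of turns, the direction is computed from a
#' one-turn (window 4) moving average of the C-alpha trace, which damps
#' the helical wobble while leaving straight traces untouched.
#' `"termini"` uses the normalised last-minus-first C-alpha difference
#' vector instead.
#'
#' @param x n x 3 coordinates of the helix segment, N-to-C order, n >= 3.
#' @param segment Optional [segment_spec()] recorded with the result.
#' @param method `"pca"` (default) or `"termini"`.
#' @return An object of class `helix_axis`: `centroid`, unit `direction`,
#'   `fit_rms` (perpendicular scatter, Angstrom; `NA` for `"termini"`),
#'   `segment`, `method`.
#' @export
fit_helix_axis <- function(x, segment = NULL, method = c("pca", "termini")) {
  method <- match.arg(method)
  x <- as_coords(x)
  if (nrow(x) < 3L) stop("helix axis fit needs at least 3 points")
  ctr <- colMeans(x)
  x0 <- sweep(x, 2L, ctr)
  if (all(abs(x0) < 1e-12)) stop("all points coincide; axis undefined")
  if (method == "pca") {
    xs <- x
    if (nrow(x) >= 6L) {           # one-turn smoothing against helical wobble
      k <- 4L
      xs <- vapply(seq_len(nrow(x) - k + 1L), function(i)
        colMeans(x[i:(i + k - 1L), , drop = FALSE]), numeric(3L))
      xs <- t(xs)
    }
    xs0 <- sweep(xs, 2L, colMeans(xs))
    sv <- svd(xs0)
    dir <- sv$v[, 1L]
    perp <- x0 - outer(as.numeric(x0 %*% dir), dir)
    fit_rms <- sqrt(mean(rowSums(perp^2)))
  } else {
    dir <- x[nrow(x), ] - x[1L, ]
    if (sqrt(sum(dir^2)) < 1e-12) stop("terminal residues coincide; axis undefined")
    fit_rms <- NA_real_
  }
  dir <- dir / sqrt(sum(dir^2))
  span <- x[nrow(x), ] - x[1L, ]
  if (sum(dir * span) < 0) dir <- -dir
  structure(list(centroid = ctr, direction = as.numeric(dir),
                 fit_rms = fit_rms, segment = segment, method = method),
            class = "helix_axis")
}

#' Crossing angle between two oriented helix axes
#'
#' Angle between the N-to-C direction vectors, in degrees on \[0, 180\].
#' The angle is deliberately not folded to \[0, 90\]: orientation carries
#' the native-versus-inverted information, and flipping one axis maps the
#' angle to its complement 180 - theta.
#'
#' @param a,b `helix_axis` objects or length-3 direction vectors.
#' @return Angle in degrees.
#' @export
interhelix_angle <- function(a, b) {
  dir <- function(v) {
    if (inherits(v, "helix_axis")) v <- v$direction
    v <- as.numeric(v)
    if (length(v) != 3L) stop("axis must be a helix_axis or length-3 vector")
    v / sqrt(sum(v^2))
  }
  ca <- sum(dir(a) * dir(b))
  acos(min(1, max(-1, ca))) * 180 / pi
}

#' Pairwise superposed-RMSD matrix
#'
#' @param frames List of >= 2 equally sized n x 3 coordinate matrices.
#' @return Symmetric matrix of superposed RMSDs with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(frames) {
  frames <- as_frame_list(frames)
  k <- length(frames)
  if (k < 2L) stop("need at least 2 frames")
  M <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    M[i, j] <- M[j, i] <- superpose_kabsch(frames[[i]], frames[[j]])$rmsd
  }
  M
}

#' Cluster conformations from a pairwise-RMSD matrix
#'
#' Average-linkage agglomerative clustering cut at a fixed RMSD height.
#' The medoid of each cluster is the member minimising the mean distance
#' to the rest of its cluster (index ties go to the earlier frame).
#'
#' @param M Symmetric non-negative distance matrix, zero diagonal.
#' @param cutoff Linkage cut height in Angstrom (default 4).
#' @return An object of class `cluster_result`: integer `labels` (one
#'   per frame, numbered by first appearance), `medoids` (one frame index
#'   per cluster), `linkage_cutoff`.
#' @export
cluster_conformations <- function(M, cutoff = 4) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8 || any(M < 0))
    stop("'M' must be a symmetric non-negative distance matrix")
  if (nrow(M) == 1L) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(M), method = "average")
    labels <- stats::cutree(hc, h = cutoff)
  }
  labels <- as.integer(match(labels, unique(labels)))
  medoids <- vapply(seq_len(max(labels)), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1L) return(members)
    members[which.min(rowMeans(M[members, members, drop = FALSE]))]
  }, 1L)
  structure(list(labels = labels, medoids = medoids,
                 linkage_cutoff = cutoff), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %d frames, %d cluster(s) at cutoff %.2f A>\n",
              length(x$labels), length(x$medoids), x$linkage_cutoff))
  invisible(x)
}
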