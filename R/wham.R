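# Weighted histogram analysis (WHAM) for umbrella-sampled windows.
#
# Windows carry samples of a reaction coordinate q (e.g. Q) collected
# under a harmonic bias U_bias(q) = 0.5 * spring * (q - center)^2.  The
# self-consistent WHAM equations estimate the window free-energy
# constants f_w and the unbiased distribution p(q); F(q) = -kT ln p(q)
# is reported anchored so its sampled minimum is 0.  Samples biased on q
# can additionally be reweighted onto a second, unbiased coordinate to
# build 2D surfaces such as F(Q, alpha2-alpha2 angle).

#' An umbrella window
#'
#' @param center Bias centre on the reaction coordinate.
#' @param spring Bias strength k in energy units per coordinate squared;
#'   the bias is `0.5 * k * (q - center)^2` (the factor 1/2 is part of
#'   the convention, not of `spring`).
#' @param samples Numeric vector of reaction-coordinate values.
#' @param aux_samples Optional second coordinate (same length), unbiased,
#'   used by [reweight_2d()].
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring, samples, aux_samples = NULL) {
  samples <- as.numeric(samples)
  if (!length(samples)) stop("'samples' must be non-empty")
  if (spring < 0) stop("'spring' must be non-negative")
  if (!is.null(aux_samples) && length(aux_samples) != length(samples))
    stop("'aux_samples' length must match 'samples'")
  structure(list(center = as.numeric(center), spring = as.numeric(spring),
                 samples = samples,
                 aux_samples = if (is.null(aux_samples)) NULL
                 else as.numeric(aux_samples)),
            class = "umbrella_window")
}

#' WHAM configuration
#'
#' @param kT Thermal energy in kcal/mol (default 0.593, about 300 K).
#' @param n_bins Number of histogram bins (>= 10).
#' @param range Length-2 numeric `(lo, hi)`, `lo < hi`; bins are
#'   left-closed, right-open (the last bin closed), samples outside are
#'   dropped and counted.
#' @param tol Convergence tolerance on the maximum change of the window
#'   free-energy constants (kcal/mol, default 1e-7).
#' @param max_iter Iteration cap (default 100000).
#' @return An object of class `wham_config`.
#' @export
wham_config <- function(kT = 0.593, n_bins = 50L, range = c(0, 1),
                        tol = 1e-7, max_iter = 100000L) {
  if (length(range) != 2L || range[1L] >= range[2L])
    stop("'range' must be (lo, hi) with lo < hi")
  if (n_bins < 10L) stop("'n_bins' must be at least 10")
  structure(list(kT = kT, n_bins = as.integer(n_bins),
                 range = as.numeric(range), tol = tol,
                 max_iter = as.integer(max_iter)), class = "wham_config")
}

bias_energy <- function(window, q) 0.5 * window$spring * (q - window$center)^2

bin_index <- function(x, lo, hi, n_bins) {
  idx <- floor((x - lo) / (hi - lo) * n_bins) + 1L
  idx[x == hi] <- n_bins        # close the last bin
  idx[x < lo | x > hi] <- NA_integer_
  idx
}

#' Solve the 1D WHAM equations
#'
#' @param windows List of [umbrella_window()] objects; every window must
#'   contribute at least one sample inside the histogram range.
#' @param config A [wham_config()].
#' @return An object of class `fe_profile`: `bin_centers`, `F`
#'   (kcal/mol, sampled minimum anchored to 0, `Inf` in empty bins),
#'   `counts`, `converged`, `iterations`, `window_constants` (f_w,
#'   first window gauged to 0), `n_dropped`, `connectivity_warning`
#'   (TRUE when an internal zero-count gap splits the sampled range),
#'   and the `config`.
#' @export
solve_wham_1d <- function(windows, config = wham_config()) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, inherits, TRUE, "umbrella_window")),
            inherits(config, "wham_config"))
  lo <- config$range[1L]; hi <- config$range[2L]; nb <- config$n_bins
  centers <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  W <- length(windows)
  counts <- matrix(0, W, nb)
  n_dropped <- 0L
  for (w in seq_len(W)) {
    idx <- bin_index(windows[[w]]$samples, lo, hi, nb)
    n_dropped <- n_dropped + sum(is.na(idx))
    tab <- tabulate(idx[!is.na(idx)], nbins = nb)
    counts[w, ] <- tab
  }
  if (any(rowSums(counts) == 0))
    stop("window(s) ", paste(which(rowSums(counts) == 0), collapse = ", "),
         " contribute no samples inside the histogram range")
  N_w <- rowSums(counts)
  n_b <- colSums(counts)
  beta <- 1 / config$kT
  U <- t(vapply(windows, function(w) bias_energy(w, centers),
                numeric(nb)))                       # W x nb bias energies
  f <- numeric(W)
  converged <- FALSE
  iter <- 0L
  expU <- exp(-beta * U)
  while (iter < config$max_iter) {
    iter <- iter + 1L
    denom <- colSums(N_w * exp(beta * f) * expU)    # length nb
    p <- ifelse(n_b > 0, n_b / denom, 0)
    f_new <- -config$kT * log(expU %*% p)
    f_new <- as.numeric(f_new - f_new[1L])
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < config$tol) { converged <- TRUE; break }
  }
  p <- p / sum(p)
  F <- ifelse(n_b > 0, -config$kT * log(p), Inf)
  F <- F - min(F[n_b > 0])
  sampled <- which(n_b > 0)
  gap <- length(sampled) > 0 &&
    any(n_b[min(sampled):max(sampled)] == 0)
  if (gap)
    warning("zero-count gap splits the sampled range; ",
            "profile segments are only internally comparable")
  structure(list(bin_centers = centers, F = F, counts = n_b,
                 converged = converged, iterations = iter,
                 window_constants = f, n_dropped = n_dropped,
                 connectivity_warning = gap, config = config),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  cat(sprintf(
    "<fe_profile: %d bins on [%g, %g], %s after %d iteration(s)%s>\n",
    length(x$bin_centers), x$config$range[1L], x$config$range[2L],
    if (x$converged) "converged" else "NOT converged", x$iterations,
    if (x$connectivity_warning) ", connectivity warning" else ""))
  invisible(x)
}

#' Reweight biased samples onto a 2D surface
#'
#' Uses the converged window constants to weight every sample by the
#' inverse of its total biased density,
#' `w_s = 1 / sum_w N_w exp[beta (f_w - U_w(q_s))]`, then histograms the
#' weights on (q, aux) and reports `F = -kT ln p`, anchored to 0 at its
#' sampled minimum.
#'
#' @param windows The windows used for the 1D solve; every window must
#'   carry `aux_samples`.
#' @param profile The converged [solve_wham_1d()] result.
#' @param config The [wham_config()] used for the primary coordinate.
#' @param bins2 Number of bins for the second coordinate.
#' @param range2 Length-2 `(lo, hi)` range for the second coordinate.
#' @return An object of class `fe_surface`: `q_centers`, `aux_centers`,
#'   `F` (matrix, q in rows), `weights` (unnormalised probability mass),
#'   `counts`.
#' @export
reweight_2d <- function(windows, profile, config, bins2, range2) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(inherits(profile, "fe_profile"), inherits(config, "wham_config"))
  if (!profile$converged)
    stop("the 1D profile did not converge; refusing to reweight")
  if (any(vapply(windows, function(w) is.null(w$aux_samples), TRUE)))
    stop("every window needs aux_samples for 2D reweighting")
  if (length(range2) != 2L || range2[1L] >= range2[2L])
    stop("'range2' must be (lo, hi) with lo < hi")
  beta <- 1 / config$kT
  f <- profile$window_constants
  N_w <- vapply(windows, function(w) length(w$samples), 1.0)
  lo <- config$range[1L]; hi <- config$range[2L]; nb <- config$n_bins
  lo2 <- range2[1L]; hi2 <- range2[2L]; nb2 <- as.integer(bins2)
  Wt <- matrix(0, nb, nb2)
  Ct <- matrix(0L, nb, nb2)
  for (w in seq_along(windows)) {
    q <- windows[[w]]$samples
    y <- windows[[w]]$aux_samples
    denom <- rowSums(vapply(seq_along(windows), function(v)
      N_w[v] * exp(beta * (f[v] - bias_energy(windows[[v]], q))),
      numeric(length(q))))
    wts <- 1 / denom
    iq <- bin_index(q, lo, hi, nb)
    iy <- bin_index(y, lo2, hi2, nb2)
    ok <- !is.na(iq) & !is.na(iy)
    for (s in which(ok)) {
      Wt[iq[s], iy[s]] <- Wt[iq[s], iy[s]] + wts[s]
      Ct[iq[s], iy[s]] <- Ct[iq[s], iy[s]] + 1L
    }
  }
  if (all(Wt == 0)) stop("no samples fall inside the 2D range")
  p <- Wt / sum(Wt)
  F2 <- ifelse(p > 0, -config$kT * log(p), Inf)
  F2 <- F2 - min(F2[p > 0])
  structure(list(
    q_centers = lo + (seq_len(nb) - 0.5) * (hi - lo) / nb,
    aux_centers = lo2 + (seq_len(nb2) - 0.5) * (hi2 - lo2) / nb2,
    F = F2, weights = Wt, counts = Ct), class = "fe_surface")
}

#' Free-energy barrier between two basins of a 1D profile
#'
#' Locates the minimum of F inside each basin range and returns the
#' highest sampled F between the two minima, measured from the minimum
#' of `basin_a`.
#'
#' @param profile An [solve_wham_1d()] result.
#' @param basin_a,basin_b Length-2 coordinate ranges `(lo, hi)`; both
#'   must contain sampled bins.
#' @return Barrier height in the profile's energy units (kcal/mol).
#' @export
barrier_height <- function(profile, basin_a, basin_b) {
  stopifnot(inherits(profile, "fe_profile"))
  locate_min <- function(rng, label) {
    in_rng <- which(profile$bin_centers >= rng[1L] &
                      profile$bin_centers <= rng[2L] &
                      is.finite(profile$F))
    if (!length(in_rng))
      stop(sprintf("basin [%g, %g] contains no sampled bins", rng[1L], rng[2L]))
    in_rng[which.min(profile$F[in_rng])]
  }
  ia <- locate_min(basin_a); ib <- locate_min(basin_b)
  if (ia == ib) return(0)
  span <- min(ia, ib):max(ia, ib)
  if (any(!is.finite(profile$F[span])))
    stop("unsampled gap between the basins; barrier undefined")
  max(profile$F[span]) - profile$F[ia]
}

#' Write umbrella windows to plain-text files plus a metadata TSV
#'
#' One file per window (one sample per line; a second column when
#' `aux_samples` are present), each with a `#`-comment header recording
#' centre, spring and the bias convention, plus a metadata TSV with
#' columns `path`, `center`, `spring`.
#'
#' @param windows List of [umbrella_window()]s.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"window"`).
#' @return Invisibly, the metadata file path.
#' @export
write_windows <- function(windows, dir, prefix = "window") {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(path = character(0), center = numeric(0),
                     spring = numeric(0))
  for (w in seq_along(windows)) {
    fn <- sprintf("%s_%03d.dat", prefix, w)
    win <- windows[[w]]
    hdr <- c(sprintf("# center %.10g spring %.10g", win$center, win$spring),
             "# bias convention: U_bias(q) = 0.5 * spring * (q - center)^2")
    body <- if (is.null(win$aux_samples))
      sprintf("%.10g", win$samples)
    else sprintf("%.10g\t%.10g", win$samples, win$aux_samples)
    writeLines(c(hdr, body), file.path(dir, fn))
    meta <- rbind(meta, data.frame(path = fn, center = win$center,
                                   spring = win$spring))
  }
  meta_path <- file.path(dir, paste0(prefix, "_meta.tsv"))
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(meta_path)
}

#' Read umbrella windows from a metadata TSV
#'
#' @param meta_path Metadata TSV with columns `path`, `center`, `spring`;
#'   window paths are resolved relative to the metadata file.
#' @return List of [umbrella_window()]s.
#' @export
read_windows <- function(meta_path) {
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("path", "center", "spring") %in% names(meta)))
    stop("metadata must have columns path, center, spring")
  base <- dirname(meta_path)
  lapply(seq_len(nrow(meta)), function(k) {
    fn <- meta$path[k]
    if (!file.exists(fn)) fn <- file.path(base, meta$path[k])
    lines <- readLines(fn, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    fields <- strsplit(trimws(lines), "\\s+")
    ncol <- unique(lengths(fields))
    if (length(ncol) != 1L)
      stop(sprintf("inconsistent column count in '%s'", fn))
    vals <- suppressWarnings(as.numeric(unlist(fields)))
    if (anyNA(vals)) stop(sprintf("non-numeric sample in '%s'", fn))
    m <- matrix(vals, ncol = ncol, byrow = TRUE)
    umbrella_window(meta$center[k], meta$spring[k], m[, 1L],
                    if (ncol > 1L) m[, 2L] else NULL)
  })
}

#' Write a 1D free-energy profile as TSV
#' @param profile An `fe_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(
    data.frame(bin_center = profile$bin_centers, F = profile$F,
               counts = profile$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
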