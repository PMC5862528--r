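# Internal numerics shared across the imaging modules. All volumes are plain
# 3D numeric/logical arrays indexed [z, y, x]; physical sizes are in microns.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  }
  invisible(x)
}

check_voxel_size <- function(voxel_size_um) {
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop("`voxel_size_um` must be 3 positive reals (z, y, x)", call. = FALSE)
  }
  as.numeric(voxel_size_um)
}

# Apply an n x n operator matrix K along one axis of a 3D array.
apply_along <- function(vol, axis, K) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- K %*% matrix(v, nrow = d[axis])
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

# Row-normalised Gaussian convolution matrix (replicate-like boundary).
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) {
    w <- exp(-((i - j)^2) / (2 * sigma^2))
    w[abs(i - j) > r] <- 0
    w
  })
  K / rowSums(K)
}

# Separable anisotropic Gaussian smoothing; sigma_vox is length-3 (z, y, x).
gauss_smooth3 <- function(vol, sigma_vox) {
  check_volume(vol)
  d <- dim(vol)
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      vol <- apply_along(vol, axis, gauss_matrix(d[axis], sigma_vox[axis]))
    }
  }
  vol
}

# Shift a 3D array by one voxel along `axis`, replicating the boundary plane.
shift1 <- function(vol, axis, by) {
  d <- dim(vol)
  n <- d[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

# Gradient magnitude in physical units (central differences / 2h).
gradient_magnitude3 <- function(vol, voxel_size_um) {
  g2 <- 0
  for (axis in 1:3) {
    g <- (shift1(vol, axis, 1L) - shift1(vol, axis, -1L)) /
      (2 * voxel_size_um[axis])
    g2 <- g2 + g^2
  }
  sqrt(g2)
}

# Laplacian in physical units (second differences / h^2).
laplacian3 <- function(vol, voxel_size_um) {
  out <- 0
  for (axis in 1:3) {
    out <- out + (shift1(vol, axis, 1L) + shift1(vol, axis, -1L) - 2 * vol) /
      voxel_size_um[axis]^2
  }
  out
}

# 3x3x3 box maximum via sequential 3-point running maxima.
boxmax3 <- function(vol) {
  for (axis in 1:3) {
    vol <- pmax(vol, shift1(vol, axis, 1L), shift1(vol, axis, -1L))
  }
  vol
}

# Classic histogram Otsu threshold on a numeric vector.
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= 1e-12 * max(abs(rng), 1)) {
    stop("intensity is constant; threshold undefined", call. = FALSE)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(
    tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins))
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w1 <- cumsum(h)
  w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  between <- w1 * w2 * (m1 - m2)^2
  between[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(between)]
}

# Photon-limited noise: Poisson shot noise (Gaussian approximation for large
# expected counts) plus Gaussian read noise. `snr` is the signal-to-noise
# ratio at the reference amplitude.
add_acquisition_noise <- function(signal, snr, reference_amplitude = 100) {
  stopifnot(snr > 0)
  kappa <- snr^2 / reference_amplitude       # photons per intensity unit
  lam <- pmax(signal, 0) * kappa
  big <- lam > 1e4
  shot <- numeric(length(lam))
  shot[big] <- (lam[big] + stats::rnorm(sum(big), sd = sqrt(lam[big]))) / kappa
  shot[!big] <- stats::rpois(sum(!big), lam[!big]) / kappa
  read <- stats::rnorm(length(lam), sd = 0.5 * reference_amplitude / snr)
  out <- shot + read
  dim(out) <- dim(signal)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
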