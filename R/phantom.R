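#' Multi-channel 3D image stack
#'
#' Container for confocal-like voxel data: a named list of 3D arrays (one per
#' channel, indexed `[z, y, x]`) plus the physical voxel size in microns.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions.
#' @param voxel_size_um numeric length-3, voxel edge length in microns for the
#'   (z, y, x) axes.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size_um) {
  if (!is.list(channels) || length(channels) < 1L || is.null(names(channels)) ||
      any(names(channels) == "")) {
    stop("`channels` must be a non-empty named list of 3D arrays", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  lapply(channels, check_volume, name = "channel")
  if (length(unique(lapply(dims, as.integer))) != 1L) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  structure(
    list(channels = channels,
         voxel_size_um = stats::setNames(check_voxel_size(voxel_size_um),
                                         c("z", "y", "x"))),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), %s um/voxel\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size_um, digits = 3), collapse = " x ")))
  cat("channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$channels[[1]])

get_channel <- function(stack, channel) {
  if (!inherits(stack, "image_stack")) {
    stop("`stack` must be an image_stack", call. = FALSE)
  }
  if (!channel %in% names(stack$channels)) {
    stop(sprintf("unknown channel '%s'; stack has: %s", channel,
                 paste(names(stack$channels), collapse = ", ")), call. = FALSE)
  }
  stack$channels[[channel]]
}

voxel_volume_um3 <- function(voxel_size_um) prod(check_voxel_size(voxel_size_um))

#' Disc phantom parameters
#'
#' Parameter set for [simulate_disc()]. Defaults emulate a scaled-down
#' eye-antennal imaginal disc acquired as a confocal z-stack: z spacing about
#' 1 micron and 0.5 micron lateral sampling. The pH3 densities are per mm^3 of
#' the respective compartment; defaults are chosen so a phantom carries a few
#' tens of mitotic spots, the per-disc scale seen in real discs.
#'
#' @param shape_voxels integer length-3, stack dimensions (z, y, x); each
#'   must be at least 16.
#' @param voxel_size_um numeric length-3, voxel size in microns (z, y, x).
#' @param target_clone_fraction fraction of tissue voxels occupied by GFP+
#'   clones, in `[0, 1]`.
#' @param n_clones_range integer length-2, inclusive range for the number of
#'   seeded clones.
#' @param ph3_density_inside_per_mm3,ph3_density_outside_per_mm3 expected pH3+
#'   spot densities inside clones and in the GFP- tissue, per mm^3.
#' @param snr signal-to-noise ratio at the nominal channel amplitude.
#' @param background_level constant intensity offset added to every channel.
#' @param nuclear_radius_um nominal nuclear radius used to render pH3 spots
#'   and to enforce a hard-core minimum separation of twice this radius.
#' @param clone_scale_um length scale of the smoothed clone blobs.
#' @return An object of class `disc_phantom_params`.
#' @seealso [make_condition_preset()] for the study-condition presets.
#' @export
disc_phantom_params <- function(shape_voxels = c(24L, 56L, 80L),
                                voxel_size_um = c(1.0, 0.5, 0.5),
                                target_clone_fraction = 0.46,
                                n_clones_range = c(3L, 8L),
                                ph3_density_inside_per_mm3 = 3e6,
                                ph3_density_outside_per_mm3 = 1e6,
                                snr = 10,
                                background_level = 5,
                                nuclear_radius_um = 2.5,
                                clone_scale_um = 6) {
  shape_voxels <- as.integer(shape_voxels)
  if (length(shape_voxels) != 3L || any(shape_voxels < 16L)) {
    stop("`shape_voxels` must be 3 integers, each >= 16", call. = FALSE)
  }
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (!is.finite(target_clone_fraction) || target_clone_fraction < 0 ||
      target_clone_fraction > 1) {
    stop("`target_clone_fraction` must be in [0, 1]", call. = FALSE)
  }
  n_clones_range <- as.integer(n_clones_range)
  if (length(n_clones_range) != 2L || n_clones_range[1] < 1L ||
      n_clones_range[2] < n_clones_range[1]) {
    stop("`n_clones_range` must be an integer interval with lower bound >= 1",
         call. = FALSE)
  }
  dens <- c(ph3_density_inside_per_mm3, ph3_density_outside_per_mm3)
  if (any(!is.finite(dens)) || any(dens < 0)) {
    stop("pH3 densities must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(snr) || snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  if (background_level < 0) stop("`background_level` must be >= 0", call. = FALSE)
  structure(
    list(shape_voxels = shape_voxels, voxel_size_um = voxel_size_um,
         target_clone_fraction = target_clone_fraction,
         n_clones_range = n_clones_range,
         ph3_density_inside_per_mm3 = ph3_density_inside_per_mm3,
         ph3_density_outside_per_mm3 = ph3_density_outside_per_mm3,
         snr = snr, background_level = background_level,
         nuclear_radius_um = nuclear_radius_um,
         clone_scale_um = clone_scale_um),
    class = "disc_phantom_params")
}

# Mean tumor-volume fraction per study condition. The FRT19A neutral-clone
# fraction is a declared stand-in (no printed value exists for it).
.clone_fraction_presets <- c(
  FRT19A          = 0.25,
  ph505           = 0.46,
  ph505_rescue    = 0.07,
  ph505_cadKD     = 0.14,
  ph505_drmKD     = 0.13,
  ph505_kniKD     = 0.05,
  ph505_kniKD2    = 0.14,
  ph505_bgcnKD    = 0.14,
  ph505_kniKD_p35 = 0.06,
  ph505_ato       = 0.03)

#' Phantom parameters for a named study condition
#'
#' Returns [disc_phantom_params()] whose `target_clone_fraction` equals the
#' condition's mean tumor-volume fraction: 46% for the ph505 baseline, 7% for
#' the UAS-ph rescue, 14/13/5/14% for cad/drm/kni/bgcn knock-downs, 14% for
#' the second kni RNAi line, 6% for kni-KD with apoptosis blocked (UAS-p35)
#' and 3% for atonal overexpression. The FRT19A neutral-clone preset (25%) is
#' a documented stand-in, not a reported value.
#'
#' @param name condition label; one of
#'   `r paste(names(.clone_fraction_presets), collapse = ", ")`.
#' @param ... overrides passed to [disc_phantom_params()].
#' @return A `disc_phantom_params` object.
#' @examples
#' make_condition_preset("ph505")$target_clone_fraction       # 0.46
#' make_condition_preset("ph505_kniKD")$target_clone_fraction # 0.05
#' @export
make_condition_preset <- function(name, ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.clone_fraction_presets)) {
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 as.character(name)[1],
                 paste(names(.clone_fraction_presets), collapse = ", ")),
         call. = FALSE)
  }
  disc_phantom_params(
    target_clone_fraction = unname(.clone_fraction_presets[name]), ...)
}

#' Condition preset names
#' @return Character vector of registered condition labels.
#' @export
condition_presets <- function() names(.clone_fraction_presets)

# Two overlapping ellipsoids ("eye" + "antennal" lobes); coordinates in um.
render_tissue_mask <- function(shape_voxels, voxel_size_um, jitter = 0.04) {
  d <- shape_voxels
  zc <- (seq_len(d[1]) - 0.5) * voxel_size_um[1]
  yc <- (seq_len(d[2]) - 0.5) * voxel_size_um[2]
  xc <- (seq_len(d[3]) - 0.5) * voxel_size_um[3]
  ext <- d * voxel_size_um
  jit <- function() 1 + stats::runif(1, -jitter, jitter)
  ellipsoid <- function(center, radii) {
    f <- outer(((zc - center[1]) / radii[1])^2,
               ((yc - center[2]) / radii[2])^2, "+")
    outer(f, ((xc - center[3]) / radii[3])^2, "+") <= 1
  }
  eye <- ellipsoid(
    center = c(ext[1] * 0.5 * jit(), ext[2] * 0.5 * jit(), ext[3] * 0.63),
    radii = c(ext[1] * 0.36 * jit(), ext[2] * 0.40 * jit(), ext[3] * 0.28 * jit()))
  antennal <- ellipsoid(
    center = c(ext[1] * 0.5 * jit(), ext[2] * 0.5 * jit(), ext[3] * 0.28),
    radii = c(ext[1] * 0.28 * jit(), ext[2] * 0.28 * jit(), ext[3] * 0.20 * jit()))
  eye | antennal
}

# Clone support: seeded Gaussian bumps plus a smoothed noise field,
# thresholded at the tissue quantile that yields the target voxel count.
# Lowering the threshold accretes voxels; the quantile step finds the
# accretion endpoint in one pass, so the +/-0.01 fraction tolerance is met
# by construction whenever the target is attainable (0 <= fraction <= 1).
render_clone_mask <- function(tissue, params) {
  target <- params$target_clone_fraction
  d <- dim(tissue)
  n_tissue <- sum(tissue)
  mask <- array(FALSE, d)
  if (target <= 0 || n_tissue == 0L) return(mask)
  n_target <- round(target * n_tissue)
  if (n_target == 0L) return(mask)
  vs <- params$voxel_size_um
  n_clones <- if (params$n_clones_range[1] == params$n_clones_range[2]) {
    params$n_clones_range[1]
  } else {
    sample(seq(params$n_clones_range[1], params$n_clones_range[2]), 1L)
  }
  seeds <- arrayInd(sample(which(tissue), n_clones,
                           replace = n_clones > n_tissue), d)
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]
  s <- params$clone_scale_um
  field <- array(0, d)
  for (k in seq_len(n_clones)) {
    ctr <- c(zc[seeds[k, 1]], yc[seeds[k, 2]], xc[seeds[k, 3]])
    amp <- stats::runif(1, 0.6, 1)
    f <- outer((zc - ctr[1])^2, (yc - ctr[2])^2, "+")
    f <- outer(f, (xc - ctr[3])^2, "+")
    field <- pmax(field, amp * exp(-f / (2 * s^2)))
  }
  noise <- gauss_smooth3(array(stats::rnorm(prod(d)), d), 2 / vs)
  field <- field + 0.15 * noise / stats::sd(noise)
  vals <- field[tissue]
  thr <- sort(vals, decreasing = TRUE)[n_target]
  mask[tissue] <- vals >= thr
  # ties at the threshold can overshoot; trim back to the exact count
  excess <- sum(mask) - n_target
  if (excess > 0) {
    at_thr <- which(mask & field == thr)
    mask[at_thr[seq_len(min(excess, length(at_thr)))]] <- FALSE
  }
  mask
}

# Draw spot centers on compartment voxels with a hard-core minimum
# separation against all previously placed spots (nuclei do not overlap,
# including across the clone boundary).
place_spots <- function(compartment_mask, n, voxel_size_um, min_sep_um,
                        existing = matrix(numeric(0), ncol = 3)) {
  d <- dim(compartment_mask)
  idx_pool <- which(compartment_mask)
  if (n == 0L || length(idx_pool) == 0L) {
    return(matrix(numeric(0), ncol = 3))
  }
  accepted <- matrix(NA_real_, nrow = n, ncol = 3)
  got <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (got < n && tries < max_tries) {
    tries <- tries + 1L
    cand_vox <- arrayInd(sample(idx_pool, 1L), d)
    cand <- as.numeric((cand_vox - 0.5) * voxel_size_um)
    others <- rbind(existing, accepted[seq_len(got), , drop = FALSE])
    ok <- nrow(others) == 0L ||
      min(sqrt(colSums((t(others) - cand)^2))) >= min_sep_um
    if (ok) {
      got <- got + 1L
      accepted[got, ] <- cand
    }
  }
  while (got < n) {  # fall back to unconstrained placement; counts are exact
    got <- got + 1L
    accepted[got, ] <- (arrayInd(sample(idx_pool, 1L), d) - 0.5) * voxel_size_um
  }
  accepted
}

render_spot_channel <- function(positions_um, d, voxel_size_um, sigma_um,
                                amplitude) {
  impulses <- array(0, d)
  if (nrow(positions_um) > 0) {
    vox <- cbind(pmin(pmax(round(positions_um[, 1] / voxel_size_um[1] + 0.5), 1), d[1]),
                 pmin(pmax(round(positions_um[, 2] / voxel_size_um[2] + 0.5), 1), d[2]),
                 pmin(pmax(round(positions_um[, 3] / voxel_size_um[3] + 0.5), 1), d[3]))
    for (i in seq_len(nrow(vox))) {
      impulses[vox[i, 1], vox[i, 2], vox[i, 3]] <-
        impulses[vox[i, 1], vox[i, 2], vox[i, 3]] + 1
    }
  }
  sigma_vox <- sigma_um / voxel_size_um
  sm <- gauss_smooth3(impulses, sigma_vox)
  # normalised kernels have central weight ~ 1/(sqrt(2*pi)*sigma) per axis;
  # rescale so an isolated spot peaks at `amplitude`
  peak <- prod(pmin(1, 1 / (sqrt(2 * pi) * sigma_vox)))
  sm * (amplitude / peak)
}

#' Simulate a disc phantom with ground truth
#'
#' Generates a confocal-like multi-channel stack of a two-lobed disc: a DAPI
#' channel with nuclear-scale texture over the tissue, a GFP channel
#' supported on clone blobs occupying the target fraction of tissue voxels,
#' and a pH3 channel of Gaussian spots whose per-compartment counts are
#' Poisson with mean density x compartment volume (in mm^3). Channels are
#' blurred by a small optical PSF and degraded with Poisson shot noise plus
#' Gaussian read noise set by `snr`. The returned ground truth carries the
#' exact masks, clone labels, clone fraction and spot positions.
#'
#' @param params a [disc_phantom_params()] object.
#' @param seed integer seed; identical `(params, seed)` give bit-identical
#'   output and the caller's RNG stream is left untouched.
#' @return A list with components `stack` ([image_stack]) and `truth`
#'   (class `disc_ground_truth`: `tissue_mask`, `clone_mask`, `clone_labels`,
#'   `true_fraction`, `ph3_true` data frame with positions in microns and the
#'   `compartment` flag).
#' @examples
#' ph <- simulate_disc(make_condition_preset("ph505"), seed = 1)
#' ph$truth$true_fraction
#' @export
simulate_disc <- function(params, seed) {
  if (!inherits(params, "disc_phantom_params")) {
    stop("`params` must be a disc_phantom_params object", call. = FALSE)
  }
  with_seed(seed, {
    d <- params$shape_voxels
    vs <- params$voxel_size_um
    vv <- voxel_volume_um3(vs)
    tissue <- render_tissue_mask(d, vs)
    clone <- render_clone_mask(tissue, params)
    stopifnot(!any(clone & !tissue))
    true_fraction <- if (sum(tissue) == 0L) 0 else sum(clone) / sum(tissue)
    labels <- label_clones(clone)

    clone_vol_mm3 <- sum(clone) * vv / 1e9
    outside_vol_mm3 <- (sum(tissue) - sum(clone)) * vv / 1e9
    n_in <- stats::rpois(1, params$ph3_density_inside_per_mm3 * clone_vol_mm3)
    n_out <- stats::rpois(1, params$ph3_density_outside_per_mm3 * outside_vol_mm3)
    min_sep <- 2 * params$nuclear_radius_um
    pos_in <- place_spots(clone, n_in, vs, min_sep)
    pos_out <- place_spots(tissue & !clone, n_out, vs, min_sep,
                           existing = pos_in)
    ph3_true <- data.frame(
      z_um = c(pos_in[, 1], pos_out[, 1]),
      y_um = c(pos_in[, 2], pos_out[, 2]),
      x_um = c(pos_in[, 3], pos_out[, 3]),
      compartment = rep(c("inside", "outside"), c(nrow(pos_in), nrow(pos_out))),
      stringsAsFactors = FALSE)

    optic_sigma_vox <- 0.5 / vs            # 0.5 um PSF
    texture <- gauss_smooth3(array(stats::rnorm(prod(d)), d), 1 / vs)
    texture <- pmax(0.25, 1 + 0.3 * texture / stats::sd(texture))
    dapi <- gauss_smooth3((tissue * 100) * texture, optic_sigma_vox)
    gfp <- gauss_smooth3(clone * 120, optic_sigma_vox)
    spot_sigma_um <- params$nuclear_radius_um / sqrt(3)
    ph3 <- render_spot_channel(ph3_true[, c("z_um", "y_um", "x_um")] |>
                                 as.matrix(), d, vs, spot_sigma_um, 150)
    channels <- lapply(list(DAPI = dapi, GFP = gfp, pH3 = ph3), function(ch) {
      add_acquisition_noise(ch + params$background_level, params$snr)
    })
    list(stack = image_stack(channels, vs),
         truth = structure(
           list(tissue_mask = tissue, clone_mask = clone,
                clone_labels = labels, true_fraction = true_fraction,
                ph3_true = ph3_true),
           class = "disc_ground_truth"))
  })
}

#' @export
print.disc_ground_truth <- function(x, ...) {
  cat(sprintf(
    "disc_ground_truth: %d tissue voxels, %d clone voxels (fraction %.3f), %d pH3 spots\n",
    sum(x$tissue_mask), sum(x$clone_mask), x$true_fraction, nrow(x$ph3_true)))
  invisible(x)
}

#' Training label volume from phantom ground truth
#'
#' Converts a phantom's ground truth into the label convention used by
#' [train_voxel_classifier()]: 1 = clone, 2 = not-clone, 0 = unlabelled.
#' All non-clone voxels (tissue and background) are labelled not-clone.
#'
#' @param truth a `disc_ground_truth` object.
#' @return Integer label array.
#' @export
phantom_labels <- function(truth) {
  lab <- array(2L, dim(truth$clone_mask))
  lab[truth$clone_mask] <- 1L
  lab
}
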