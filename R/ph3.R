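#' Detect pH3+ mitotic spots
#'
#' Single-scale Laplacian-of-Gaussian blob detection tuned to a nuclear
#' radius: the channel is smoothed at `sigma = radius / sqrt(3)` (the scale
#' at which the 3D LoG response of a ball of that radius peaks), the
#' negative Laplacian is taken, and 26-neighbourhood local maxima are kept
#' when they exceed a robust noise threshold (`noise_k` times the MAD of the
#' response). Maxima closer than one radius (in microns) are merged keeping
#' the stronger one, and spots whose centroid voxel lies outside the tissue
#' mask are discarded.
#'
#' @param stack an [image_stack].
#' @param ph3_channel channel holding the mitosis marker.
#' @param tissue_mask logical volume restricting detections.
#' @param nuclear_radius_um expected nuclear radius in microns (> 0).
#' @param noise_k multiple of the response MAD used as detection threshold.
#' @return Data frame with voxel indices (`z`, `y`, `x`), physical
#'   coordinates (`z_um`, `y_um`, `x_um`) and `response`, ordered by
#'   decreasing response.
#' @export
detect_ph3_spots <- function(stack, ph3_channel = "pH3", tissue_mask,
                             nuclear_radius_um = 2.5, noise_k = 6) {
  if (!is.finite(nuclear_radius_um) || nuclear_radius_um <= 0) {
    stop("`nuclear_radius_um` must be > 0", call. = FALSE)
  }
  vol <- get_channel(stack, ph3_channel)
  check_volume(tissue_mask)
  vs <- stack$voxel_size_um
  sigma_um <- nuclear_radius_um / sqrt(3)
  sm <- gauss_smooth3(vol, sigma_um / vs)
  resp <- -laplacian3(sm, vs)
  thr <- noise_k * stats::mad(resp, center = 0)
  is_max <- resp >= boxmax3(resp) & resp > thr & resp > 0
  idx <- which(is_max)
  empty <- data.frame(z = integer(0), y = integer(0), x = integer(0),
                      z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      response = numeric(0))
  if (length(idx) == 0L) return(empty)
  coords <- arrayInd(idx, dim(vol))
  pos_um <- sweep(coords - 0.5, 2, vs, `*`)
  r <- resp[idx]
  ord <- order(r, decreasing = TRUE)
  coords <- coords[ord, , drop = FALSE]
  pos_um <- pos_um[ord, , drop = FALSE]
  r <- r[ord]
  # greedy non-maximum suppression at one nuclear radius
  keep <- logical(length(r))
  for (i in seq_along(r)) {
    if (i == 1L || !any(keep)) {
      keep[i] <- TRUE
    } else {
      dmin <- min(sqrt(colSums((t(pos_um[keep, , drop = FALSE]) -
                                  pos_um[i, ])^2)))
      keep[i] <- dmin >= nuclear_radius_um
    }
  }
  coords <- coords[keep, , drop = FALSE]
  pos_um <- pos_um[keep, , drop = FALSE]
  r <- r[keep]
  inside_tissue <- tissue_mask[coords]
  data.frame(z = coords[inside_tissue, 1], y = coords[inside_tissue, 2],
             x = coords[inside_tissue, 3],
             z_um = pos_um[inside_tissue, 1], y_um = pos_um[inside_tissue, 2],
             x_um = pos_um[inside_tissue, 3],
             response = r[inside_tissue])
}

#' Partition pH3 spots inside/outside GFP+ clones
#'
#' A spot is "inside" iff its centroid voxel lies in the clone mask, the
#' spot-level analogue of masking pH3 voxels by the segmented GFP signal.
#'
#' @param spots data frame with voxel columns `z`, `y`, `x` (e.g. from
#'   [detect_ph3_spots()]).
#' @param clone_mask,tissue_mask logical volumes sharing the stack geometry.
#' @return Object of class `ph3_partition`: `n_whole`, `n_inside`,
#'   `n_outside` and the `spots` table with a `compartment` column.
#'   `n_inside + n_outside == n_whole` always.
#' @export
partition_ph3 <- function(spots, clone_mask, tissue_mask) {
  check_volume(clone_mask)
  check_volume(tissue_mask)
  if (!identical(dim(clone_mask), dim(tissue_mask))) {
    stop("masks must share the same geometry", call. = FALSE)
  }
  d <- dim(clone_mask)
  n <- nrow(spots)
  if (n > 0) {
    vox <- as.matrix(spots[, c("z", "y", "x")])
    if (any(vox < 1L) || any(sweep(vox, 2, d, `>`))) {
      stop("spot centroid outside the volume bounds", call. = FALSE)
    }
    inside <- clone_mask[vox]
  } else {
    inside <- logical(0)
  }
  spots$compartment <- ifelse(inside, "inside", "outside")
  structure(list(n_whole = n, n_inside = sum(inside),
                 n_outside = sum(!inside), spots = spots),
            class = "ph3_partition")
}

#' @export
print.ph3_partition <- function(x, ...) {
  cat(sprintf("ph3_partition: %d spots (%d inside clones, %d outside)\n",
              x$n_whole, x$n_inside, x$n_outside))
  invisible(x)
}

#' pH3 densities per cubic millimetre
#'
#' Normalises the partitioned counts the way the study reports them:
#' whole-tissue count over total tissue volume, inside count over the GFP+
#' clone volume, outside count over the GFP- tissue volume, all per mm^3
#' (1 mm^3 = 1e9 um^3). When the clone volume is zero the inside density is
#' undefined and reported as `NA`.
#'
#' @param part a [partition_ph3()] result.
#' @param tissue_volume_um3 total tissue volume (> clone volume).
#' @param clone_volume_um3 total GFP+ clone volume (>= 0).
#' @return Named numeric vector `c(whole, inside, outside)` in spots/mm^3.
#' @examples
#' p <- structure(list(n_whole = 2, n_inside = 0, n_outside = 2),
#'                class = "ph3_partition")
#' ph3_densities(p, 1e6, 0)  # whole = outside = 2000, inside = NA
#' @export
ph3_densities <- function(part, tissue_volume_um3, clone_volume_um3) {
  if (clone_volume_um3 < 0 || tissue_volume_um3 <= clone_volume_um3) {
    stop("need tissue volume > clone volume >= 0", call. = FALSE)
  }
  to_mm3 <- 1e9
  c(whole = part$n_whole / (tissue_volume_um3 / to_mm3),
    inside = if (clone_volume_um3 > 0) {
      part$n_inside / (clone_volume_um3 / to_mm3)
    } else NA_real_,
    outside = part$n_outside / ((tissue_volume_um3 - clone_volume_um3) / to_mm3))
}
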