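#' Per-voxel features for supervised clone classification
#'
#' Computes, for one channel of a stack, the feature set used by the voxel
#' classifier: the raw intensity and, for every smoothing scale, the
#' Gaussian-smoothed intensity, its gradient magnitude and its Laplacian.
#' Scales are physical (microns) and converted per axis to anisotropic voxel
#' sigmas (`scale_um / voxel_size_um[axis]`), so features are comparable
#' across stacks with different voxel sizes. Feature order is stable:
#' `raw`, then `smooth_<s>`, `grad_<s>`, `log_<s>` per scale in the given
#' order.
#'
#' @param stack an [image_stack].
#' @param channel channel name to featurise (typically `"GFP"`).
#' @param scales_um positive smoothing scales in microns; at least one.
#' @return An object of class `voxel_features`: list with `features`
#'   (matrix, one row per voxel in column-major order), `feature_names`,
#'   `dim`, `voxel_size_um`, `channel`, `scales_um`.
#' @export
compute_voxel_features <- function(stack, channel, scales_um = c(1, 3)) {
  vol <- get_channel(stack, channel)
  if (length(scales_um) < 1L || any(scales_um <= 0)) {
    stop("`scales_um` must be positive", call. = FALSE)
  }
  vs <- stack$voxel_size_um
  cols <- list(raw = as.numeric(vol))
  for (s in scales_um) {
    sm <- gauss_smooth3(vol, s / vs)
    cols[[sprintf("smooth_%g", s)]] <- as.numeric(sm)
    cols[[sprintf("grad_%g", s)]] <- as.numeric(gradient_magnitude3(sm, vs))
    cols[[sprintf("log_%g", s)]] <- as.numeric(laplacian3(sm, vs))
  }
  features <- do.call(cbind, cols)
  structure(
    list(features = features, feature_names = colnames(features),
         dim = dim(vol), voxel_size_um = vs, channel = channel,
         scales_um = scales_um),
    class = "voxel_features")
}

#' @export
print.voxel_features <- function(x, ...) {
  cat(sprintf("voxel_features: %d voxels x %d features (%s), channel %s\n",
              nrow(x$features), ncol(x$features),
              paste(x$feature_names, collapse = ", "), x$channel))
  invisible(x)
}
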