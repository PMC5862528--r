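#' DAPI-based tissue mask
#'
#' Segments the whole tissue from the DAPI channel: Gaussian smoothing at a
#' physical scale, a global Otsu threshold, boundary regularisation
#' (majority vote via Gaussian smoothing of the binary mask), filling of
#' interior holes (background components not connected to the stack border),
#' and removal of components below a size floor. Disjoint lobes above the
#' floor are all retained.
#'
#' @param stack an [image_stack].
#' @param dapi_channel channel name holding the nuclear stain.
#' @param smooth_um smoothing scale in microns before thresholding; kept
#'   sub-voxel by default so nuclear-scale texture is averaged without
#'   flattening the tissue edge.
#' @param regularize_um scale of the binary boundary regularisation; 0
#'   disables it.
#' @param min_size_um3 size floor; smaller components are dropped.
#' @return Logical 3D array.
#' @export
compute_tissue_mask <- function(stack, dapi_channel = "DAPI",
                                smooth_um = 0.4, regularize_um = 0.6,
                                min_size_um3 = 500) {
  vol <- get_channel(stack, dapi_channel)
  vs <- stack$voxel_size_um
  sm <- gauss_smooth3(vol, smooth_um / vs)
  thr <- otsu_threshold(as.numeric(sm))
  mask <- sm > thr
  if (regularize_um > 0) {
    mask <- gauss_smooth3(mask + 0, regularize_um / vs) >= 0.5
  }
  mask <- fill_holes3(mask)
  drop_small_components(mask, min_size_um3, vs)
}

# Fill interior holes: background voxels not 6-connected to the border.
fill_holes3 <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- label_components6(bg)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0L]
  outside <- array(lab %in% border_labels, d)
  mask | (bg & !outside)
}

# 6-connectivity labelling (for hole filling only).
label_components6 <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  out <- array(0L, d)
  if (length(fg) == 0L) return(out)
  vox_id <- array(0L, d)
  vox_id[fg] <- seq_along(fg)
  edges <- list()
  for (axis in 1:3) {
    n <- d[axis]
    idx_a <- switch(axis, vox_id[-n, , , drop = FALSE],
                    vox_id[, -n, , drop = FALSE], vox_id[, , -n, drop = FALSE])
    idx_b <- switch(axis, vox_id[-1, , , drop = FALSE],
                    vox_id[, -1, , drop = FALSE], vox_id[, , -1, drop = FALSE])
    keep <- idx_a > 0L & idx_b > 0L
    if (any(keep)) edges[[axis]] <- cbind(idx_a[keep], idx_b[keep])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    comp <- seq_along(fg)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  out[fg] <- as.integer(comp)
  out
}

drop_small_components <- function(mask, min_size_um3, voxel_size_um) {
  if (min_size_um3 <= 0 || !any(mask)) return(mask)
  lab <- label_clones(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * voxel_volume_um3(voxel_size_um) >= min_size_um3)
  array(lab %in% keep, dim(mask))
}

#' Predict the clone mask for a stack
#'
#' Applies a trained [voxel classifier][train_voxel_classifier] to a stack:
#' the clone mask is the set of voxels with clone probability at or above
#' `threshold`, intersected with the DAPI tissue mask, with connected
#' objects smaller than `min_size_um3` removed. The probability volume is
#' retained for audit.
#'
#' @param stack an [image_stack] with the classifier's channel and a DAPI
#'   channel.
#' @param clf a `voxel_classifier`.
#' @param threshold probability cutoff in (0, 1).
#' @param min_size_um3 minimum physical object size kept, in cubic microns.
#' @param tissue_mask optional precomputed logical tissue mask; when `NULL`
#'   it is derived with [compute_tissue_mask()].
#' @param dapi_channel channel used for the tissue mask.
#' @return Object of class `segmentation_masks`: list with `tissue_mask`,
#'   `clone_mask` and `clone_probability`.
#' @export
predict_clone_mask <- function(stack, clf, threshold = 0.5,
                               min_size_um3 = 50, tissue_mask = NULL,
                               dapi_channel = "DAPI") {
  if (!inherits(clf, "voxel_classifier")) {
    stop("`clf` must be a voxel_classifier", call. = FALSE)
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  }
  if (min_size_um3 < 0) stop("`min_size_um3` must be >= 0", call. = FALSE)
  prob <- predict(clf, stack)
  if (is.null(tissue_mask)) {
    tissue_mask <- compute_tissue_mask(stack, dapi_channel)
  }
  mask <- (prob >= threshold) & tissue_mask
  mask <- drop_small_components(mask, min_size_um3, stack$voxel_size_um)
  structure(list(tissue_mask = tissue_mask, clone_mask = mask,
                 clone_probability = prob),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  cat(sprintf("segmentation_masks: %d tissue voxels, %d clone voxels\n",
              sum(x$tissue_mask), sum(x$clone_mask)))
  invisible(x)
}
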