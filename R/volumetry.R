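#' Label spatially distinct clones in 3D
#'
#' Connected-component labelling of a boolean clone mask under 26-connectivity
#' (voxels sharing a face, edge or corner belong to the same clone). Labels
#' are 1..K in order of first voxel occurrence (column-major), background 0.
#'
#' @param clone_mask logical 3D array.
#' @return Integer array of the same shape; 0 = background.
#' @export
label_clones <- function(clone_mask) {
  check_volume(clone_mask)
  d <- dim(clone_mask)
  fg <- which(clone_mask)
  out <- array(0L, d)
  if (length(fg) == 0L) return(out)
  # map voxel linear index -> 1..M over foreground voxels
  vox_id <- array(0L, d)
  vox_id[fg] <- seq_along(fg)
  offsets <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offsets <- offsets[offsets$dz != 0 | offsets$dy != 0 | offsets$dx != 0, ]
  # keep lexicographically positive half of the 26-neighbourhood
  offsets <- offsets[offsets$dx > 0 | (offsets$dx == 0 & offsets$dy > 0) |
                       (offsets$dx == 0 & offsets$dy == 0 & offsets$dz > 0), ]
  edges <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    o <- as.integer(offsets[k, ])
    zi <- seq(max(1L, 1L - o[1]), min(d[1], d[1] - o[1]))
    yi <- seq(max(1L, 1L - o[2]), min(d[2], d[2] - o[2]))
    xi <- seq(max(1L, 1L - o[3]), min(d[3], d[3] - o[3]))
    a <- vox_id[zi, yi, xi, drop = FALSE]
    b <- vox_id[zi + o[1], yi + o[2], xi + o[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[k]] <- cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    comp <- seq_along(fg)  # isolated voxels only
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  # relabel so clone ids follow first-occurrence order
  first <- match(unique(comp), comp)
  relab <- integer(max(comp))
  relab[comp[sort(first)]] <- seq_along(first)
  out[fg] <- relab[comp]
  out
}

#' Per-clone volume table
#'
#' Converts a labelled clone volume into a table of voxel counts, physical
#' volumes and centroids. Volume is voxel count times the voxel volume
#' (product of the three axis sizes); centroids are in microns.
#'
#' @param labels non-negative integer 3D array from [label_clones()].
#' @param voxel_size_um numeric length-3 voxel size (z, y, x) in microns.
#' @return A data frame with columns `clone_id`, `voxel_count`, `volume_um3`,
#'   `centroid_z_um`, `centroid_y_um`, `centroid_x_um`.
#' @export
clone_table <- function(labels, voxel_size_um) {
  check_volume(labels)
  voxel_size_um <- check_voxel_size(voxel_size_um)
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  idx <- which(labels > 0)
  if (length(idx) == 0L) {
    return(data.frame(clone_id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), centroid_z_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_x_um = numeric(0)))
  }
  l <- as.integer(labels[idx])
  ids <- sort(unique(l))
  if (!identical(ids, seq_along(ids))) {
    warning("non-contiguous label ids; relabelling 1..K")
    l <- match(l, ids)
    ids <- seq_along(ids)
  }
  coords <- arrayInd(idx, dim(labels))
  cnt <- tabulate(l, nbins = length(ids))
  cent <- sapply(1:3, function(a) {
    rowsum((coords[, a] - 0.5) * voxel_size_um[a], l)[, 1] / cnt
  })
  cent <- matrix(cent, ncol = 3)
  data.frame(clone_id = ids, voxel_count = cnt,
             volume_um3 = cnt * voxel_volume_um3(voxel_size_um),
             centroid_z_um = cent[, 1], centroid_y_um = cent[, 2],
             centroid_x_um = cent[, 3])
}

#' Tumor-volume percent
#'
#' The study's per-disc measure: 100 x (summed volume of all GFP+ clones) /
#' (DAPI-defined tissue volume).
#'
#' @param clones a [clone_table()] data frame (or anything with a
#'   `volume_um3` column).
#' @param tissue_volume_um3 positive tissue volume in cubic microns.
#' @return Percentage in `[0, 100]` when clones are nested in the tissue.
#' @examples
#' tumor_volume_percent(data.frame(volume_um3 = 64), 512)  # 12.5
#' @export
tumor_volume_percent <- function(clones, tissue_volume_um3) {
  if (!is.finite(tissue_volume_um3) || tissue_volume_um3 <= 0) {
    stop("`tissue_volume_um3` must be > 0", call. = FALSE)
  }
  100 * sum(clones$volume_um3) / tissue_volume_um3
}
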