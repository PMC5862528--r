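# On-disk formats: multi-page TIFF per channel plus a JSON manifest carrying
# voxel size, channel names and intensity scale; TSV for tables.

#' Write an image stack to disk
#'
#' One multi-page TIFF per channel (pages = z planes, 32-bit float scaled to
#' `[0, 1]`) plus `<prefix>_manifest.json` with channel names, per-channel
#' intensity scales, dimensions and voxel size in microns.
#'
#' @param stack an [image_stack].
#' @param prefix output path prefix; files are `<prefix>_<channel>.tif`.
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  d <- dim(stack$channels[[1]])
  offsets <- vapply(stack$channels, min, numeric(1))
  scales <- vapply(stack$channels, function(ch) {
    max(1e-12, max(ch) - min(ch))
  }, numeric(1))
  for (nm in names(stack$channels)) {
    pages <- lapply(seq_len(d[1]), function(z) {
      (stack$channels[[nm]][z, , ] - offsets[[nm]]) / scales[[nm]]
    })
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, nm),
                    bits.per.sample = 32L)
  }
  manifest <- list(channels = names(stack$channels),
                   intensity_scale = as.list(scales),
                   intensity_offset = as.list(offsets),
                   shape_voxels = d,
                   voxel_size_um = unname(stack$voxel_size_um))
  path <- sprintf("%s_manifest.json", prefix)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param prefix the path prefix used when writing.
#' @return An [image_stack].
#' @export
read_stack <- function(prefix) {
  manifest <- jsonlite::read_json(sprintf("%s_manifest.json", prefix),
                                  simplifyVector = TRUE)
  d <- as.integer(manifest$shape_voxels)
  channels <- lapply(manifest$channels, function(nm) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, nm), all = TRUE)
    vol <- array(0, d)
    for (z in seq_len(d[1])) vol[z, , ] <- pages[[z]]
    vol * manifest$intensity_scale[[nm]] + manifest$intensity_offset[[nm]]
  })
  names(channels) <- manifest$channels
  image_stack(channels, as.numeric(manifest$voxel_size_um))
}

#' Write a boolean or label mask as single-channel TIFF
#'
#' Labels are stored as 16-bit integers scaled by the maximum label; the
#' convention for classifier label volumes is 0 = unlabelled, 1 = clone,
#' 2 = not-clone.
#'
#' @param mask logical or integer 3D array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  check_volume(mask)
  m <- max(1L, max(as.integer(mask)))
  d <- dim(mask)
  pages <- lapply(seq_len(d[1]), function(z) {
    matrix(as.integer(mask[z, , ]) / m, d[2], d[3])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  attr(path, "scale") <- m
  invisible(path)
}

#' Read a mask written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @param max_label the label scale used when writing (1 for boolean masks).
#' @return Integer 3D array.
#' @export
read_mask_tiff <- function(path, max_label = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(length(pages), dim(pages[[1]]))
  vol <- array(0L, d)
  for (z in seq_len(d[1])) {
    vol[z, , ] <- as.integer(round(pages[[z]] * max_label))
  }
  vol
}

#' Write phantom ground truth (masks as TIFF, scalars as JSON)
#'
#' @param truth a `disc_ground_truth` from [simulate_disc()].
#' @param prefix output path prefix.
#' @return The JSON sidecar path, invisibly.
#' @export
write_ground_truth <- function(truth, prefix) {
  write_mask_tiff(truth$tissue_mask, sprintf("%s_tissue.tif", prefix))
  write_mask_tiff(truth$clone_mask, sprintf("%s_clones.tif", prefix))
  write_mask_tiff(truth$clone_labels, sprintf("%s_labels.tif", prefix))
  side <- list(true_fraction = truth$true_fraction,
               max_label = max(1L, max(truth$clone_labels)),
               n_ph3_spots = nrow(truth$ph3_true),
               ph3_true = truth$ph3_true)
  path <- sprintf("%s_truth.json", prefix)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write / read a count matrix with gene ids as the first column
#'
#' @param counts matrix, genes x samples, with row and column names.
#' @param path TSV path.
#' @return `path` invisibly (writer); integer matrix (reader).
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Append per-disc measurements to a TSV
#'
#' One row per disc: identifiers, volumes, tumor-volume percent, clone
#' count and pH3 counts/densities. Creates the file with a header when it
#' does not exist.
#'
#' @param measurement a [measure_disc()] result.
#' @param disc_id,condition identifiers recorded with the row.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
append_measurement_tsv <- function(measurement, disc_id, condition, path) {
  row <- cbind(data.frame(disc_id = disc_id, condition = condition,
                          stringsAsFactors = FALSE),
               as.data.frame(measurement))
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
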