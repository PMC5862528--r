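#' Quantify one disc
#'
#' Orchestrates the full per-disc pipeline: DAPI tissue mask, clone
#' probability and mask from the trained voxel classifier, 26-connectivity
#' clone labelling, per-clone volumetry, tumor-volume percent, and (when a
#' pH3 channel is present or requested) spot detection, inside/outside
#' partition and per-mm^3 densities. Deterministic given the classifier and
#' configuration.
#'
#' @param stack an [image_stack] with DAPI and GFP channels (pH3 optional).
#' @param clf a trained [voxel classifier][train_voxel_classifier].
#' @param config list of settings: `threshold` (probability cutoff, 0.5),
#'   `min_size_um3` (clone size floor, 50), `dapi_channel` ("DAPI"),
#'   `ph3_channel` ("pH3" when present, else skipped),
#'   `nuclear_radius_um` (2.5).
#' @return Object of class `disc_measurement` with fields
#'   `tissue_volume_um3`, `total_clone_volume_um3`, `tumor_volume_percent`,
#'   `n_clones`, `clones` (the [clone_table()]), `masks`
#'   (`segmentation_masks`), and when pH3 was quantified `ph3`
#'   (`ph3_partition`) and `ph3_density_per_mm3` (whole/inside/outside;
#'   inside is `NA` for clone-free discs).
#' @examples
#' \donttest{
#' ph <- simulate_disc(make_condition_preset("ph505"), seed = 1)
#' tr <- lapply(101:105, function(s) {
#'   sim <- simulate_disc(make_condition_preset("ph505"), seed = s)
#'   list(features = compute_voxel_features(sim$stack, "GFP"),
#'        labels = phantom_labels(sim$truth))
#' })
#' clf <- train_voxel_classifier(tr, seed = 0)
#' measure_disc(ph$stack, clf)
#' }
#' @export
measure_disc <- function(stack, clf, config = list()) {
  cfg <- utils::modifyList(
    list(threshold = 0.5, min_size_um3 = 50, dapi_channel = "DAPI",
         ph3_channel = if ("pH3" %in% names(stack$channels)) "pH3" else NULL,
         nuclear_radius_um = 2.5),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  masks <- stage("segmentation", predict_clone_mask(
    stack, clf, threshold = cfg$threshold, min_size_um3 = cfg$min_size_um3,
    dapi_channel = cfg$dapi_channel))
  vs <- stack$voxel_size_um
  vv <- voxel_volume_um3(vs)
  tissue_volume <- sum(masks$tissue_mask) * vv
  labels <- stage("labelling", label_clones(masks$clone_mask))
  clones <- stage("volumetry", clone_table(labels, vs))
  clone_volume <- sum(clones$volume_um3)
  pct <- stage("tumor_percent", tumor_volume_percent(clones, tissue_volume))
  out <- list(tissue_volume_um3 = tissue_volume,
              total_clone_volume_um3 = clone_volume,
              tumor_volume_percent = pct,
              n_clones = nrow(clones),
              clones = clones,
              masks = masks)
  if (!is.null(cfg$ph3_channel)) {
    spots <- stage("ph3_detection", detect_ph3_spots(
      stack, cfg$ph3_channel, masks$tissue_mask,
      nuclear_radius_um = cfg$nuclear_radius_um))
    part <- stage("ph3_partition",
                  partition_ph3(spots, masks$clone_mask, masks$tissue_mask))
    out$ph3 <- part
    out$ph3_density_per_mm3 <- stage("ph3_densities",
                                     ph3_densities(part, tissue_volume,
                                                   clone_volume))
  }
  structure(out, class = "disc_measurement")
}

#' @export
print.disc_measurement <- function(x, ...) {
  cat(sprintf(paste0(
    "disc_measurement\n",
    "  tissue volume : %.0f um^3\n",
    "  clone volume  : %.0f um^3 over %d clone(s)\n",
    "  tumor volume  : %.1f %%\n"),
    x$tissue_volume_um3, x$total_clone_volume_um3, x$n_clones,
    x$tumor_volume_percent))
  if (!is.null(x$ph3)) {
    dens <- x$ph3_density_per_mm3
    cat(sprintf(
      "  pH3 spots     : %d (inside %d / outside %d); per mm^3 whole %.0f, inside %s, outside %.0f\n",
      x$ph3$n_whole, x$ph3$n_inside, x$ph3$n_outside, dens[["whole"]],
      if (is.na(dens[["inside"]])) "NA" else sprintf("%.0f", dens[["inside"]]),
      dens[["outside"]]))
  }
  invisible(x)
}

#' @export
as.data.frame.disc_measurement <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  dens <- x$ph3_density_per_mm3 %||% c(whole = NA_real_, inside = NA_real_,
                                       outside = NA_real_)
  data.frame(tissue_volume_um3 = x$tissue_volume_um3,
             total_clone_volume_um3 = x$total_clone_volume_um3,
             tumor_volume_percent = x$tumor_volume_percent,
             n_clones = x$n_clones,
             ph3_whole = if (is.null(x$ph3)) NA_integer_ else x$ph3$n_whole,
             ph3_inside = if (is.null(x$ph3)) NA_integer_ else x$ph3$n_inside,
             ph3_outside = if (is.null(x$ph3)) NA_integer_ else x$ph3$n_outside,
             ph3_density_whole = dens[["whole"]],
             ph3_density_inside = dens[["inside"]],
             ph3_density_outside = dens[["outside"]],
             row.names = row.names)
}
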