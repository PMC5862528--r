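#' Train the voxel classifier for clone segmentation
#'
#' Fits a random-forest voxel classifier mapping [compute_voxel_features()]
#' vectors to the probability of the "clone" class, emulating a supervised
#' pixel-classification workflow trained on a handful of annotated discs.
#' Only labelled voxels are used (label 1 = clone, 2 = not-clone,
#' 0 = unlabelled); labelled voxels are subsampled per class to
#' `max_per_class` with the given seed, an 80/20 split is held out, and the
#' reported held-out accuracy is stored in the training metadata.
#'
#' @param training list of `list(features = voxel_features, labels = array)`
#'   pairs, one per training disc.
#' @param seed integer seed controlling subsampling and the forest.
#' @param max_per_class cap on training voxels per class after pooling discs.
#' @param num_trees number of trees.
#' @return Object of class `voxel_classifier` with elements `forest`
#'   (a ranger probability forest), `feature_names`, `channel`, `scales_um`
#'   and `metadata` (n discs, n labelled voxels used, held-out accuracy,
#'   seed).
#' @seealso [predict_clone_mask()]
#' @export
train_voxel_classifier <- function(training, seed = 0,
                                   max_per_class = 20000L,
                                   num_trees = 100L) {
  if (!is.list(training) || length(training) < 1L) {
    stop("`training` must be a non-empty list of (features, labels) pairs",
         call. = FALSE)
  }
  xs <- list(); ys <- list()
  for (tr in training) {
    fs <- tr$features
    if (!inherits(fs, "voxel_features")) {
      stop("each training element needs a `features` voxel_features object",
           call. = FALSE)
    }
    lab <- as.integer(tr$labels)
    if (length(lab) != nrow(fs$features)) {
      stop("label volume and feature set disagree in voxel count", call. = FALSE)
    }
    keep <- lab %in% c(1L, 2L)
    xs[[length(xs) + 1L]] <- fs$features[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- lab[keep]
  }
  x <- do.call(rbind, xs)
  y <- do.call(c, ys)
  if (length(unique(y)) < 2L) {
    stop("training labels must contain both the clone and the not-clone class",
         call. = FALSE)
  }
  ref <- training[[1]]$features
  with_seed(seed, {
    sel <- unlist(lapply(split(seq_along(y), y), function(i) {
      if (length(i) > max_per_class) sample(i, max_per_class) else i
    }), use.names = FALSE)
    x <- x[sel, , drop = FALSE]
    y <- y[sel]
    n <- length(y)
    holdout <- sample(n, max(1L, round(0.2 * n)))
    train_df <- data.frame(x[-holdout, , drop = FALSE],
                           class = factor(y[-holdout], levels = c(1L, 2L),
                                          labels = c("clone", "not_clone")))
    forest <- ranger::ranger(class ~ ., data = train_df, probability = TRUE,
                             num.trees = num_trees, seed = seed,
                             num.threads = 1L)
    pred <- ranger::predictions(
      predict(forest, data.frame(x[holdout, , drop = FALSE]),
              num.threads = 1L))
    acc <- mean((pred[, "clone"] >= 0.5) == (y[holdout] == 1L))
    structure(
      list(forest = forest,
           feature_names = ref$feature_names,
           channel = ref$channel,
           scales_um = ref$scales_um,
           metadata = list(n_discs = length(training),
                           n_voxels_used = n,
                           holdout_accuracy = acc,
                           seed = seed)),
      class = "voxel_classifier")
  })
}

#' @export
print.voxel_classifier <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(paste0(
    "voxel_classifier: random forest on channel %s (features: %s)\n",
    "trained on %d disc(s), %d labelled voxels; held-out accuracy %.3f\n"),
    x$channel, paste(x$feature_names, collapse = ", "),
    m$n_discs, m$n_voxels_used, m$holdout_accuracy))
  invisible(x)
}

#' Clone-probability volume for a stack
#'
#' @param object a `voxel_classifier`.
#' @param stack an [image_stack]; features are recomputed with the
#'   classifier's channel and scales.
#' @param ... unused.
#' @return 3D array of clone probabilities in `[0, 1]`.
#' @export
predict.voxel_classifier <- function(object, stack, ...) {
  fs <- compute_voxel_features(stack, object$channel, object$scales_um)
  if (!identical(fs$feature_names, object$feature_names)) {
    stop("feature set does not match the classifier's training features",
         call. = FALSE)
  }
  p <- ranger::predictions(
    predict(object$forest, data.frame(fs$features), num.threads = 1L))
  array(p[, "clone"], fs$dim)
}
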