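two_level_stack <- function(seed = 1, d = c(16, 24, 32), noise_sd = 0) {
  # crisp two-intensity phantom: bright box (clone) inside dim tissue
  set.seed(seed)
  gfp <- array(0, d)
  gfp[5:12, 6:18, 8:24] <- 100
  dapi <- array(0, d)
  dapi[2:15, 2:22, 2:30] <- 80
  if (noise_sd > 0) {
    gfp <- gfp + array(rnorm(prod(d), sd = noise_sd), d)
    dapi <- dapi + array(rnorm(prod(d), sd = noise_sd), d)
  }
  image_stack(list(DAPI = dapi, GFP = gfp), c(1, 0.5, 0.5))
}

train_on_stack <- function(stack, clone_truth, seed = 0) {
  lab <- array(2L, dim(stack$channels$GFP))
  lab[clone_truth] <- 1L
  train_voxel_classifier(
    list(list(features = compute_voxel_features(stack, "GFP"), labels = lab)),
    seed = seed)
}

test_that("linearly separable training data gives perfect held-out accuracy", {
  stack <- two_level_stack()
  truth <- stack$channels$GFP > 50
  clf <- train_on_stack(stack, truth)
  expect_equal(clf$metadata$holdout_accuracy, 1.0)
})

test_that("randomly shuffled labels give chance-level held-out accuracy", {
  stack <- two_level_stack(noise_sd = 5)
  accs <- vapply(1:3, function(s) {
    set.seed(s)
    lab <- array(sample(c(1L, 2L), length(stack$channels$GFP),
                        replace = TRUE, prob = c(0.3, 0.7)),
                 dim(stack$channels$GFP))
    clf <- train_voxel_classifier(
      list(list(features = compute_voxel_features(stack, "GFP"),
                labels = lab)), seed = s)
    clf$metadata$holdout_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.7), 0.05)
})

test_that("single-class labels are rejected", {
  stack <- two_level_stack()
  lab <- array(1L, dim(stack$channels$GFP))
  expect_error(train_voxel_classifier(
    list(list(features = compute_voxel_features(stack, "GFP"), labels = lab))),
    "both")
})

test_that("on a noiseless two-level phantom the pipeline equals thresholding", {
  stack <- two_level_stack()
  truth <- stack$channels$GFP > 50
  clf <- train_on_stack(stack, truth)
  masks <- predict_clone_mask(stack, clf, threshold = 0.5, min_size_um3 = 0)
  expect_identical(masks$clone_mask, truth & masks$tissue_mask)
})

test_that("raising the threshold never grows the clone mask", {
  p <- small_params()
  sim <- simulate_disc(p, seed = 21)
  clf <- default_classifier()
  prev <- NULL
  for (thr in c(0.3, 0.5, 0.7, 0.9)) {
    masks <- predict_clone_mask(sim$stack, clf, threshold = thr,
                                min_size_um3 = 0)
    if (!is.null(prev)) expect_true(all(prev | !masks$clone_mask))
    prev <- masks$clone_mask
  }
})

test_that("objects below the physical size floor are removed", {
  stack <- two_level_stack()
  truth <- stack$channels$GFP > 50
  clf <- train_on_stack(stack, truth)
  # a 10-voxel object is 2.5 um^3 at 1 x 0.5 x 0.5 um voxels
  small <- two_level_stack()
  small$channels$GFP[] <- 0
  small$channels$GFP[8, 10:14, 12:13] <- 100
  expect_equal(sum(small$channels$GFP > 50), 10)
  kept <- predict_clone_mask(small, clf, min_size_um3 = 0)
  expect_equal(max(label_clones(kept$clone_mask)), 1)
  # brute-force physical size of the single detected object
  object_um3 <- sum(kept$clone_mask) * prod(small$voxel_size_um)
  expect_gt(object_um3, 0)
  removed <- predict_clone_mask(small, clf, min_size_um3 = object_um3 + 0.01)
  expect_equal(sum(removed$clone_mask), 0)
})

test_that("noiseless phantom segmentation recovers the true clones closely", {
  p0 <- make_condition_preset("ph505", snr = 1e5)
  sim <- simulate_disc(p0, seed = 31)
  masks <- predict_clone_mask(sim$stack, noiseless_classifier())
  expect_gte(dice_coef(masks$clone_mask, sim$truth$clone_mask), 0.98)
})

test_that("tissue mask recovers the phantom tissue at default snr", {
  p <- make_condition_preset("ph505")
  sim <- simulate_disc(p, seed = 41)
  mask <- compute_tissue_mask(sim$stack)
  jac <- sum(mask & sim$truth$tissue_mask) /
    sum(mask | sim$truth$tissue_mask)
  expect_gte(jac, 0.95)
})

test_that("tissue mask handles crisp geometry, lobes and degenerate input", {
  d <- c(16, 24, 32)
  dapi <- array(0, d)
  dapi[4:12, 4:12, 4:12] <- 100   # lobe 1
  dapi[4:12, 4:12, 20:28] <- 100  # lobe 2
  stack <- image_stack(list(DAPI = dapi), c(1, 0.5, 0.5))
  mask <- compute_tissue_mask(stack, regularize_um = 0, min_size_um3 = 0)
  expect_true(all(mask[5:11, 5:11, 5:11]))
  expect_true(all(mask[5:11, 5:11, 21:27]))
  expect_false(any(mask[, , 14:18]))
  flat <- image_stack(list(DAPI = array(7, d)), c(1, 0.5, 0.5))
  expect_error(compute_tissue_mask(flat), "constant")
})

test_that("segmentation is equivariant to axis-aligned translation", {
  p <- small_params()
  sim <- simulate_disc(p, seed = 51)
  clf <- default_classifier()
  d <- dim(sim$stack$channels$GFP)
  shift_vol <- function(v, s) {
    out <- array(0, d)
    out[(1 + s[1]):d[1], (1 + s[2]):d[2], (1 + s[3]):d[3]] <-
      v[1:(d[1] - s[1]), 1:(d[2] - s[2]), 1:(d[3] - s[3])]
    out
  }
  s <- c(2, 3, 4)
  shifted <- image_stack(lapply(sim$stack$channels, shift_vol, s = s),
                         sim$stack$voxel_size_um)
  m0 <- predict_clone_mask(sim$stack, clf, min_size_um3 = 0)
  m1 <- predict_clone_mask(shifted, clf, min_size_um3 = 0)
  # compare away from the padded border (features use replicate boundaries)
  core <- function(m, off) {
    m[(7 + off[1]):(d[1] - 7 + off[1]), (7 + off[2]):(d[2] - 7 + off[2]),
      (7 + off[3]):(d[3] - 7 + off[3])]
  }
  a <- core(m0$clone_mask, c(0, 0, 0))
  b <- core(m1$clone_mask, s)
  expect_gte(mean(a == b), 0.99)
})

test_that("segmentation quality degrades monotonically with noise", {
  clf <- default_classifier()
  mean_dice <- vapply(c(10, 2), function(snr) {
    p <- small_params(snr = snr)
    mean(vapply(1:10, function(i) {
      sim <- simulate_disc(p, seed = 600 + i)
      m <- predict_clone_mask(sim$stack, clf)
      dice_coef(m$clone_mask, sim$truth$clone_mask)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mean_dice[1], mean_dice[2])
})
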