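# Shared fixtures built in code. The default classifier is trained once per
# test run on five ph505 phantoms (seeds 901..905) and cached.

.fixtures <- new.env(parent = emptyenv())

small_params <- function(...) {
  disc_phantom_params(shape_voxels = c(16L, 24L, 32L), ...)
}

train_phantom_classifier <- function(params, seeds = 901:905, seed = 0) {
  training <- lapply(seeds, function(s) {
    sim <- simulate_disc(params, seed = s)
    list(features = compute_voxel_features(sim$stack, "GFP"),
         labels = phantom_labels(sim$truth))
  })
  train_voxel_classifier(training, seed = seed)
}

default_classifier <- function() {
  if (is.null(.fixtures$clf)) {
    .fixtures$clf <- train_phantom_classifier(make_condition_preset("ph505"))
  }
  .fixtures$clf
}

noiseless_classifier <- function() {
  if (is.null(.fixtures$clf0)) {
    .fixtures$clf0 <- train_phantom_classifier(
      make_condition_preset("ph505", snr = 1e5))
  }
  .fixtures$clf0
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Independent flood-fill labelling oracle (26-connectivity), brute force.
flood_fill_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextlab <- 0L
  coords <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    v <- coords[r, ]
    if (lab[v[1], v[2], v[3]] > 0L) next
    nextlab <- nextlab + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- nextlab
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        nb <- cur + c(dz, dy, dx)
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nextlab
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}
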