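test_that("condition presets carry the reported tumor-volume fractions", {
  expect_equal(make_condition_preset("ph505")$target_clone_fraction, 0.46)
  expect_equal(make_condition_preset("ph505_kniKD")$target_clone_fraction, 0.05)
  expect_equal(make_condition_preset("ph505_ato")$target_clone_fraction, 0.03)
  expect_equal(make_condition_preset("ph505_rescue")$target_clone_fraction, 0.07)
  expect_error(make_condition_preset("nope"), "valid presets.*ph505")
})

test_that("phantom ground truth is internally consistent and hits the target", {
  for (target in c(0.46, 0.05)) {
    p <- small_params(target_clone_fraction = target)
    sim <- simulate_disc(p, seed = 11)
    tr <- sim$truth
    expect_false(any(tr$clone_mask & !tr$tissue_mask))
    expect_identical(tr$true_fraction, sum(tr$clone_mask) / sum(tr$tissue_mask))
    expect_lte(abs(tr$true_fraction - target), 0.01)
    expect_true(all(tr$clone_labels[!tr$clone_mask] == 0L))
    expect_true(all(tr$clone_labels[tr$clone_mask] > 0L))
  }
})

test_that("zero clone fraction yields an empty clone mask", {
  sim <- simulate_disc(small_params(target_clone_fraction = 0), seed = 2)
  expect_equal(sum(sim$truth$clone_mask), 0)
  expect_equal(sim$truth$true_fraction, 0)
  expect_equal(nrow(sim$truth$ph3_true[sim$truth$ph3_true$compartment ==
                                         "inside", ]), 0)
})

test_that("phantom generation is a pure function of params and seed", {
  p <- small_params()
  a <- simulate_disc(p, seed = 7)
  b <- simulate_disc(p, seed = 7)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$clone_mask, b$truth$clone_mask)
  expect_identical(a$truth$ph3_true, b$truth$ph3_true)
  c <- simulate_disc(p, seed = 8)
  expect_false(identical(a$stack$channels$GFP, c$stack$channels$GFP))
  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(3)
  set.seed(123); invisible(simulate_disc(p, seed = 7)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("pH3 spot counts follow the Poisson compartment intensities", {
  p <- small_params()
  n_seeds <- 40
  vv <- prod(p$voxel_size_um)
  obs_in <- obs_out <- exp_in <- exp_out <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    sim <- simulate_disc(p, seed = 400 + i)
    tr <- sim$truth
    exp_in[i] <- p$ph3_density_inside_per_mm3 * sum(tr$clone_mask) * vv / 1e9
    exp_out[i] <- p$ph3_density_outside_per_mm3 *
      (sum(tr$tissue_mask) - sum(tr$clone_mask)) * vv / 1e9
    obs_in[i] <- sum(tr$ph3_true$compartment == "inside")
    obs_out[i] <- sum(tr$ph3_true$compartment == "outside")
    # hard-core separation: nuclei never closer than twice their radius
    pos <- as.matrix(tr$ph3_true[, c("z_um", "y_um", "x_um")])
    if (nrow(pos) >= 2) {
      expect_gte(min(dist(pos)), 2 * p$nuclear_radius_um - 1e-9)
    }
  }
  se_in <- sd(obs_in) / sqrt(n_seeds)
  se_out <- sd(obs_out) / sqrt(n_seeds)
  expect_lte(abs(mean(obs_in) - mean(exp_in)), 3 * se_in)
  expect_lte(abs(mean(obs_out) - mean(exp_out)), 3 * se_out)
})

test_that("phantom parameter validation rejects bad inputs", {
  expect_error(disc_phantom_params(target_clone_fraction = 1.2), "\\[0, 1\\]")
  expect_error(disc_phantom_params(shape_voxels = c(8, 48, 64)), ">= 16")
  expect_error(disc_phantom_params(snr = 0), "snr")
  expect_error(disc_phantom_params(n_clones_range = c(0, 3)), "n_clones_range")
})

test_that("eclosion simulation is binomial with the preset survival", {
  expect_equal(simulate_eclosion(
    eclosion_sim_params("x", 100, 0), seed = 1)$n_adults, 0)
  expect_equal(simulate_eclosion(
    eclosion_sim_params("x", 48, 1), seed = 1)$n_adults, 48)
  expect_error(eclosion_sim_params("x", 10, 1.5), "\\[0, 1\\]")
  expect_error(make_eclosion_preset("unknown"), "valid presets")
  p <- make_eclosion_preset("ph505_rescue", n_larvae = 48)
  expect_equal(p$p_eclose, 0.97)
  rates <- vapply(1:300, function(s) {
    eclosion_rate(simulate_eclosion(p, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 97), 1)
})

test_that("expression simulator reproduces its negative-binomial moments", {
  # Poisson limit: dispersion -> 0 makes variance approach the mean
  p <- count_sim_params(n_genes = 10L, groups = c(a = 5000L, b = 2L),
                        dispersion = 1e-8, embryonic_module_size = 0L,
                        neural_module_size = 0L,
                        library_size_range = c(1, 1))
  sim <- simulate_expression(p, seed = 3)
  a <- sim$counts[, sim$samples$group == "a"]
  ratio <- apply(a, 1, var) / rowMeans(a)
  expect_true(all(abs(ratio - 1) < 0.15))
  # with dispersion the NB variance m + alpha m^2 appears
  p2 <- count_sim_params(n_genes = 10L, groups = c(a = 5000L, b = 2L),
                         dispersion = 0.2, embryonic_module_size = 0L,
                         neural_module_size = 0L, library_size_range = c(1, 1))
  sim2 <- simulate_expression(p2, seed = 3)
  a2 <- sim2$counts[, sim2$samples$group == "a"]
  m <- rowMeans(a2)
  expect_equal(apply(a2, 1, var), m + 0.2 * m^2, tolerance = 0.15)
})

test_that("embryonic module is up-shifted by 2^log2fc in tumor samples", {
  sim <- simulate_expression(count_sim_params(), seed = 7)
  emb <- sim$genes$module == "embryonic"
  tumor <- sim$samples$group == "tumor"
  disc <- sim$samples$group == "eye_disc"
  ratio <- mean(sim$counts[emb, tumor]) / mean(sim$counts[emb, disc])
  expect_equal(ratio, 2^count_sim_params()$log2fc_embryonic, tolerance = 0.1)
})

test_that("null expression design carries no module signal", {
  p <- count_sim_params(log2fc_embryonic = 0, log2fc_neural = 0)
  sim <- simulate_expression(p, seed = 5)
  emb <- sim$genes$module == "embryonic"
  tumor <- sim$samples$group == "tumor"
  disc <- sim$samples$group == "eye_disc"
  ratio <- mean(sim$counts[emb, tumor]) / mean(sim$counts[emb, disc])
  expect_equal(ratio, 1, tolerance = 0.25)
})

test_that("expression parameter validation", {
  expect_error(count_sim_params(dispersion = 0), "dispersion")
  expect_error(count_sim_params(groups = c(a = 5L)), "groups")
  expect_error(count_sim_params(n_genes = 100L, embryonic_module_size = 80L,
                                neural_module_size = 40L), "module sizes")
})
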