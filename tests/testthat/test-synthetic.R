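test_that("filament generation is deterministic and honours its config", {
  cfg <- filament_sim_config(n_filaments = 20, seed = 5)
  g1 <- gen_filaments(cfg)
  g2 <- gen_filaments(cfg)
  expect_identical(g1$truth, g2$truth)
  expect_equal(g1$traces[[7]]$points, g2$traces[[7]]$points)

  # realized arc length equals the drawn target; vertex spacing <= 5 nm
  for (i in seq_along(g1$traces)) {
    pts <- g1$traces[[i]]$points
    steps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    expect_lte(max(steps), 5 + 1e-9)
    expect_equal(loop_arc_length(pts), g1$truth$true_length[i],
                 tolerance = 0.02)
  }
})

test_that("straight axis-aligned filaments arise in the degenerate limit", {
  cfg <- filament_sim_config(n_filaments = 10, curvature = 0,
                             concentration = 1e6, mean_angle = 0, seed = 2)
  g <- gen_filaments(cfg)
  expect_lt(max(g$truth$mean_angle), 0.5)
  # all segments parallel to +x up to the residual orientation spread
  for (tr in g$traces) {
    d <- diff(tr$points[, 1])
    expect_true(all(d > 0))
    expect_lt(max(abs(diff(tr$points[, 2]))), 0.01 * max(abs(d)))
  }
})

test_that("sampled filament length medians track the configured median", {
  meds <- vapply(1:10, function(s) {
    g <- gen_filaments(filament_sim_config(n_filaments = 325, seed = s))
    stats::median(g$truth$true_length)
  }, numeric(1))
  expect_equal(mean(meds), 182.4, tolerance = 0.05)
})

test_that("an oversized median relative to the box is rejected", {
  expect_error(gen_filaments(filament_sim_config(
    n_filaments = 2, median_length = 5000, bounding_box = c(100, 100, 100))),
    "box")
})

test_that("a single zero-spread chain has exactly the drawn spacing", {
  cfg <- particle_sim_config(n_particles_target = 5, chain_fraction = 1,
                             chain_mean_length = 60, spacing_mean = 30,
                             spacing_sd = 0, scattered_fraction = 0,
                             bounding_box = c(500, 500, 500), seed = 3)
  g <- gen_particles(cfg)
  expect_equal(nrow(g$particles$coords), 5L)
  expect_true(all(g$truth$kind == "chain"))
  expect_true(all(g$truth$chain_id == 1L))
  gaps <- sqrt(rowSums(diff(g$particles$coords)^2))
  expect_equal(gaps, rep(30, 4), tolerance = 1e-9)
})

test_that("fully isolated configurations respect the minimum distance", {
  cfg <- particle_sim_config(n_particles_target = 40, chain_fraction = 0,
                             scattered_fraction = 0,
                             isolated_min_distance = 60,
                             bounding_box = c(1500, 1500, 400), seed = 8)
  g <- gen_particles(cfg)
  nn <- brute_nn(g$particles$coords)
  expect_gte(min(nn$nn_distance), 60)
})

test_that("particle generation is a pure function of config and seed", {
  cfg <- particle_sim_config(n_particles_target = 300, seed = 12)
  expect_identical(gen_particles(cfg)$particles$coords,
                   gen_particles(cfg)$particles$coords)
  cfg2 <- particle_sim_config(n_particles_target = 300, seed = 13)
  expect_false(identical(gen_particles(cfg)$particles$coords,
                         gen_particles(cfg2)$particles$coords))
})

test_that("chained particles' nearest neighbours equal their chain spacing", {
  g <- gen_particles(particle_sim_config(n_particles_target = 400, seed = 21))
  nn <- nn_distances(g$particles)
  ch <- g$truth$kind == "chain"
  expect_equal(nn$nn_distance[ch], g$truth$spacing[ch], tolerance = 1e-9)
  iso <- g$truth$kind == "isolated"
  expect_gte(min(nn$nn_distance[iso]), 55)
})

test_that("particle volumes carry the stated transform and wedge", {
  # no wedge, negligible noise: volume equals the rotated/shifted template
  cfg <- volume_sim_config(box = 24, voxel_size = 21.8, n_particles = 2,
                           snr = 1e12, wedge_halfangle = 90, seed = 6)
  sim <- gen_particle_volumes(cfg)
  i <- 1L
  R <- euler_to_matrix(sim$truth$phi[i], sim$truth$theta[i], sim$truth$psi[i])
  expected <- rotate_volume(sim$template$data, R,
                            shift = as.numeric(sim$truth[i, c("sx", "sy", "sz")]))
  expect_gt(stats::cor(as.numeric(sim$volumes[[i]]$data),
                       as.numeric(expected)), 0.999)

  # wedge on: Fourier amplitudes inside the missing wedge are removed
  cfgw <- volume_sim_config(box = 24, voxel_size = 21.8, n_particles = 1,
                            snr = 1e12, wedge_halfangle = 30, seed = 6)
  simw <- gen_particle_volumes(cfgw)
  W <- wedge_mask(24, 30)
  Fv <- fft(simw$volumes[[1]]$data)
  expect_lt(max(Mod(Fv[W == 0])), 1e-6 * max(Mod(Fv)))
})

test_that("noise realizations from different seeds are uncorrelated", {
  mk <- function(seed) {
    cfg <- volume_sim_config(box = 32, voxel_size = 21.8, n_particles = 1,
                             snr = 0.5, wedge_halfangle = 90, seed = seed)
    sim <- gen_particle_volumes(cfg)
    R <- euler_to_matrix(sim$truth$phi[1], sim$truth$theta[1],
                         sim$truth$psi[1])
    sig <- rotate_volume(sim$template$data, R,
                         shift = as.numeric(sim$truth[1, c("sx", "sy", "sz")]))
    as.numeric(sim$volumes[[1]]$data) - as.numeric(sig)
  }
  r <- stats::cor(mk(101), mk(202))
  expect_lt(abs(r), 0.05)
})

test_that("organelle generation matches its degenerate and empty limits", {
  groups <- data.frame(structure = "mitochondrion", region = "mature_branch",
                       median = 445, sigma_log = 0, n = 34L,
                       source = "cryo_et")
  mt <- gen_measurements(organelle_sim_config(groups, seed = 1))
  expect_equal(nrow(mt), 34L)
  expect_equal(mt$value, rep(445, 34))

  empty <- gen_measurements(organelle_sim_config(
    groups = organelle_defaults()[0, ], seed = 1))
  expect_s3_class(empty, "measurement_table")
  expect_equal(nrow(empty), 0L)

  cfg <- organelle_sim_config(seed = 4)
  expect_identical(gen_measurements(cfg)$value, gen_measurements(cfg)$value)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_particles(particle_sim_config(n_particles_target = 50,
                                              seed = 1)))
  expect_identical(.Random.seed, before)
})
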