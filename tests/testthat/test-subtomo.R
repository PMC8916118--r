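test_that("volume rotation is exact for the identity transform", {
  set.seed(1)
  v <- array(rnorm(16^3), dim = c(16, 16, 16))
  expect_equal(rotate_volume(v, diag(3)), v)
  expect_equal(rotate_volume(v, diag(3), shift = c(0, 0, 0)), v)
})

test_that("Euler conversions round-trip and measure rotation distance", {
  set.seed(2)
  for (i in 1:20) {
    R <- tomomorph:::random_rotation()
    eul <- matrix_to_euler(R)
    expect_lt(rotation_distance(R, euler_to_matrix(eul[1], eul[2], eul[3])),
              1e-4)
  }
  expect_equal(rotation_distance(diag(3), euler_to_matrix(90, 0, 0)), 90,
               tolerance = 1e-9)
})

test_that("self-alignment returns the identity with score near 1", {
  tpl <- sim_template(volume_sim_config(box = 24, voxel_size = 21.8))
  o <- align(tpl, tpl, angular_steps = c(30, 15))
  expect_gt(o$score, 0.999)
  expect_lt(rotation_distance(o$R, diag(3)), 1e-6)
  expect_equal(o$shift, c(0, 0, 0), tolerance = 1e-6)
})

test_that("box mismatches are rejected", {
  a <- tomo_volume(array(0, dim = c(16, 16, 16)), 21.8)
  b <- tomo_volume(array(0, dim = c(24, 24, 24)), 21.8)
  expect_error(align(a, b), "box")
  expect_error(compute_fsc(a, b), "dimensions")
})

test_that("alignment scores are invariant under a common rotation", {
  cfg <- volume_sim_config(box = 24, voxel_size = 21.8, n_particles = 1,
                           snr = 1e6, wedge_halfangle = 90, seed = 31)
  sim <- gen_particle_volumes(cfg)
  p <- sim$volumes[[1]]
  tpl <- sim$template
  o1 <- align(p, tpl, angular_steps = c(30, 15), wedge = NULL)
  Rc <- euler_to_matrix(60, 30, 0)
  p2 <- tomo_volume(rotate_volume(p$data, Rc), 21.8)
  t2 <- tomo_volume(rotate_volume(tpl$data, Rc), 21.8)
  o2 <- align(p2, t2, angular_steps = c(30, 15), wedge = NULL)
  expect_lt(abs(o1$score - o2$score), 0.02)
})

test_that("FSC identities hold exactly and noise pairs stay near zero", {
  set.seed(3)
  a <- tomo_volume(array(rnorm(32^3), dim = c(32, 32, 32)), 5.46)
  self <- compute_fsc(a, a)
  expect_equal(self$fsc, rep(1, nrow(self)), tolerance = 1e-9)
  neg <- compute_fsc(a, tomo_volume(-a$data, 5.46))
  expect_equal(neg$fsc, rep(-1, nrow(neg)), tolerance = 1e-9)
  expect_true(all(diff(self$freq) > 0))

  b <- tomo_volume(array(rnorm(32^3), dim = c(32, 32, 32)), 5.46)
  ab <- compute_fsc(a, b)
  ba <- compute_fsc(b, a)
  expect_identical(ab$fsc, ba$fsc)
  shells <- ab$shell > 0
  expect_lt(mean(abs(ab$fsc[shells])),
            3 / sqrt(min(ab$n_voxels[shells])))
})

test_that("threshold crossings interpolate linearly between shells", {
  curve <- structure(data.frame(shell = 0:2, freq = c(0, 0.01, 0.02),
                                fsc = c(1, 1, 0), n_voxels = c(1, 10, 20)),
                     class = c("fsc_curve", "data.frame"))
  expect_equal(resolution_at(curve, 0.5, 5.46), 1 / 0.015)

  flat <- structure(data.frame(shell = 0:3, freq = c(0, 0.01, 0.02, 0.03),
                               fsc = rep(1, 4), n_voxels = rep(10, 4)),
                    class = c("fsc_curve", "data.frame"))
  r <- resolution_at(flat, 0.5, 5.46)
  expect_equal(as.numeric(r), 2 * 5.46)
  expect_true(isTRUE(attr(r, "nyquist_limited")))

  dead <- structure(data.frame(shell = 0:2, freq = c(0, 0.01, 0.02),
                               fsc = c(1, 0.05, 0.01), n_voxels = rep(10, 3)),
                    class = c("fsc_curve", "data.frame"))
  expect_true(is.na(resolution_at(dead, 0.143, 5.46)))

  expect_error(resolution_at(curve, 1.5, 5.46), "threshold")
  expect_error(resolution_at(curve, 0, 5.46), "threshold")

  # the 0.5 criterion is never finer than the 0.143 criterion
  set.seed(8)
  mono <- structure(data.frame(shell = 0:16, freq = (0:16) / (32 * 5.46),
                               fsc = c(1, sort(runif(16), decreasing = TRUE)),
                               n_voxels = rep(50, 17)),
                    class = c("fsc_curve", "data.frame"))
  r143 <- resolution_at(mono, 0.143, 5.46)
  r05 <- resolution_at(mono, 0.5, 5.46)
  if (!is.na(r143) && !is.na(r05)) expect_gte(as.numeric(r05),
                                              as.numeric(r143))
})

test_that("identical particles average to themselves with unit FSC", {
  cfg <- volume_sim_config(box = 16, voxel_size = 21.8, n_particles = 1,
                           snr = 5, wedge_halfangle = 90, seed = 41)
  p <- gen_particle_volumes(cfg)$volumes[[1]]
  particles <- rep(list(p), 4)
  st <- iterate_average(particles, p, n_iter = 1,
                        schedule = list(c(30, 15)), wedge = NULL,
                        lowpass_start = 2 * 21.8)
  fsc <- st$fsc[[1]]
  expect_equal(fsc$fsc, rep(1, nrow(fsc)), tolerance = 1e-6)
  expect_gt(stats::cor(as.numeric(st$average$data), as.numeric(p$data)),
            0.99)
})

test_that("pure-noise half-sets do not produce a confident resolution", {
  set.seed(9)
  mk <- function() tomo_volume(array(rnorm(32^3), dim = c(32, 32, 32)), 21.8)
  box_extent <- 32 * 21.8
  for (i in 1:10) {
    r <- resolution_at(compute_fsc(mk(), mk()), 0.5, 21.8)
    expect_true(is.na(r) || as.numeric(r) >= box_extent / 4)
  }
})

test_that("missing-wedge masks cover the stated angular range", {
  W <- wedge_mask(32, 30)
  k <- tomomorph:::freq_grids(c(32L, 32L, 32L))
  ang <- atan2(abs(k$kz), abs(k$kx)) * 180 / pi
  inside <- ang <= 60
  on_axis <- abs(k$kx) + abs(k$kz) == 0
  expect_true(all(W[inside | on_axis] == 1))
  expect_true(all(W[!(inside | on_axis)] == 0))
  expect_true(all(wedge_mask(16, 90) == 1))
})
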