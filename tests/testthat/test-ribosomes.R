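test_that("nearest-neighbour distances match hand-computable cases", {
  p2 <- particle_set(rbind(c(0, 0, 0), c(30, 0, 0)))
  nn2 <- nn_distances(p2)
  expect_equal(nn2$nn_distance, c(30, 30))

  p3 <- particle_set(rbind(c(0, 0, 0), c(30, 0, 0), c(70, 0, 0)))
  expect_equal(nn_distances(p3)$nn_distance, c(30, 30, 40))

  expect_error(nn_distances(particle_set(matrix(1:3, 1, 3))), "2 particles")
  dup <- particle_set(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0)))
  expect_warning(nnd <- nn_distances(dup), "duplicate")
  expect_equal(nnd$nn_distance[1], 0)
})

test_that("nearest neighbours equal the O(n^2) scan and are rigid-invariant", {
  set.seed(123)
  coords <- matrix(runif(500 * 3, 0, 800), 500, 3)
  nn <- nn_distances(particle_set(coords))
  oracle <- brute_nn(coords)
  expect_identical(nn$nn_distance, oracle$nn_distance)
  expect_identical(nn$nn_index, oracle$nn_index)

  R <- euler_to_matrix(33, 71, 150)
  moved <- apply_rigid(coords, R, c(100, -40, 7))
  nn_t <- nn_distances(particle_set(moved))
  expect_equal(nn_t$nn_distance, nn$nn_distance, tolerance = 1e-9)
})

test_that("the Gaussian histogram fit recovers a known distribution", {
  set.seed(5)
  d <- rnorm(1e4, 30, 3)
  d <- d[d > 0]
  nn <- structure(data.frame(nn_distance = d, nn_index = NA_integer_),
                  class = c("nn_result", "data.frame"))
  fit <- fit_gaussian(nn)
  expect_equal(fit$mean, 30, tolerance = 0.2 / 30)
  expect_equal(fit$sd, 3, tolerance = 0.2 / 3)
  expect_equal(fit$n_fitted, sum(d < 40))

  allsame <- structure(data.frame(nn_distance = rep(30, 100),
                                  nn_index = NA_integer_),
                       class = c("nn_result", "data.frame"))
  expect_error(fit_gaussian(allsame), "degenerate|nonempty")
})

test_that("the fitted mean is stable under bin-width halving", {
  set.seed(6)
  d <- rnorm(2000, 29.5, 3.4)
  nn <- structure(data.frame(nn_distance = d[d > 0], nn_index = NA_integer_),
                  class = c("nn_result", "data.frame"))
  f2 <- fit_gaussian(nn, bin_width = 2)
  f1 <- fit_gaussian(nn, bin_width = 1)
  expect_lt(abs(f2$mean - f1$mean), 0.3)
})

test_that("classification counts windowed and isolated fractions", {
  mknn <- function(d) structure(data.frame(nn_distance = d,
                                           nn_index = NA_integer_),
                                class = c("nn_result", "data.frame"))
  all30 <- classify_nn(mknn(rep(30, 8)))
  expect_equal(all30$fraction_in_window, 1)
  expect_equal(all30$fraction_isolated, 0)

  mix <- classify_nn(mknn(c(30, 30, 60, 100)))
  expect_equal(mix$fraction_in_window, 0.5)
  expect_equal(mix$fraction_isolated, 0.5)

  expect_error(classify_nn(mknn(c(30, 40)), window = c(35, 25)), "window")

  set.seed(30)
  rand <- classify_nn(mknn(runif(500, 0, 120)))
  expect_lte(rand$fraction_in_window + rand$fraction_isolated, 1)
})

test_that("chain extraction matches a union-find oracle", {
  # 5-particle helix at 30 nm spacing plus one remote particle
  g <- gen_particles(particle_sim_config(
    n_particles_target = 5, chain_fraction = 1, chain_mean_length = 60,
    spacing_mean = 30, spacing_sd = 0, scattered_fraction = 0,
    bounding_box = c(400, 400, 400), seed = 2))
  coords <- rbind(g$particles$coords, g$particles$coords[1, ] + c(200, 200, 200))
  ch <- extract_chains(particle_set(coords), link_threshold = 35)
  expect_length(ch$chains, 1L)
  expect_equal(sort(ch$chains[[1]]), 1:5)
  # path ordering walks the helix end to end
  expect_true(ch$chains[[1]][1] %in% c(1L, 5L))

  expect_length(extract_chains(particle_set(coords), link_threshold = 0)$chains, 0L)

  set.seed(77)
  cl <- matrix(runif(120 * 3, 0, 300), 120, 3)
  got <- extract_chains(particle_set(cl), link_threshold = 40)
  oracle <- brute_components(cl, 40)
  oracle <- unname(Filter(function(x) length(x) >= 2, oracle))
  sort_comp <- function(l) l[order(vapply(l, min, numeric(1)))]
  expect_equal(sort_comp(lapply(got$chains, sort)),
               sort_comp(lapply(oracle, sort)))
})

test_that("plot-back tables echo coordinates and round-trip through CSV", {
  coords <- matrix(runif(12, 0, 100), 4, 3)
  p <- particle_set(coords, orientations = matrix(0, 4, 3))
  tab <- plot_back(p)
  expect_equal(as.matrix(tab[, c("x", "y", "z")]), coords,
               ignore_attr = TRUE)
  expect_true(all(tab[, c("phi", "theta", "psi")] == 0))

  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back, tab, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(plot_back(particle_set(coords)), "orientations")
})
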