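test_that("resampling a straight trace gives equal axis-aligned segments", {
  tr <- filament_trace(rbind(c(0, 0, 0), c(0, 0, 100)))
  ss <- resample(tr, 10)
  expect_false(ss$short)
  expect_equal(nrow(ss$segments), 10L)
  expect_equal(ss$segments$length, rep(10, 10))
  expect_equal(ss$segments$dz, rep(1, 10))
  expect_equal(ss$segments$dx, rep(0, 10))
})

test_that("resampling follows the 3-4-5 direction example", {
  tr <- filament_trace(rbind(c(0, 0, 0), c(30, 40, 0)))
  ss <- resample(tr, 10)
  expect_equal(nrow(ss$segments), 5L)
  expect_equal(ss$segments$dx, rep(0.6, 5))
  expect_equal(ss$segments$dy, rep(0.8, 5))
})

test_that("the trailing remainder rule keeps >= spacing/2 and drops less", {
  tr_keep <- filament_trace(rbind(c(0, 0, 0), c(0, 0, 27)))
  expect_equal(nrow(resample(tr_keep, 10)$segments), 3L)  # 10+10+7
  expect_equal(filament_length(tr_keep), 27)
  tr_drop <- filament_trace(rbind(c(0, 0, 0), c(0, 0, 24)))
  expect_equal(nrow(resample(tr_drop, 10)$segments), 2L)  # 10+10, 4 dropped
  expect_equal(filament_length(tr_drop), 20)
})

test_that("short traces flag as empty but still report a length", {
  tr <- filament_trace(rbind(c(0, 0, 0), c(0, 0, 6)))
  ss <- resample(tr, 10)
  expect_true(ss$short)
  expect_equal(nrow(ss$segments), 0L)
  expect_equal(filament_length(tr), 6)
})

test_that("quarter-circle resampled length approaches the analytic arc", {
  tr <- quarter_circle_trace(r = 100)
  arc <- pi * 50  # 157.08 nm
  l10 <- filament_length(tr, 10)
  expect_equal(l10, arc, tolerance = 10 / arc)
  # chord shortening: always below the true arc, converging as spacing -> 0
  l5 <- filament_length(tr, 5); l1 <- filament_length(tr, 1)
  expect_lte(l10, arc + 1e-9)
  expect_lte(l5, arc + 1e-9)
  expect_true(l10 <= l5 + 5 && l5 <= l1 + 2.5)  # monotone up to remainder rule
  expect_equal(l1, arc, tolerance = 1e-3)
})

test_that("filament length matches an independent pairwise-distance loop", {
  set.seed(10)
  pts <- apply(matrix(rnorm(300 * 3, sd = 3), 300, 3), 2, cumsum)
  tr <- filament_trace(pts)
  ss <- resample(tr, 10)
  resampled_pts <- rbind(as.matrix(ss$segments[, c("x0", "y0", "z0")]),
                         as.matrix(ss$segments[nrow(ss$segments),
                                               c("x1", "y1", "z1")]))
  expect_equal(filament_length(tr), loop_arc_length(resampled_pts),
               tolerance = 1e-9)
})

test_that("filament length is invariant under trace reversal", {
  tr <- filament_trace(rbind(c(0, 0, 0), c(0, 0, 50)))
  rev_tr <- filament_trace(tr$points[nrow(tr$points):1, ])
  expect_equal(filament_length(tr), 50)
  expect_equal(filament_length(rev_tr), filament_length(tr))
  qc <- quarter_circle_trace()
  qc_rev <- filament_trace(qc$points[nrow(qc$points):1, ])
  expect_equal(filament_length(qc_rev), filament_length(qc),
               tolerance = 1e-3)
})

test_that("segment angles hit the analytic identities and fold to [0, 90]", {
  along <- resample(filament_trace(rbind(c(0, 0, 0), c(100, 0, 0))), 10)
  expect_equal(segment_angles(along, c(1, 0, 0)), rep(0, 10))
  perp <- resample(filament_trace(rbind(c(0, 0, 0), c(0, 100, 0))), 10)
  expect_equal(segment_angles(perp, c(1, 0, 0)), rep(90, 10))
  diag45 <- resample(filament_trace(rbind(c(0, 0, 0), c(100, 100, 0))), 10)
  expect_equal(segment_angles(diag45, c(1, 0, 0)),
               rep(45, length(segment_angles(diag45, c(1, 0, 0)))))
  # reflection of the filament and negation of the axis leave angles fixed
  refl <- resample(filament_trace(rbind(c(0, 0, 0), c(-100, -100, 0))), 10)
  expect_equal(segment_angles(refl, c(1, 0, 0)),
               segment_angles(diag45, c(1, 0, 0)))
  expect_equal(segment_angles(diag45, c(-1, 0, 0)),
               segment_angles(diag45, c(1, 0, 0)))
  expect_error(segment_angles(diag45, c(0, 0, 0)), "non-zero")
})

test_that("summaries apply the type-7 quantile rule per region", {
  traces <- lapply(c(100, 200, 300), function(L)
    filament_trace(rbind(c(0, 0, 0), c(0, 0, L)), id = paste0("f", L)))
  fs <- summarize_filaments(traces)
  expect_equal(fs$stats$median_length, 200)
  expect_equal(fs$stats$q1, 150)
  expect_equal(fs$stats$q3, 250)
  expect_equal(fs$stats$n, 3L)
  # histogram counts account for every segment
  expect_equal(sum(fs$angle_hist$count), fs$stats$n_segments)

  single <- summarize_filaments(traces[2])
  expect_equal(single$stats$median_length, 200)
  expect_equal(single$stats$q1, 200)
  expect_equal(single$stats$q3, 200)
})

test_that("recovered segment angles match the generating mean direction", {
  g <- gen_filaments(filament_sim_config(n_filaments = 60, mean_angle = 30,
                                         concentration = 20, curvature = 0,
                                         seed = 17))
  angs <- unlist(lapply(g$traces, function(tr)
    segment_angles(resample(tr, 10), c(1, 0, 0))))
  expect_gte(length(angs), 300)
  # circular mean of the folded angles
  cm <- atan2(mean(sin(angs * pi / 180)), mean(cos(angs * pi / 180))) * 180 / pi
  expect_equal(cm, 30, tolerance = 2 / 30)
})

test_that("the principal-axis helper recovers an elongated cloud axis", {
  set.seed(3)
  pts <- cbind(rnorm(200, sd = 100), rnorm(200, sd = 5), rnorm(200, sd = 5))
  ax <- estimate_reference_axis(pts)
  expect_gt(abs(ax[1]), 0.99)
})
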