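test_that("tangent construction recovers a planted glass transition", {
  g <- gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                      width = 4, baseline = c(1.6, 0), t_range = c(30, 100))
  gt <- detect_glass_transition(g$data, window = c(45, 72))
  expect_equal(gt$delta_cp, 0.45, tolerance = 0.02)
  expect_lt(abs(gt$tg_onset - 58), 0.5)
  expect_equal(gt$width, 4, tolerance = 0.1)
  expect_identical(gt$half_width, gt$width / 2)

  # invariance to a sloped linear baseline
  g2 <- gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                       width = 4, baseline = c(1.2, 0.005), t_range = c(30, 100))
  gt2 <- detect_glass_transition(g2$data, window = c(45, 72))
  expect_equal(gt2$delta_cp, gt$delta_cp, tolerance = 0.02)
  expect_lt(abs(gt2$tg_onset - gt$tg_onset), 0.2)

  # invariance to Gaussian noise of 1 % of step height
  g3 <- gen_thermogram(generator_recipe(7, noise_sigma = 0.0045,
                                        noise_model = "additive"),
                       tg_onset = 58, delta_cp = 0.45, width = 4,
                       t_range = c(30, 100))
  gt3 <- detect_glass_transition(g3$data, window = c(45, 72))
  expect_equal(gt3$delta_cp, 0.45, tolerance = 0.02)
  expect_lt(abs(gt3$tg_onset - 58), 0.5)
})

test_that("a flat trace raises a 'no glass transition' error", {
  flat <- thermogram(seq(30, 100, by = 0.1),
                     rep(1.6, length(seq(30, 100, by = 0.1))),
                     heating_rate = 10)
  expect_error(detect_glass_transition(flat, window = c(45, 72)),
               "no glass transition")
  expect_error(detect_glass_transition(flat, window = c(20, 72)),
               "outside the trace")
})

test_that("heat-flow thermograms convert through the declared rate", {
  g <- gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                      width = 4, t_range = c(30, 100), heating_rate = 10)
  hf <- g$data
  hf$signal <- hf$signal * (10 / 60)   # J/(g K) * K/s = W/g
  hf$signal_kind <- "heat_flow"
  gt_cp <- detect_glass_transition(g$data, window = c(45, 72))
  gt_hf <- detect_glass_transition(hf, window = c(45, 72))
  expect_equal(gt_hf$delta_cp, gt_cp$delta_cp, tolerance = 1e-10)
})

test_that("peak integration recovers planted enthalpies", {
  pk_def <- list(center = 130, area = 58.5, width = 3, direction = "exothermic")
  g <- gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                      width = 4, peaks = list(pk_def), t_range = c(30, 170))
  pk <- integrate_peak(g$data, c(115, 145), "exothermic")
  expect_equal(pk$enthalpy, 58.5, tolerance = 0.01)
  expect_equal(pk$t_peak, 130, tolerance = 0.2)

  # zero deviation integrates to zero enthalpy
  flat <- thermogram(seq(30, 170, by = 0.1),
                     rep(1.6, length(seq(30, 170, by = 0.1))),
                     heating_rate = 10)
  expect_equal(integrate_peak(flat, c(115, 145), "exothermic")$enthalpy, 0)

  # truncating the window strictly reduces the recovered area
  pk_cut <- integrate_peak(g$data, c(127, 133), "exothermic")
  expect_lt(pk_cut$enthalpy, 58.5)

  expect_error(integrate_peak(g$data, c(160, 200), "exothermic"),
               "outside the trace")
})

test_that("peak integration is additive over disjoint windows", {
  peaks <- list(
    list(center = 110, area = 30, width = 2.5, direction = "exothermic"),
    list(center = 150, area = 80, width = 3, direction = "endothermic"))
  g <- gen_thermogram(generator_recipe(1), tg_onset = 58, delta_cp = 0.45,
                      width = 4, peaks = peaks, t_range = c(30, 175))
  h1 <- integrate_peak(g$data, c(98, 122), "exothermic")$enthalpy
  h2 <- integrate_peak(g$data, c(136, 164), "endothermic")$enthalpy
  expect_equal(h1, 30, tolerance = 0.01)
  expect_equal(h2, 80, tolerance = 0.01)
  expect_equal(h1 + h2, 110, tolerance = 0.01)
})

test_that("crystallinity from the residual Cp step", {
  expect_equal(crystallinity_from_dcp(0.45, 0.45), 0)
  expect_equal(crystallinity_from_dcp(0, 0.45), 1)
  expect_equal(crystallinity_from_dcp(0.25 * 0.45, 0.45), 0.75)
  # affine invariance: joint rescaling leaves X unchanged
  expect_equal(crystallinity_from_dcp(0.1 * 7, 0.45 * 7),
               crystallinity_from_dcp(0.1, 0.45))
  expect_error(crystallinity_from_dcp(0.1, 0), "positive")
})
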