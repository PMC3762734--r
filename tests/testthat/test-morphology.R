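test_that("morphology of a constructed AP equals its closed form", {
  # triangle AP: rest -80 mV, linear rise to +40 at 60 mV/ms, linear
  # repolarization at 0.4 mV/ms; every metric has an exact value
  tr <- synthetic_ap(dt = 0.1)
  m <- measure_ap_morphology(tr)
  expect_equal(m$V_rest, -80)
  expect_equal(m$V_max, 40, tolerance = 1e-9)
  expect_equal(m$dVdt_max, 60, tolerance = 1e-9)
  # level crossings: APDx = 2 ms rise remainder + 1.2 x ms of tail
  # (amplitude 120 mV; x% below peak reached at (1.2x - offset)/0.4 ms)
  expect_equal(m$APD70, 2 + 0.7 * 120 / 0.4, tolerance = 1e-6)
  expect_equal(m$APD80, 2 + 0.8 * 120 / 0.4, tolerance = 1e-6)
  expect_equal(m$APD90, 2 + 0.9 * 120 / 0.4, tolerance = 1e-6)
  # monotone tail: no notch, no separate plateau maximum
  expect_true(is.na(m$V_notch))
})

test_that("APD ordering and voltage ordering hold on a real AP", {
  tr <- run_single_cell(composite_config(N_f = 0), stim_events(50, 3, -52),
                        t_end = 1500, sample_every = 5L)
  m <- measure_ap_morphology(tr)
  expect_true(m$APD70 <= m$APD80 && m$APD80 <= m$APD90)
  expect_true(m$V_rest <= m$V_notch && m$V_notch <= m$V_max)
  expect_true(m$V_plateau <= m$V_max)
  expect_identical(m$regime, "excitable")
})

test_that("a flat trace yields the excitable regime with undefined APDs", {
  t <- seq(0, 500, by = 0.5)
  tr <- structure(data.frame(t = t, V_m = rep(-86.2, length(t))),
                  class = c("mf_trace", "data.frame"), regime = "excitable")
  m <- measure_ap_morphology(tr)
  expect_identical(m$regime, "excitable")
  expect_true(all(is.na(c(m$APD70, m$APD80, m$APD90))))
  expect_equal(m$V_rest, -86.2)
})

test_that("an AP that never reaches a level reports that APD as NA", {
  # truncate the synthetic AP before the 90% level is reached
  tr <- synthetic_ap(dt = 0.1)
  tr <- tr[tr$t < 300, ]
  attr(tr, "stim_onset") <- 50
  m <- measure_ap_morphology(tr)
  expect_false(is.na(m$APD70))
  expect_true(is.na(m$APD90))
})
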