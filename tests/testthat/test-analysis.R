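test_that("CV of a constructed front equals dx over the frame interval", {
  a <- generate_fixture("plane-wave-strip", nx = 60, ny = 7, n_frames = 59,
                        frame_dt = 0.5)
  i1 <- round(0.25 * 59) + 1; i2 <- round(0.75 * 59) + 1
  v1 <- vapply(a$frames, function(f) f$V_m[i1, 4], 0)
  v2 <- vapply(a$frames, function(f) f$V_m[i2, 4], 0)
  cv <- measure_cv(a$t, v1, v2, distance_mm = (i2 - i1) * a$dx)
  expect_false(cv$failed)
  # one node per frame: dx / frame_dt mm/ms = 45 cm/s
  expect_equal(cv$cv_cm_s, a$dx / 0.5 * 100, tolerance = 1e-9)
})

test_that("conduction failure is flagged when the far probe never activates", {
  t <- seq(0, 100, by = 0.5)
  v_near <- ifelse(t > 10, 20, -86)
  v_far <- rep(-86, length(t))
  cv <- measure_cv(t, v_near, v_far, 10)
  expect_true(cv$failed)
  expect_true(is.na(cv$cv_cm_s))
})

test_that("the tip tracker recovers the core of an analytic rotor", {
  a <- generate_fixture("synthetic-rotor-field", nx = 81, ny = 81,
                        n_frames = 8, frame_dt = 10)
  core <- unlist(a$meta$core)
  traj <- track_tip(a, threshold = 100)
  expect_true(all(traj$n_tips >= 1))
  err <- sqrt((traj$x_mm - core[1])^2 + (traj$y_mm - core[2])^2)
  expect_lt(max(err), 3 * a$dx + 1e-9)
})

test_that("a quiescent field yields an empty trajectory", {
  a <- generate_fixture("resting-strip", nx = 30, ny = 30, n_frames = 3)
  a$frames <- lapply(a$frames, function(f) list(I_Na = f$V_m * 0))
  traj <- track_tip(a, threshold = 100)
  expect_true(all(traj$n_tips == 0))
  expect_true(all(is.na(traj$x_mm)))
})

test_that("beat statistics: upstrokes, ibi and the periodogram line", {
  dt <- 1                                 # ms
  t <- (0:4095) * dt
  f0 <- 4                                 # Hz
  v <- -60 + 30 * sin(2 * pi * f0 * t / 1000)
  bs <- beat_statistics(v, dt, v_thresh = -50, slope_thresh = 0)
  expect_equal(bs$df_Hz, 1 / (length(v) * dt * 1e-3))
  expect_equal(mean(bs$ibi), 1000 / f0, tolerance = 1e-3)
  peak <- bs$freq[which.max(bs$power[-1]) + 1]
  expect_lt(abs(peak - f0), bs$df_Hz)
})

test_that("rotation period from a constructed circular trajectory", {
  period <- 240
  t <- seq(0, 1200, by = 10)
  traj <- structure(data.frame(t = t,
                               x_mm = 20 + 5 * cos(2 * pi * t / period),
                               y_mm = 20 + 5 * sin(2 * pi * t / period),
                               n_tips = 1),
                    class = c("tip_trajectory", "data.frame"))
  p <- rotation_period(traj)
  expect_equal(p$period_ms, period, tolerance = 0.05)
  # fewer than two revolutions: refuse with NA
  short <- traj[t <= 300, ]
  class(short) <- c("tip_trajectory", "data.frame")
  expect_true(is.na(rotation_period(short)$period_ms))
})

test_that("periodic and nonperiodic probe series are classified", {
  mk <- function(ibis) {
    ups <- cumsum(c(100, ibis))
    structure(list(upstrokes = ups, ibi = ibis,
                   freq = 1, power = 1, df_Hz = 1), class = "beat_series")
  }
  per <- mk(rep(250, 10) + rnorm(10, 0, 1))
  non <- mk(runif(10, 150, 400))
  cl <- classify_inhomogeneity_dynamics(per, non)
  expect_identical(cl$inside, "periodic")
  expect_identical(cl$outside, "nonperiodic")
  traj <- structure(data.frame(t = 1:10, x_mm = 12, y_mm = 14, n_tips = 1),
                    class = c("tip_trajectory", "data.frame"))
  cl2 <- classify_inhomogeneity_dynamics(per, per, traj, c(10, 10, 20, 20))
  expect_true(cl2$anchored)
  cl3 <- classify_inhomogeneity_dynamics(per, per, traj, c(30, 30, 40, 40))
  expect_false(cl3$anchored)
})

test_that("sodium and isopotential trackers agree on a model spiral", {
  fx <- spiral_run_fixture()
  a <- fx$run$snapshots
  traj <- track_tip(archive_subset(a, fx$regular))
  expect_gt(sum(traj$n_tips >= 1), 10)
  ok <- is.finite(traj$x_mm)
  fx_t <- traj$t[ok]
  # isopotential tips from the closely spaced frame pairs (where the
  # finite-difference dV/dt approximates the instantaneous rate), compared
  # against the sodium-current trajectory interpolated to those times
  errs <- c()
  for (k in seq_along(a$t)[-1]) {
    dtk <- a$t[k] - a$t[k - 1]
    if (dtk > 2.5) next
    iso <- tip_isopotential(a$frames[[k - 1]]$V_m, a$frames[[k]]$V_m,
                            frame_dt = dtk, dx = a$dx)
    if (!nrow(iso)) next
    tx <- approx(fx_t, traj$x_mm[ok], xout = a$t[k])$y
    ty <- approx(fx_t, traj$y_mm[ok], xout = a$t[k])$y
    if (!is.finite(tx)) next
    d <- sqrt((iso[, 1] - tx)^2 + (iso[, 2] - ty)^2)
    errs <- c(errs, min(d))
  }
  expect_gt(length(errs), 5)
  rms <- sqrt(mean(errs^2))
  # three nodes of the rescaled domain's effective lattice (the grid runs
  # at D/9, i.e. 3x coarser effective spacing; the front itself is only
  # resolved to that scale)
  expect_lt(rms, 3 * 3 * a$dx)
})

test_that("ibi-based and tip-revolution period estimates agree", {
  fx <- spiral_run_fixture()
  p_ibi <- rotation_period(beat_statistics(fx$run$probes$V_m_1, 0.2))
  p_tip <- rotation_period(track_tip(archive_subset(fx$run$snapshots,
                                                    fx$regular)))
  expect_gte(p_ibi$n, 3)
  expect_false(is.na(p_tip$period_ms))
  expect_lt(abs(p_ibi$period_ms - p_tip$period_ms) / p_ibi$period_ms, 0.05)
})
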