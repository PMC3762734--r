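test_that("composite config derives and checks G_gap = N_f * g_j", {
  cfg <- composite_config(N_f = 4, g_j = 2)
  expect_identical(cfg$G_gap, 8)
  expect_error(composite_config(N_f = 1.5), "N_f")
  expect_error(composite_config(g_j = -1), "g_j")
})

test_that("gap current follows the linear driving force", {
  # G_gap = 8 nS, V_m = -84 mV, V_f = -24 mV -> -480 pA: the fibroblast
  # sources current into the myocyte
  cfg <- composite_config(N_f = 1, g_j = 8)
  s <- myocyte_resting_state()
  s["V"] <- -84
  st <- step_composite(s, -24, cfg)
  expect_identical(st$I_gap, 8 * (-84 - -24))
  # V_m = V_f: zero driving force, both cells evolve as uncoupled
  st0 <- step_composite(s, -84, cfg)
  expect_identical(st0$I_gap, 0)
  cfg_un <- composite_config(N_f = 0)
  st_un <- step_composite(s, numeric(0), cfg_un)
  expect_identical(st0$myocyte[["V"]], st_un$myocyte[["V"]])
})

test_that("N_f identical fibroblasts equal one cluster fibroblast", {
  # N fibroblasts (C_f, G_f) each coupled at g_j are equivalent to a single
  # cluster fibroblast (N C_f, N G_f) coupled at N g_j: the myocyte-side
  # current and the per-fibroblast relaxation are both preserved
  proto <- stim_events(50, 3, -52)
  tr_many <- run_single_cell(
    composite_config(N_f = 4, g_j = 2, fib = fibroblast_params(6.3, 4, -25)),
    proto, t_end = 600, sample_every = 20L, equilibrate_ms = 100)
  tr_one <- run_single_cell(
    composite_config(N_f = 1, g_j = 8,
                     fib = fibroblast_params(4 * 6.3, 4 * 4, -25)),
    proto, t_end = 600, sample_every = 20L, equilibrate_ms = 100)
  expect_lt(max(abs(tr_many$V_m - tr_one$V_m)), 1e-9)
  expect_lt(max(abs(tr_many$V_f - tr_one$V_f)), 1e-9)
})

test_that("all deltas vanish exactly at zero coupling", {
  d <- delta_vs_uncoupled(composite_config(N_f = 1, g_j = 0), t_end = 700)
  expect_identical(d$dAPD70, 0)
  expect_identical(d$dAPD80, 0)
  expect_identical(d$dAPD90, 0)
  expect_identical(d$d_dVdt_max, 0)
  expect_identical(d$dV_rest, 0)
})

test_that("resting potential rises and upstroke velocity falls with G_gap", {
  fib <- fibroblast_params(6.3, 4, -9)
  ggaps <- c(0.5, 2, 8)
  res <- lapply(ggaps, function(g)
    delta_vs_uncoupled(composite_config(N_f = 1, g_j = g, fib = fib)))
  dvr <- vapply(res, `[[`, 1, "dV_rest")
  dvdt <- vapply(res, `[[`, 1, "d_dVdt_max")
  expect_true(all(diff(dvr) > 0))
  expect_true(all(diff(dvdt) < 0))
})

test_that("APD lengthens with G_gap at high E_f and shortens at low E_f", {
  d_hi <- lapply(c(2, 8), function(g)
    delta_vs_uncoupled(composite_config(N_f = 1, g_j = g,
                                        fib = fibroblast_params(6.3, 4, -9))))
  expect_gt(d_hi[[2]]$dAPD90, d_hi[[1]]$dAPD90)
  expect_gt(d_hi[[2]]$dAPD90, 0)
  d_lo <- lapply(c(2, 8), function(g)
    delta_vs_uncoupled(composite_config(N_f = 1, g_j = g,
                                        fib = fibroblast_params(6.3, 4, -39))))
  expect_lt(d_lo[[2]]$dAPD90, d_lo[[1]]$dAPD90)
  expect_lt(d_lo[[2]]$dAPD90, 0)
})

test_that("a depolarising load can make the composite autorhythmic or oscillatory", {
  # three fibroblasts at E_f = -19 mV drive slow repetitive calcium-driven
  # firing; the stimulated-beat delta is then ill-defined and refused
  cfg <- composite_config(N_f = 3, g_j = 8,
                          fib = fibroblast_params(6.3, 4, -19))
  tr <- run_single_cell(cfg, stim_events(), t_end = 100,
                        equilibrate_ms = 5000, sample_every = 50L)
  expect_identical(attr(tr, "regime"), "autorhythmic")
  expect_error(delta_vs_uncoupled(cfg, equilibrate_ms = 5000), "autorhythmic")
  # a stronger load parks the membrane at a depolarized level where it
  # oscillates without full upstrokes
  cfg2 <- composite_config(N_f = 3, g_j = 8,
                           fib = fibroblast_params(6.3, 4, -9))
  tr2 <- run_single_cell(cfg2, stim_events(), t_end = 100,
                         equilibrate_ms = 20000, sample_every = 100L)
  expect_identical(attr(tr2, "regime"), "oscillatory")
})

test_that("an undefined APD level propagates as NA in the delta", {
  # the seven-fibroblast composite never repolarizes to the deeper levels
  # measured against the uncoupled rest
  d <- delta_vs_uncoupled(composite_config(N_f = 7, g_j = 8,
                                           fib = fibroblast_params(6.3, 4, -49)))
  expect_true(is.na(d$dAPD90))
  expect_false(is.na(d$dAPD70))
})
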