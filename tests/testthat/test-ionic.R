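test_that("current breakdown is consistent and pure", {
  s <- tnnp_initial_state()
  cur <- myocyte_currents(s)
  expect_equal(unname(cur["I_ion"]), sum(cur[setdiff(names(cur), "I_ion")]),
               tolerance = 1e-12)
  # pure function: same state, same answer
  expect_identical(cur, myocyte_currents(s))
  # zero activation gate kills I_Na exactly (cubic factor)
  s["m"] <- 0
  expect_identical(unname(myocyte_currents(s)["I_Na"]), 0)
})

test_that("compiled and R current evaluations agree", {
  s <- myocyte_resting_state()
  s["V"] <- 0; s["m"] <- 0.9; s["h"] <- 0.5; s["j"] <- 0.5; s["d"] <- 0.3
  cpp <- mfwave:::.cpp_currents(unname(s), unclass(tnnp_params()))
  r <- myocyte_currents(s)
  expect_equal(as.numeric(cpp), as.numeric(r[names(cpp)]), tolerance = 1e-12)
})

test_that("sodium current matches an independent scalar evaluation", {
  # independent oracle: the I_Na formula recoded from scratch, evaluated
  # at a depolarised state (V stepped to 0 mV from rest)
  s <- myocyte_resting_state()
  s["V"] <- 0; s["m"] <- 0.9
  RTONF <- 8314.472 * 310 / 96485.3415
  ena <- RTONF * log(140 / s[["Nai"]])
  ina_oracle <- 14.838 * 0.9^3 * s[["h"]] * s[["j"]] * (0 - ena)
  ina <- myocyte_currents(s)[["I_Na"]]
  expect_lt(ina, 0)                      # inward
  expect_equal(ina, ina_oracle, tolerance = 1e-12)
  expect_gt(abs(ina), 100)               # hundreds of pA/pF once activated
})

test_that("state validation names the offending variable", {
  s <- tnnp_initial_state()
  s["h"] <- NaN
  expect_error(myocyte_currents(s), "h")
  s <- tnnp_initial_state()
  s["m"] <- 1.5
  expect_error(validate_myocyte_state(s), "m")
  s <- tnnp_initial_state()
  s["Cai"] <- -1
  expect_error(validate_myocyte_state(s), "Cai")
})

test_that("unstimulated myocyte stays at rest; response is all-or-none", {
  cfg <- composite_config(N_f = 0)
  tr <- run_single_cell(cfg, stim_events(), t_end = 1000, sample_every = 50L,
                        equilibrate_ms = 0)
  expect_lt(diff(range(tr$V_m)), 0.5)
  # a supra-threshold 3 ms stimulus elicits exactly one AP
  tr1 <- run_single_cell(cfg, stim_events(50, 3, -52), t_end = 1500,
                         sample_every = 10L, equilibrate_ms = 0)
  t <- tr1$t
  ups <- sum(tr1$V_m[-length(t)] < -40 & tr1$V_m[-1] >= -40)
  expect_identical(ups, 1L)
  expect_gt(max(tr1$V_m), 0)
  # a 100x weaker stimulus elicits none
  tr2 <- run_single_cell(cfg, stim_events(50, 3, -0.52), t_end = 500,
                         sample_every = 10L, equilibrate_ms = 0)
  expect_lt(max(tr2$V_m), -40)
})

test_that("fibroblast current and RC relaxation follow the closed form", {
  fp <- fibroblast_params(C_f = 6.3, G_f = 4, E_f = -49)
  expect_identical(fibroblast_current(-49, fp), 0)
  expect_identical(fibroblast_current(0, fp), 196)
  # uncoupled relaxation: V_f(t) = E_f + (V0 - E_f) exp(-G_f t / C_f);
  # time constant C_f/G_f = 1.575 ms.  Forward Euler is first order: the
  # amplitude-relative error is bounded by (dt/2 tau) e^-1 and halves with
  # the step.
  relax_err <- function(dt, n) {
    v <- numeric(n + 1)
    for (k in seq_len(n)) v[k + 1] <- v[k] - dt * fp$G_f * (v[k] - fp$E_f) / fp$C_f
    exact <- fp$E_f + (0 - fp$E_f) * exp(-fp$G_f * (0:n) * dt / fp$C_f)
    max(abs(v - exact)) / abs(fp$E_f)
  }
  e02 <- relax_err(0.02, 500)
  e01 <- relax_err(0.01, 1000)
  expect_lt(e02, 0.02 / (2 * fp$C_f / fp$G_f) * exp(-1) * 1.2)
  expect_equal(e02 / e01, 2, tolerance = 0.05)
  # the integrator's own fibroblast (gap conductance 0 = uncoupled)
  # must reproduce the R-level Euler recursion to machine precision
  dt <- 0.02; n <- 500
  v <- numeric(n + 1)
  for (k in seq_len(n)) v[k + 1] <- v[k] - dt * fp$G_f * (v[k] - fp$E_f) / fp$C_f
  cfg <- composite_config(N_f = 1, g_j = 0,
                          fib = fibroblast_params(6.3, 4, -49))
  st <- step_composite(myocyte_resting_state(), 0, cfg, dt = dt, n_steps = n)
  expect_equal(st$fibroblast, v[n + 1], tolerance = 1e-12)
})

test_that("fibroblast parameter sanity windows are enforced", {
  expect_error(fibroblast_params(C_f = -1), "C_f")
  expect_error(fibroblast_params(E_f = 40), "sanity window")
  expect_error(fibroblast_current(NaN), "non-finite")
})
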