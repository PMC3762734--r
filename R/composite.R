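#' Stimulus schedule for single-cell runs
#'
#' Each event is a (start, duration, amplitude) triple.  Amplitudes are the
#' applied current density in the membrane-equation sign convention
#' (dV/dt contains \eqn{-(I_{ion} + I_{stim})}), so a depolarizing stimulus
#' is negative, e.g. -52 pA/pF.
#'
#' @param start onset times (ms).
#' @param duration durations (ms).
#' @param amplitude amplitudes (pA/pF, signed).
#' @return a numeric matrix with columns start, duration, amplitude.
#' @export
stim_events <- function(start = numeric(0), duration = numeric(0),
                        amplitude = numeric(0)) {
  stopifnot(length(start) == length(duration),
            length(start) == length(amplitude))
  if (length(duration) && any(duration <= 0)) stop("stimulus duration must be > 0")
  cbind(start = start, duration = duration, amplitude = amplitude)
}

#' Configuration of a single myocyte-fibroblast composite
#'
#' A myocyte coupled to `N_f` identical passive fibroblasts, each through a
#' per-junction conductance `g_j` (nS); the aggregate coupling is
#' `G_gap = N_f * g_j`.  The `N_f` identical fibroblasts are exactly
#' equivalent to a single cluster fibroblast with capacitance `N_f * C_f`,
#' membrane conductance `N_f * G_f` and coupling `G_gap` -- the reduction
#' the tissue model's one-fibroblast-per-node representation rests on.  The
#' single-cell integrator keeps all `N_f` junctions explicit, so the
#' equivalence is a verified property rather than an assumption.
#'
#' @param N_f number of fibroblasts (integer >= 0).
#' @param g_j per-junction gap conductance (nS, >= 0).
#' @param fib [fibroblast_params()].
#' @param stimulus a [stim_events()] matrix.
#' @param C_m total myocyte capacitance (pF), used to convert the
#'   gap-junctional current (pA) into a density (pA/pF) in the myocyte
#'   equation.
#' @param params ionic-model constants, [tnnp_params()].
#' @return a `composite_config` list with derived `G_gap`.
#' @export
composite_config <- function(N_f = 1, g_j = 8, fib = fibroblast_params(),
                             stimulus = stim_events(),
                             C_m = myocyte_capacitance_pF(params),
                             params = tnnp_params()) {
  stopifnot(N_f >= 0, N_f == as.integer(N_f), g_j >= 0)
  structure(list(N_f = as.integer(N_f), g_j = g_j, G_gap = N_f * g_j,
                 fib = fib, stimulus = stimulus, C_m = C_m, params = params),
            class = "composite_config")
}

#' Advance a composite by one (or more) time steps
#'
#' Forward-Euler step of the coupled myocyte/fibroblast unit.  The gap
#' current \eqn{I_{gap} = \sum_k g_j (V_m - V_{f,k})} (pA) leaves the
#' myocyte (divided by `C_m` to become a density) and enters the fibroblasts
#' with the opposite sign, so charge is conserved at the junction.
#'
#' @param m_state myocyte state vector.
#' @param f_state numeric vector of fibroblast potentials (length `N_f`).
#' @param cfg a [composite_config()].
#' @param dt step (ms).
#' @param n_steps number of steps to take.
#' @return list with elements `myocyte` (state vector), `fibroblast`
#'   (potentials) and `I_gap` (pA, at the initial time).
#' @export
step_composite <- function(m_state, f_state, cfg, dt = 0.02, n_steps = 1L) {
  stopifnot(dt > 0, inherits(cfg, "composite_config"),
            length(f_state) == cfg$N_f)
  m_state <- validate_myocyte_state(m_state)
  igap <- sum(cfg$g_j * (m_state[["V"]] - f_state))
  out <- .cpp_run_composite(unname(m_state), f_state, unclass(cfg$params),
                            cfg$fib$C_f, cfg$fib$G_f, cfg$fib$E_f, cfg$g_j,
                            cfg$C_m, cfg$stimulus, dt, dt * n_steps,
                            sample_every = n_steps, record_currents = FALSE,
                            rush_larsen = TRUE)
  list(myocyte = stats::setNames(out$state, .state_names),
       fibroblast = out$V_f_final, I_gap = igap)
}

#' Run a single-cell (composite) protocol
#'
#' Runs the MF unit from its relaxed state through a stimulus schedule and
#' records uniformly sampled traces of the myocyte and fibroblast potentials,
#' the aggregate gap current, and (optionally) the full ionic-current
#' breakdown.
#'
#' The run starts from the cached resting state of the isolated myocyte
#' (5 s unstimulated pre-run) with the fibroblasts at `E_f`, and the coupled
#' unit is then relaxed, unstimulated, for `equilibrate_ms` before the
#' schedule is applied, so that the pre-stimulus state is the composite's own
#' steady state.  The firing regime over the equilibration window is
#' classified as `excitable` (quiescent), `autorhythmic` (spontaneous
#' upstrokes) or `oscillatory` (sustained sub-threshold oscillations).
#'
#' @param cfg [composite_config()]; its `stimulus` is used unless `protocol`
#'   is given.
#' @param protocol optional [stim_events()] overriding `cfg$stimulus`.
#' @param t_end trace length (ms); should cover full repolarization of the
#'   last stimulated beat.
#' @param dt integration step (ms).
#' @param equilibrate_ms coupled, unstimulated relaxation before the
#'   protocol (ms).
#' @param record_currents record the 12-current breakdown per sample.
#' @param sample_every sampling stride in steps (1 = every step).
#' @param rush_larsen integrate the gating variables with the exponential
#'   (Rush-Larsen) update (the default, and the scheme of the published
#'   model code; the fast sodium activation gate makes plain Euler unstable
#'   at the model's 0.02 ms step).  `FALSE` selects plain forward-Euler
#'   gates for small-`dt` experimentation.
#' @return an `mf_trace` data frame with columns `t`, `V_m`, `V_f`, `I_gap`
#'   (and the currents if requested), with attributes `regime`, `config`,
#'   `dt`, `stim_onset`.
#' @export
run_single_cell <- function(cfg, protocol = NULL, t_end = 1500, dt = 0.02,
                            equilibrate_ms = 5000, record_currents = FALSE,
                            sample_every = 1L, rush_larsen = TRUE) {
  stopifnot(inherits(cfg, "composite_config"), dt > 0, t_end > 0)
  stim <- if (is.null(protocol)) cfg$stimulus else protocol
  rest <- myocyte_resting_state(cfg$params, dt = dt)
  vf0 <- rep(cfg$fib$E_f, cfg$N_f)

  # coupled relaxation; sampled coarsely, only to classify the regime
  eq <- .cpp_run_composite(unname(rest), vf0, unclass(cfg$params),
                           cfg$fib$C_f, cfg$fib$G_f, cfg$fib$E_f, cfg$g_j,
                           cfg$C_m, stim_events(), dt, equilibrate_ms,
                           sample_every = 25L, record_currents = FALSE,
                           rush_larsen = rush_larsen)
  regime <- detect_regime(eq$V_m, eq$t)

  out <- .cpp_run_composite(eq$state, eq$V_f_final, unclass(cfg$params),
                            cfg$fib$C_f, cfg$fib$G_f, cfg$fib$E_f, cfg$g_j,
                            cfg$C_m, stim, dt, t_end,
                            sample_every = as.integer(sample_every),
                            record_currents = record_currents,
                            rush_larsen = rush_larsen)
  tr <- data.frame(t = out$t, V_m = out$V_m, V_f = out$V_f, I_gap = out$I_gap)
  if (record_currents) {
    cur <- out$currents
    colnames(cur) <- c("I_Na", "I_CaL", "I_to", "I_Ks", "I_Kr", "I_K1",
                       "I_NaCa", "I_NaK", "I_pCa", "I_pK", "I_bNa", "I_bCa",
                       "I_ion")
    tr <- cbind(tr, as.data.frame(cur))
  }
  structure(tr, class = c("mf_trace", "data.frame"), regime = regime,
            config = cfg, dt = dt * sample_every,
            stim_onset = if (nrow(stim)) min(stim[, "start"]) else NA_real_)
}

#' Classify the firing regime of an unstimulated trace
#'
#' `autorhythmic`: at least `min_upstrokes` spontaneous upstrokes (upward
#' crossings of `v_thresh` with dV/dt above `slope_thresh`); `oscillatory`:
#' no upstroke but a sustained peak-to-peak excursion larger than `osc_mV`
#' over the second half of the window (the membrane oscillates about a
#' depolarized level without ever re-crossing the threshold from below);
#' otherwise `excitable`.  Spontaneous upstrokes in the autorhythmic regime
#' are carried by the L-type calcium current (the sodium channels stay
#' inactivated at the elevated diastolic potential) and rise at well under
#' 1 mV/ms, so the slope criterion here is much lower than the 5 mV/ms used
#' for propagated sodium-driven upstrokes in [beat_statistics()].
#'
#' @param v membrane-potential samples (mV).
#' @param t sample times (ms).
#' @param v_thresh activation threshold (mV).
#' @param slope_thresh upstroke-velocity threshold (mV/ms).
#' @param min_upstrokes count defining autorhythmicity.
#' @param osc_mV peak-to-peak threshold for the oscillatory label (mV).
#' @return one of "excitable", "autorhythmic", "oscillatory".
#' @export
detect_regime <- function(v, t, v_thresh = -40, slope_thresh = 0.5,
                          min_upstrokes = 2, osc_mV = 2) {
  up <- upstroke_times(v, t, v_thresh, slope_thresh)
  if (length(up) >= min_upstrokes) return("autorhythmic")
  # judge oscillation on the second half only: the first transition after
  # coupling is a transient, not a regime
  tail_half <- v[t >= max(t) / 2]
  if (length(tail_half) > 2 && diff(range(tail_half)) > osc_mV)
    return("oscillatory")
  "excitable"
}

# upward threshold crossings with a slope criterion; returns interpolated
# crossing times
upstroke_times <- function(v, t, v_thresh = -40, slope_thresh = 5) {
  n <- length(v)
  if (n < 3) return(numeric(0))
  dt <- diff(t)
  slope <- diff(v) / dt
  idx <- which(v[-n] < v_thresh & v[-1] >= v_thresh & slope > slope_thresh)
  if (!length(idx)) return(numeric(0))
  t[idx] + (v_thresh - v[idx]) / (v[idx + 1] - v[idx]) * dt[idx]
}
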