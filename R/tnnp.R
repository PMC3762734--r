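#' TNNP 2004 myocyte model parameters
#'
#' Constant set of the ten Tusscher-Noble-Noble-Panfilov (2004) human
#' ventricular cell model, epicardial variant, as published (CellML-level
#' constants).  Every constant can be overridden by name.  Units follow the
#' model: potentials mV, time ms, concentrations mM, current densities
#' pA/pF, total capacitance `CAPACITANCE` in uF (0.185 uF = 185 pF).
#'
#' @param ... named overrides of individual constants, e.g. `Gto = 0.073`.
#' @return A named list of model constants (class `tnnp_params`).
#' @examples
#' p <- tnnp_params()
#' p$GNa
#' @export
tnnp_params <- function(...) {
  p <- list(
    R = 8314.472, T = 310.0, F = 96485.3415,
    Ko = 5.4, Cao = 2.0, Nao = 140.0,
    Vc = 0.016404, Vsr = 0.001094,
    CAPACITANCE = 0.185,
    Bufc = 0.15, Kbufc = 0.001, Bufsr = 10.0, Kbufsr = 0.3,
    taufca = 2.0, taug = 2.0, Vmaxup = 0.000425, Kup = 0.00025,
    arel = 0.016464, brel = 0.25, crel = 0.008232, Vleak = 8e-05,
    GNa = 14.838, GK1 = 5.405, Gto = 0.294, GKr = 0.096, GKs = 0.245,
    pKNa = 0.03, GCaL = 0.000175,
    knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, n_naca = 0.35,
    knak = 1.362, KmK = 1.0, KmNa = 40.0,
    GpCa = 0.825, KpCa = 0.0005, GpK = 0.0146,
    GbNa = 0.00029, GbCa = 0.000592)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown TNNP parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  structure(p, class = "tnnp_params")
}

#' Total myocyte capacitance in pF
#' @param params a [tnnp_params()] list.
#' @return capacitance in pF (used to convert gap-junctional pA to pA/pF).
#' @export
myocyte_capacitance_pF <- function(params = tnnp_params()) {
  params$CAPACITANCE * 1000
}

.state_names <- c("V", "m", "h", "j", "d", "f", "fCa", "r", "s",
                  "xr1", "xr2", "xs", "g", "Cai", "CaSR", "Nai", "Ki")
.gate_names <- c("m", "h", "j", "d", "f", "fCa", "r", "s", "xr1", "xr2",
                 "xs", "g")
.conc_names <- c("Cai", "CaSR", "Nai", "Ki")

#' Published initial (resting) state of the TNNP 2004 model
#'
#' @return named numeric vector with membrane potential `V` (mV), the eleven
#'   voltage gates plus the two calcium-dependent gates (`fCa`, `g`), and the
#'   intracellular/SR concentrations (mM).
#' @export
tnnp_initial_state <- function() {
  c(V = -86.2, m = 0.0, h = 0.75, j = 0.75, d = 0.0, f = 1.0, fCa = 1.0,
    r = 0.0, s = 1.0, xr1 = 0.0, xr2 = 1.0, xs = 0.0, g = 1.0,
    Cai = 0.0002, CaSR = 0.2, Nai = 11.6, Ki = 138.3)
}

#' Validate a myocyte state vector
#'
#' Checks the state invariants: all entries finite, gating variables in
#' \[0, 1\], concentrations strictly positive.  Errors name the offending
#' variable.
#'
#' @param state named numeric vector as returned by [tnnp_initial_state()].
#' @return the state, invisibly, if valid.
#' @export
validate_myocyte_state <- function(state) {
  if (!all(.state_names %in% names(state)))
    stop("state is missing variables: ",
         paste(setdiff(.state_names, names(state)), collapse = ", "))
  state <- state[.state_names]
  bad <- names(state)[!is.finite(state)]
  if (length(bad)) stop("non-finite state variable: ", bad[1])
  g <- state[.gate_names]
  bad <- names(g)[g < 0 | g > 1]
  if (length(bad)) stop("gating variable out of [0,1]: ", bad[1],
                        " = ", format(g[bad[1]]))
  cc <- state[.conc_names]
  bad <- names(cc)[cc <= 0]
  if (length(bad)) stop("non-positive concentration: ", bad[1])
  invisible(state)
}

#' Ionic-current breakdown of the TNNP myocyte
#'
#' Evaluates the twelve membrane current densities of the model and their sum
#' at a given state.  This is a pure function of the state: the fast sodium
#' current I_Na, L-type calcium current I_CaL, transient outward I_to, slow
#' and rapid delayed rectifiers I_Ks and I_Kr, inward rectifier I_K1, the
#' Na+/Ca2+ exchanger I_NaCa, Na+/K+ pump I_NaK, plateau currents I_pCa and
#' I_pK, and background currents I_bNa and I_bCa, all in pA/pF.
#'
#' Implemented in R from the published formulas; the compiled integrator has
#' its own evaluation, and the two are compared in the package tests.
#'
#' @param state named numeric state vector (see [tnnp_initial_state()]).
#' @param params model constants from [tnnp_params()].
#' @return named numeric vector of the 12 current densities plus `I_ion`,
#'   their sum (pA/pF).
#' @examples
#' cur <- myocyte_currents(tnnp_initial_state())
#' cur["I_ion"]   # near zero close to rest
#' @export
myocyte_currents <- function(state, params = tnnp_params()) {
  state <- validate_myocyte_state(state)
  with(c(as.list(state), unclass(params)), {
    RTONF <- R * T / F
    Ek <- RTONF * log(Ko / Ki)
    Ena <- RTONF * log(Nao / Nai)
    Eks <- RTONF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai))
    Eca <- 0.5 * RTONF * log(Cao / Cai)

    I_Na <- GNa * m^3 * h * j * (V - Ena)

    if (abs(V) < 1e-9) {
      drive <- 2 * F * (Cai - 0.341 * Cao)
    } else {
      e2 <- exp(2 * V * F / (R * T))
      drive <- 4 * V * F^2 / (R * T) * (Cai * e2 - 0.341 * Cao) / (e2 - 1)
    }
    I_CaL <- GCaL * d * f * fCa * drive

    I_to <- Gto * r * s * (V - Ek)
    I_Kr <- GKr * sqrt(Ko / 5.4) * xr1 * xr2 * (V - Ek)
    I_Ks <- GKs * xs^2 * (V - Eks)

    ak1 <- 0.1 / (1 + exp(0.06 * (V - Ek - 200)))
    bk1 <- (3 * exp(2e-04 * (V - Ek + 100)) + exp(0.1 * (V - Ek - 10))) /
      (1 + exp(-0.5 * (V - Ek)))
    I_K1 <- GK1 * sqrt(Ko / 5.4) * ak1 / (ak1 + bk1) * (V - Ek)

    vfrt <- V * F / (R * T)
    eg <- exp(n_naca * vfrt); eg1 <- exp((n_naca - 1) * vfrt)
    I_NaCa <- knaca * (1 / (KmNai^3 + Nao^3)) * (1 / (KmCa + Cao)) *
      (1 / (1 + ksat * eg1)) *
      (eg * Nai^3 * Cao - eg1 * Nao^3 * Cai * 2.5)

    rec <- 1 / (1 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt))
    I_NaK <- knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) * rec

    I_pCa <- GpCa * Cai / (KpCa + Cai)
    I_pK <- GpK * (V - Ek) / (1 + exp((25 - V) / 5.98))
    I_bNa <- GbNa * (V - Ena)
    I_bCa <- GbCa * (V - Eca)

    out <- c(I_Na = I_Na, I_CaL = I_CaL, I_to = I_to, I_Ks = I_Ks,
             I_Kr = I_Kr, I_K1 = I_K1, I_NaCa = I_NaCa, I_NaK = I_NaK,
             I_pCa = I_pCa, I_pK = I_pK, I_bNa = I_bNa, I_bCa = I_bCa)
    c(out, I_ion = sum(out))
  })
}

#' Passive fibroblast parameter set
#'
#' The fibroblast is an RC element: capacitance `C_f` (pF), membrane
#' conductance `G_f` (nS), resting potential `E_f` (mV).  Its membrane
#' current is \eqn{I_f = G_f (V_f - E_f)} (nS x mV = pA).
#'
#' @param C_f capacitance in pF (> 0).
#' @param G_f conductance in nS (>= 0).
#' @param E_f resting potential in mV, sanity window \[-100, 20\].
#' @return a `fibroblast_params` list.
#' @export
fibroblast_params <- function(C_f = 6.3, G_f = 4.0, E_f = -49.0) {
  stopifnot(is.numeric(C_f), C_f > 0, is.numeric(G_f), G_f >= 0)
  if (!is.finite(E_f) || E_f < -100 || E_f > 20)
    stop("E_f outside the sanity window [-100, 20] mV: ", E_f)
  structure(list(C_f = C_f, G_f = G_f, E_f = E_f),
            class = "fibroblast_params")
}

#' Fibroblast membrane current
#'
#' @param V_f fibroblast membrane potential (mV); may be a vector.
#' @param params a [fibroblast_params()] set.
#' @return current in pA, \eqn{G_f (V_f - E_f)} (positive = outward).
#' @examples
#' fibroblast_current(0, fibroblast_params(G_f = 4, E_f = -49))  # 196 pA
#' @export
fibroblast_current <- function(V_f, params = fibroblast_params()) {
  if (any(!is.finite(V_f))) stop("non-finite V_f")
  params$G_f * (V_f - params$E_f)
}

#' Resting state of the isolated myocyte
#'
#' Integrates the unstimulated model for `pre_run_ms` (default 5 s) from the
#' published initial values and returns the relaxed state.  Cached per
#' parameter set within the session.
#'
#' @param params [tnnp_params()] constants.
#' @param pre_run_ms unstimulated pre-run length (ms).
#' @param dt integration step (ms).
#' @return named state vector at numerical rest.
#' @export
myocyte_resting_state <- function(params = tnnp_params(), pre_run_ms = 5000,
                                  dt = 0.02) {
  key <- .cache_key("rest", unclass(params), pre_run_ms, dt)
  .cache_get(key, function() {
    out <- .cpp_run_composite(
      unname(tnnp_initial_state()[.state_names]), numeric(0),
      unclass(params), 1, 0, 0, 0, myocyte_capacitance_pF(params),
      matrix(numeric(0), 0, 3), dt, pre_run_ms,
      sample_every = max(1L, as.integer(pre_run_ms / dt)),
      record_currents = FALSE, rush_larsen = TRUE)
    stats::setNames(out$state, .state_names)
  })
}
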