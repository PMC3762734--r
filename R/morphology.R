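#' Action-potential morphology of a membrane-potential trace
#'
#' Measures the quantities used to characterise an AP: resting potential
#' `V_rest` (the pre-stimulus plateau value), maximal upstroke velocity
#' `dVdt_max` (mV/ms), peak potential `V_max`, the potential at the notch
#' `V_notch` (first local minimum after the spike), the plateau maximum
#' `V_plateau` (maximum after the notch), and the AP durations `APDx`:
#' the time from the instant of maximal upstroke velocity until the membrane
#' has repolarized to \eqn{V_{max} - x\% (V_{max} - V_{rest})}, with linear
#' interpolation of the crossing.  An AP that never repolarizes to a level
#' within the trace yields `NA` for that APD (the "-" convention).  A flat
#' trace yields regime "excitable" with all APDs `NA`.
#'
#' @param trace an `mf_trace` from [run_single_cell()], or a data frame with
#'   columns `t` and `V_m`.
#' @param percents repolarization percentages to report (default 70, 80, 90).
#' @param stim_onset stimulus time (ms); taken from the trace attribute when
#'   present.  `V_rest` is read just before this time.
#' @param upstroke_start use the time of maximal dV/dt as the APD reference
#'   start (the default); set to `"threshold"` to use the -40 mV upward
#'   crossing instead.
#' @param V_rest_ref optional external resting potential (mV) used for the
#'   repolarization levels instead of the trace's own pre-stimulus value
#'   (the coupled-vs-uncoupled comparison uses the uncoupled myocyte's rest
#'   as the common reference; see [delta_vs_uncoupled()]).
#' @param measure_every measurement-grid stride over the trace samples
#'   (morphology is read on this coarser grid; 1 = native resolution).
#' @return an `ap_morphology` list.
#' @export
measure_ap_morphology <- function(trace, percents = c(70, 80, 90),
                                  stim_onset = attr(trace, "stim_onset"),
                                  upstroke_start = c("dvdtmax", "threshold"),
                                  V_rest_ref = NULL, measure_every = 1L) {
  upstroke_start <- match.arg(upstroke_start)
  idx <- seq(1, length(trace$t), by = as.integer(measure_every))
  t <- trace$t[idx]
  v <- trace$V_m[idx]
  stopifnot(length(t) == length(v), length(t) > 2)
  regime <- attr(trace, "regime")
  if (is.null(regime)) regime <- "excitable"

  if (is.null(stim_onset) || is.na(stim_onset)) stim_onset <- t[1]
  i_pre <- max(which(t <= stim_onset))
  V_rest <- v[i_pre]
  V_level <- if (is.null(V_rest_ref)) V_rest else V_rest_ref

  dt <- diff(t)
  dvdt <- diff(v) / dt
  i_up <- which.max(dvdt)
  dVdt_max <- dvdt[i_up]

  apd <- stats::setNames(rep(NA_real_, length(percents)),
                         paste0("APD", percents))
  res <- list(V_rest = V_rest, dVdt_max = dVdt_max, V_max = NA_real_,
              V_notch = NA_real_, V_plateau = NA_real_)

  flat <- dVdt_max < 5 || max(v) < -30
  if (!flat) {
    t_up <- if (upstroke_start == "dvdtmax") t[i_up] else {
      up <- upstroke_times(v, t)
      if (length(up)) up[1] else t[i_up]
    }
    i_peak <- which.max(v[t >= t_up]) + match(TRUE, t >= t_up) - 1L
    V_max <- v[i_peak]
    res$V_max <- V_max

    # notch: first local minimum after the spike peak (within 60 ms)
    seg <- which(t > t[i_peak] & t <= t[i_peak] + 60)
    if (length(seg) > 2) {
      vs <- v[seg]
      locmin <- which(diff(sign(diff(vs))) > 0) + 1L
      if (length(locmin)) {
        i_notch <- seg[locmin[1]]
        res$V_notch <- v[i_notch]
        after <- v[t > t[i_notch]]
        if (length(after)) res$V_plateau <- max(after)
      }
    }

    amp <- V_max - V_level
    post <- which(t >= t[i_peak])
    for (k in seq_along(percents)) {
      level <- V_max - percents[k] / 100 * amp
      vv <- v[post]
      cross <- which(vv[-length(vv)] > level & vv[-1] <= level)
      if (length(cross)) {
        i1 <- post[cross[1]]
        tc <- t[i1] + (level - v[i1]) / (v[i1 + 1] - v[i1]) *
          (t[i1 + 1] - t[i1])
        apd[k] <- tc - t_up
      }
    }
  }

  structure(c(res, as.list(apd), list(regime = regime,
                                      percents = percents)),
            class = "ap_morphology")
}

#' @export
print.ap_morphology <- function(x, ...) {
  cat("AP morphology (", x$regime, ")\n", sep = "")
  cat(sprintf("  V_rest    %8.2f mV\n", x$V_rest))
  cat(sprintf("  dVdt_max  %8.2f mV/ms\n", x$dVdt_max))
  cat(sprintf("  V_max     %8.2f mV\n", x$V_max))
  cat(sprintf("  V_notch   %8.2f mV\n", x$V_notch))
  cat(sprintf("  V_plateau %8.2f mV\n", x$V_plateau))
  for (p in x$percents)
    cat(sprintf("  APD%-6d %8.2f ms\n", p, x[[paste0("APD", p)]]))
  invisible(x)
}

#' Morphology change of a composite relative to the uncoupled myocyte
#'
#' Runs the composite and the isolated myocyte through the identical one-beat
#' protocol (by default the -52 pA/pF, 3 ms stimulus at t = 50 ms) and
#' subtracts: \eqn{\Delta X = X_{coupled} - X_{uncoupled}} for APD70/80/90,
#' the maximal upstroke velocity and the resting potential.  An `NA`
#' (non-repolarizing) APD propagates as `NA`.  A composite that fires
#' spontaneously has no well-defined stimulated-beat delta and raises an
#' error.
#'
#' Measurement conventions (see the methods vignette for the rationale):
#' the fibroblasts are attached `equilibrate_ms + 50` ms before the
#' stimulus, i.e. the delta is taken on the first beat after coupling,
#' while the diastolic sodium-channel availability is still near its
#' uncoupled value -- the changes in upstroke velocity are specific to this
#' first-beat condition, since the slow inactivation gates adapt to the
#' elevated diastolic potential over the following seconds; morphology is
#' read on a 0.1 ms grid; and the repolarization levels of *both* runs are
#' referenced to the uncoupled myocyte's resting potential, the common
#' baseline against which the change is defined -- a composite whose
#' diastolic potential stays above an APD level then reports that duration
#' as undefined.
#'
#' @param cfg a [composite_config()].
#' @param protocol stimulus schedule applied to both runs.
#' @param t_end,dt,equilibrate_ms integration settings, see
#'   [run_single_cell()].
#' @param measure_every measurement-grid stride (samples), see
#'   [measure_ap_morphology()].
#' @return an `ap_delta` list: `dAPD70`, `dAPD80`, `dAPD90` (ms),
#'   `d_dVdt_max` (mV/ms), `dV_rest` (mV) plus both morphologies.
#' @export
delta_vs_uncoupled <- function(cfg,
                               protocol = stim_events(50, 3, -52),
                               t_end = 1500, dt = 0.02,
                               equilibrate_ms = 50, measure_every = 5L) {
  stopifnot(inherits(cfg, "composite_config"))
  coupled <- run_single_cell(cfg, protocol, t_end = t_end, dt = dt,
                             equilibrate_ms = equilibrate_ms)
  if (attr(coupled, "regime") != "excitable")
    stop("composite is ", attr(coupled, "regime"),
         ": stimulated-beat deltas are not defined")
  # the uncoupled reference is cached per (params, protocol) fingerprint
  key <- .cache_key("uncoupled-ap", unclass(cfg$params), protocol, t_end, dt,
                    equilibrate_ms, measure_every)
  m0 <- .cache_get(key, function() {
    cfg0 <- composite_config(N_f = 0, g_j = 0, fib = cfg$fib,
                             C_m = cfg$C_m, params = cfg$params)
    measure_ap_morphology(run_single_cell(cfg0, protocol, t_end = t_end,
                                          dt = dt,
                                          equilibrate_ms = equilibrate_ms),
                          measure_every = measure_every)
  })
  m1 <- measure_ap_morphology(coupled, V_rest_ref = m0$V_rest,
                              measure_every = measure_every)
  structure(list(
    dAPD70 = m1$APD70 - m0$APD70,
    dAPD80 = m1$APD80 - m0$APD80,
    dAPD90 = m1$APD90 - m0$APD90,
    d_dVdt_max = m1$dVdt_max - m0$dVdt_max,
    dV_rest = m1$V_rest - m0$V_rest,
    coupled = m1, uncoupled = m0), class = "ap_delta")
}

#' @export
print.ap_delta <- function(x, ...) {
  cat("AP change, composite minus uncoupled myocyte\n")
  cat(sprintf("  dAPD70     %8.2f ms\n", x$dAPD70))
  cat(sprintf("  dAPD80     %8.2f ms\n", x$dAPD80))
  cat(sprintf("  dAPD90     %8.2f ms\n", x$dAPD90))
  cat(sprintf("  d(dV/dt)max%8.2f mV/ms\n", x$d_dVdt_max))
  cat(sprintf("  dV_rest    %8.2f mV\n", x$dV_rest))
  invisible(x)
}
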