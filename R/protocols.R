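#' Plane-wave conduction-velocity experiment
#'
#' Stimulates the left boundary (a 3-node-wide column) with a 150 pA/pF,
#' 3 ms pulse and measures the conduction velocity between two midline
#' probes at 25% and 75% of the domain length.  Conduction failure is
#' declared when the far probe never depolarizes above the activation
#' threshold within a time budget of `2 L / CV_control`.
#'
#' @param coupling a [coupling_config()]; set `G_gap = 0` and
#'   `fibroblasts = FALSE` for the myocyte-only control.
#' @param nx,ny grid size (a thin strip, e.g. 600 x 7, is sufficient).
#' @param dx lattice spacing (mm).
#' @param dt step (ms).
#' @param fibroblasts attach the fibroblast layer?
#' @param amplitude stimulus strength (pA/pF, depolarizing).
#' @param cv_control_cm_s reference CV used only to size the time budget.
#' @param threshold activation threshold (mV).
#' @return list: `cv_cm_s`, `failed`, `probes` (data frame), `grid`.
#' @export
run_plane_wave <- function(coupling = coupling_config(), nx = 600, ny = 7,
                           dx = 0.225, dt = 0.02, fibroblasts = TRUE,
                           amplitude = 150, cv_control_cm_s = 68.3,
                           threshold = -40) {
  grid <- bilayer_grid(nx, ny, dx = dx, coupling = coupling,
                       fibroblasts = fibroblasts)
  L_mm <- (nx - 1) * dx
  t_budget <- 2 * L_mm / (cv_control_cm_s / 100)   # ms
  i1 <- round(0.25 * (nx - 1)); i2 <- round(0.75 * (nx - 1))
  jmid <- (ny - 1) %/% 2
  stim <- tissue_stimulus(0, 3, amplitude, rect = c(0, 2, 0, ny - 1))
  run <- run_tissue(grid, t_budget, stimuli = list(stim), dt = dt,
                    probes = rbind(c(i1, jmid), c(i2, jmid)),
                    sample_every = 5L)
  cv <- measure_cv(run$probes$t, run$probes$V_m_1, run$probes$V_m_2,
                   distance_mm = (i2 - i1) * dx, threshold = threshold)
  list(cv_cm_s = cv$cv_cm_s, failed = cv$failed, probes = run$probes,
       grid = run$grid)
}

#' S1-S2 parallel-field spiral-initiation protocol
#'
#' The domain (myocytes only during initiation) is driven with an S1 pulse
#' (150 pA/pF, 3 ms) along the left boundary at t = 0 while the diffusion
#' coefficient is reduced to a quarter of its nominal value; at `s2_time`
#' an S2 pulse (450 pA/pF, 3 ms) is applied over the lower half-height of
#' the domain, from the left edge up to `margin_nodes` nodes behind the
#' -40 mV isoline of the S1 wave back (found at S2 time on the lower-half
#' midline); D is restored at `d_restore_time`; the run continues to
#' `t_init`, by when the broken wave has curled into a fully developed
#' spiral.  At full scale (600 x 600) the printed timings are
#' `s2_time = 560` ms and `d_restore_time = 882` ms.
#'
#' @param s1_amp,s1_dur,s2_amp,s2_dur stimulus strengths (pA/pF) and
#'   durations (ms).
#' @param s2_time S2 onset (ms).
#' @param d_restore_time time at which D returns to nominal (ms).
#' @param d_factor reduction factor during initiation (quarter of nominal).
#' @param margin_nodes gap between the wave-back isoline and the S2 edge.
#' @param t_init end of the initiation run (ms).
#' @return a `spiral_protocol` list.
#' @export
spiral_protocol <- function(s1_amp = 150, s1_dur = 3, s2_amp = 450,
                            s2_dur = 3, s2_time = 560,
                            d_restore_time = 882, d_factor = 0.25,
                            margin_nodes = 2, t_init = 1500) {
  stopifnot(s2_time > s1_dur, d_restore_time > s2_time, t_init > d_restore_time)
  structure(list(s1_amp = s1_amp, s1_dur = s1_dur, s2_amp = s2_amp,
                 s2_dur = s2_dur, s2_time = s2_time,
                 d_restore_time = d_restore_time, d_factor = d_factor,
                 margin_nodes = margin_nodes, t_init = t_init),
            class = "spiral_protocol")
}

#' Scaled-down spiral domain
#'
#' Desk-scale analogue of the full 600 x 600 spiral experiments.  The
#' monodomain equation is spatially self-similar: halving the node count at
#' fixed lattice spacing while dividing D by four leaves the dynamics
#' unchanged, because space enters only through \eqn{\sqrt{D}}.  A 200 x 200
#' grid with D/9 therefore evolves exactly like the full 135 mm domain
#' sampled at 3 x coarser effective spacing (0.675 mm); rotation periods,
#' protocol timings, and all single-composite dynamics (which D does not
#' touch) carry over verbatim, at the cost of a coarser spatial resolution
#' of the wave front.  The full-scale [spiral_protocol()] timings apply
#' unchanged on such a grid.
#'
#' @param nx nodes per side of the reduced square domain.
#' @param coupling a [coupling_config()] whose `D` is the full-scale value;
#'   it is divided by `(600/nx)^2`.
#' @param dx lattice spacing (mm).
#' @param fibroblasts attach the fibroblast layer?
#' @return a [bilayer_grid()] with the rescaled diffusion coefficient.
#' @export
scaled_spiral_grid <- function(nx = 200, coupling = coupling_config(G_gap = 0),
                               dx = 0.225, fibroblasts = FALSE) {
  s <- 600 / nx
  coupling$D <- coupling$D / s^2
  bilayer_grid(nx, nx, dx = dx, coupling = coupling,
               fibroblasts = fibroblasts)
}

#' S1-S2 protocol variant for the rescaled domain
#'
#' On a [scaled_spiral_grid()] the domain is already large relative to the
#' spiral (the rescaling shrinks the wavelength with the domain), so the
#' transient diffusion reduction that the full-scale protocol needs to trap
#' the proto-spiral hook is unnecessary -- and the coarser effective lattice
#' slows reduced-D propagation disproportionately, which distorts the
#' protocol's timing geometry.  This variant keeps D constant and applies S2
#' when the S1 wave back sits at the same fractional position as in the
#' full-scale protocol.
#'
#' @param s2_time S2 onset (ms).
#' @param t_init end of initiation (ms).
#' @param ... further overrides passed to [spiral_protocol()].
#' @return a `spiral_protocol`.
#' @export
spiral_protocol_scaled <- function(s2_time = 460, t_init = 1500, ...) {
  spiral_protocol(s2_time = s2_time, d_restore_time = s2_time + 1,
                  d_factor = 1, t_init = t_init, ...)
}

#' Initiate a spiral wave
#'
#' Runs the S1-S2 parallel-field protocol on the myocyte layer of `grid`
#' (gap coupling is held off during initiation by the protocol's design:
#' the paper-level procedure initializes the spiral in a myocyte sheet and
#' attaches fibroblasts afterwards -- use [attach_fibroblasts()] on the
#' result).  If no wave break occurs (S2 outside the vulnerable window) the
#' returned `tips` count is 0.
#'
#' @param grid a [bilayer_grid()]; typically built with
#'   `fibroblasts = FALSE`.
#' @param protocol a [spiral_protocol()].
#' @param dt step (ms).
#' @param verify track the tip on the final frame to report `n_tips`.
#' @return list: `grid` (state at `t_init`), `s2_rect` (node rectangle
#'   used), `n_tips` (or `NA` if `verify = FALSE`).
#' @export
initiate_spiral <- function(grid, protocol, dt = 0.02, verify = TRUE) {
  stopifnot(inherits(grid, "bilayer_grid"),
            inherits(protocol, "spiral_protocol"))
  p <- protocol
  dsched <- rbind(c(grid$t, p$d_factor), c(p$d_restore_time, 1))
  s1 <- tissue_stimulus(grid$t, p$s1_dur, p$s1_amp,
                        rect = c(0, 2, 0, grid$ny - 1))
  # phase 1: S1 propagation until S2 time
  r1 <- run_tissue(grid, grid$t + p$s2_time, stimuli = list(s1), dt = dt,
                   d_schedule = dsched, sample_every = 50L)
  g <- r1$grid
  # locate the -40 mV wave-back isoline on the lower-half midline
  vm <- matrix(g$state[, "V"], g$nx, g$ny)
  jrow <- max(1L, round(g$ny / 4))
  prof <- vm[, jrow]
  wb <- which(prof[-g$nx] < -40 & prof[-1] >= -40)
  if (!length(wb)) {
    warning("no S1 wave back found at S2 time; S2 lands on recovered tissue")
    i_hi <- g$nx %/% 2
  } else {
    i_hi <- max(1L, wb[1] - p$margin_nodes)
  }
  s2_rect <- c(0, i_hi - 1L, 0, (g$ny %/% 2) - 1L)
  s2 <- tissue_stimulus(g$t, p$s2_dur, p$s2_amp, rect = s2_rect)
  r2 <- run_tissue(g, grid$t + p$t_init, stimuli = list(s2), dt = dt,
                   d_schedule = dsched,
                   snapshot_times = grid$t + p$t_init,
                   snapshot_fields = c("V_m", "I_Na"), sample_every = 50L)
  n_tips <- NA_integer_
  if (verify) {
    traj <- track_tip(r2$snapshots, params = g$coupling$params)
    n_tips <- as.integer(traj$n_tips[nrow(traj)])
  }
  list(grid = r2$grid, s2_rect = s2_rect, n_tips = n_tips)
}

#' Attach the fibroblast layer to an initialized grid
#'
#' Used after [initiate_spiral()]: switches the grid to the given coupling,
#' turns the fibroblast mask on everywhere and sets every fibroblast to its
#' resting potential `E_f` (the initial condition used for the composite
#' tissue studies).
#'
#' @param grid a `bilayer_grid` (e.g. carrying a developed spiral).
#' @param coupling a [coupling_config()].
#' @return the modified grid.
#' @export
attach_fibroblasts <- function(grid, coupling) {
  stopifnot(inherits(grid, "bilayer_grid"),
            inherits(coupling, "coupling_config"))
  grid$coupling <- coupling
  grid$mask[] <- TRUE
  grid$ggap[] <- coupling$G_gap
  grid$vf[] <- coupling$fib$E_f
  grid
}

#' Mesh geometry and pulse for low-amplitude spiral control
#'
#' The control scheme applies a long low-amplitude pulse on a mesh of grid
#' lines that partitions the domain into `blocks` x `blocks` square cells
#' (at full scale: 16 cells of side 33.75 mm; pulse 30 pA/pF for 400 ms).
#' The driven lines are held refractory, act as absorbing (no-flux-like)
#' internal boundaries, and the spiral is extinguished cell by cell.
#'
#' @param blocks cells per side.
#' @param amplitude pulse strength (pA/pF, depolarizing).
#' @param duration pulse length (ms).
#' @param line_width mesh line width in nodes.
#' @return a `control_mesh` list.
#' @export
control_mesh <- function(blocks = 4, amplitude = 30, duration = 400,
                         line_width = 1) {
  stopifnot(blocks >= 1, duration > 0)
  structure(list(blocks = blocks, amplitude = amplitude,
                 duration = duration, line_width = line_width),
            class = "control_mesh")
}

.mesh_nodes <- function(grid, mesh) {
  lines <- round(seq(0, grid$nx - 1, length.out = mesh$blocks + 1))
  ids <- integer(0)
  for (l in lines) {
    for (w in seq_len(mesh$line_width) - 1L) {
      i <- min(grid$nx - 1L, l + w)
      ids <- c(ids, .node_id(grid, i, 0:(grid$ny - 1L)))
      j <- min(grid$ny - 1L, l + w)
      ids <- c(ids, .node_id(grid, 0:(grid$nx - 1L), j))
    }
  }
  unique(ids)
}

#' Run the mesh-based control experiment
#'
#' Applies the mesh pulse to a grid carrying a spiral and steps forward in
#' chunks, watching for termination: the first time no myocyte is above the
#' activation threshold, and no re-excitation occurs for `quiet_ms`
#' afterwards, the spiral is declared terminated.
#'
#' @param grid a `bilayer_grid` with a spiral present.
#' @param mesh a [control_mesh()]; use `amplitude = 0` for the null control.
#' @param t_max how long to watch (ms) beyond the pulse onset.
#' @param quiet_ms required quiescence after the last activity (ms).
#' @param threshold activation threshold (mV).
#' @param dt step (ms).
#' @param chunk_ms chunk length between termination checks (ms).
#' @return list: `outcome` ("terminated"/"persisted"), `t_terminated`
#'   (absolute ms, `NA` if persisted), `grid`.
#' @export
run_control <- function(grid, mesh, t_max = 1000, quiet_ms = 200,
                        threshold = -40, dt = 0.02, chunk_ms = 25) {
  stopifnot(inherits(grid, "bilayer_grid"), inherits(mesh, "control_mesh"))
  t0 <- grid$t
  stimuli <- if (mesh$amplitude > 0)
    list(tissue_stimulus(t0, mesh$duration, mesh$amplitude,
                         nodes = .mesh_nodes(grid, mesh)))
  else list()
  quiet_since <- NA_real_
  while (grid$t < t0 + t_max) {
    nxt <- min(t0 + t_max, grid$t + chunk_ms)
    grid <- run_tissue(grid, nxt, stimuli = stimuli, dt = dt,
                       sample_every = 1000L)$grid
    active <- max(grid$state[, "V"]) > threshold
    in_pulse <- mesh$amplitude > 0 && grid$t < t0 + mesh$duration
    if (!active && !in_pulse) {
      if (is.na(quiet_since)) quiet_since <- grid$t
      if (grid$t - quiet_since >= quiet_ms)
        return(list(outcome = "terminated", t_terminated = quiet_since - t0,
                    grid = grid))
    } else {
      quiet_since <- NA_real_
    }
  }
  list(outcome = "persisted", t_terminated = NA_real_, grid = grid)
}
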