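#' Intercellular coupling configuration for the bilayer tissue
#'
#' The tissue is a myocyte monolayer (monodomain diffusion with coefficient
#' `D`, cm^2/ms) carrying a fibroblast layer.  At each node the local MF
#' composite is coupled through the on-site conductance `G_gap` (nS).  The
#' lateral wiring comes in three categories:
#' \describe{
#'   \item{zero_sided}{fibroblasts present but not laterally connected
#'     (`G_ff = G_mf = G_fm = 0`);}
#'   \item{one_sided}{the fibroblast layer is internally connected through
#'     `G_ff` (nS) but has no cross-layer neighbour links;}
#'   \item{two_sided}{in addition, every myocyte exchanges current with its
#'     four neighbouring fibroblast nodes and vice versa.  The myocyte-side
#'     junctions carry `G_mf` and the fibroblast-side junctions `G_fm`
#'     (both nS), so each myocyte/fibroblast neighbour pair exchanges the
#'     exactly antisymmetric current \eqn{(G_{mf}+G_{fm})(V_f - V_m)};
#'     current conservation requires both to be nonzero together.}
#' }
#'
#' @param mode one of "zero_sided", "one_sided", "two_sided".
#' @param D myocyte-layer diffusion coefficient (cm^2/ms).
#' @param G_gap on-site myocyte-fibroblast conductance (nS).
#' @param G_ff fibroblast-fibroblast lateral conductance (nS).
#' @param G_mf,G_fm cross-layer neighbour conductances (nS).
#' @param fib [fibroblast_params()].
#' @param C_m myocyte capacitance (pF).
#' @param params ionic model constants.
#' @return a `coupling_config` list.
#' @export
coupling_config <- function(mode = c("zero_sided", "one_sided", "two_sided"),
                            D = 0.00154, G_gap = 8, G_ff = 0, G_mf = 0,
                            G_fm = 0, fib = fibroblast_params(),
                            C_m = myocyte_capacitance_pF(params),
                            params = tnnp_params()) {
  mode <- match.arg(mode)
  stopifnot(D > 0, G_gap >= 0, G_ff >= 0, G_mf >= 0, G_fm >= 0)
  if (mode == "zero_sided" && (G_ff != 0 || G_mf != 0 || G_fm != 0))
    stop("zero_sided coupling requires G_ff = G_mf = G_fm = 0")
  if (mode == "one_sided" && (G_mf != 0 || G_fm != 0))
    stop("one_sided coupling requires G_mf = G_fm = 0")
  if (mode == "two_sided" && xor(G_mf > 0, G_fm > 0))
    stop("two_sided coupling: G_mf and G_fm must be nonzero together ",
         "(current conservation)")
  structure(list(mode = mode, D = D, G_gap = G_gap, G_ff = G_ff,
                 G_mf = G_mf, G_fm = G_fm, fib = fib, C_m = C_m,
                 params = params),
            class = "coupling_config")
}

#' Construct a 2D bilayer grid
#'
#' Builds an `nx` by `ny` lattice with spacing `dx` (mm); node (i, j)
#' (0-based) sits at physical position (i dx, j dx).  Every myocyte starts
#' at the cached resting state of the isolated cell and every fibroblast at
#' `E_f`.  With `fibroblasts = FALSE` the grid is a myocyte-only control
#' sheet (empty fibroblast mask).
#'
#' @param nx,ny node counts (>= 3).
#' @param dx lattice spacing (mm).
#' @param coupling a [coupling_config()].
#' @param fibroblasts logical: attach the fibroblast layer?
#' @return a `bilayer_grid` object (state matrix, fibroblast field, mask,
#'   per-node `G_gap`, clock `t`).
#' @export
bilayer_grid <- function(nx, ny, dx = 0.225, coupling = coupling_config(),
                         fibroblasts = TRUE) {
  stopifnot(nx >= 3, ny >= 3, dx > 0, inherits(coupling, "coupling_config"))
  nn <- as.integer(nx) * as.integer(ny)
  rest <- myocyte_resting_state(coupling$params)
  state <- matrix(rep(unname(rest), each = nn), nrow = nn,
                  dimnames = list(NULL, .state_names))
  mask <- rep(isTRUE(fibroblasts), nn)
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 coupling = coupling, state = state,
                 vf = rep(coupling$fib$E_f, nn), mask = mask,
                 ggap = ifelse(mask, coupling$G_gap, 0), t = 0),
            class = "bilayer_grid")
}

# node id (1-based, column-major with nx rows) from 0-based indices
.node_id <- function(grid, i, j) as.integer(j) * grid$nx + as.integer(i) + 1L

#' Square MF-composite inhomogeneity
#'
#' Describes a square patch (lower-left corner and side in mm) inside which
#' the grid carries MF composites with the given coupling; outside the patch
#' the tissue is myocyte-only.  Corner and side are mapped to nodes by
#' rounding `mm / dx` to the nearest integer.
#'
#' @param corner_mm length-2 numeric, lower-left corner (mm).
#' @param side_mm side length (mm); 0 means no patch.
#' @param coupling [coupling_config()] used inside the patch.
#' @return an `inhomogeneity_spec` list.
#' @export
inhomogeneity_spec <- function(corner_mm, side_mm, coupling = coupling_config()) {
  stopifnot(length(corner_mm) == 2, side_mm >= 0)
  structure(list(corner_mm = corner_mm, side_mm = side_mm,
                 coupling = coupling), class = "inhomogeneity_spec")
}

#' Apply an inhomogeneity patch to a grid
#'
#' Turns the fibroblast mask on inside the patch (with the patch coupling)
#' and off outside; outside nodes have `G_gap = 0` and no fibroblast
#' dynamics.  A zero-side patch leaves the grid unchanged.
#'
#' @param grid a [bilayer_grid()].
#' @param spec an [inhomogeneity_spec()].
#' @return the modified grid.
#' @export
set_patch <- function(grid, spec) {
  stopifnot(inherits(grid, "bilayer_grid"),
            inherits(spec, "inhomogeneity_spec"))
  if (spec$side_mm == 0) return(grid)
  i0 <- round(spec$corner_mm[1] / grid$dx)
  j0 <- round(spec$corner_mm[2] / grid$dx)
  ns <- round(spec$side_mm / grid$dx)
  if (i0 < 0 || j0 < 0 || i0 + ns > grid$nx || j0 + ns > grid$ny)
    stop("patch extends outside the domain")
  grid$coupling <- spec$coupling
  grid$mask[] <- FALSE
  grid$ggap[] <- 0
  idx <- as.vector(outer((i0:(i0 + ns - 1L)) + 1L,
                         (j0:(j0 + ns - 1L)) * grid$nx, `+`))
  grid$mask[idx] <- TRUE
  grid$ggap[idx] <- spec$coupling$G_gap
  grid$vf <- rep(spec$coupling$fib$E_f, length(grid$vf))
  grid$patch <- list(i0 = i0, j0 = j0, nodes = ns,
                     bbox_mm = c(spec$corner_mm,
                                 spec$corner_mm + spec$side_mm))
  grid
}

#' Five-point Laplacian with no-flux boundaries
#'
#' Ghost nodes mirror the edge values (zero normal flux), which is the same
#' as summing differences to in-grid neighbours only.
#'
#' @param field numeric matrix.
#' @param dx lattice spacing (the result is divided by `dx^2`).
#' @return matrix of the same shape.
#' @export
laplacian_noflux <- function(field, dx = 1) {
  stopifnot(is.matrix(field), nrow(field) >= 3, ncol(field) >= 3)
  nx <- nrow(field); ny <- ncol(field)
  up    <- field[c(1, 1:(nx - 1)), ]
  down  <- field[c(2:nx, nx), ]
  left  <- field[, c(1, 1:(ny - 1))]
  right <- field[, c(2:ny, ny)]
  (up + down + left + right - 4 * field) / dx^2
}

#' Spatial stimulus for tissue runs
#'
#' `amplitude` is the depolarizing strength in pA/pF as quoted for tissue
#' protocols (a positive number); internally it enters the membrane equation
#' as \eqn{I_{stim} = -amplitude}.  The support is either a node-index
#' rectangle (0-based, inclusive) or an explicit vector of node ids.
#'
#' @param start onset (ms).
#' @param duration duration (ms, > 0).
#' @param amplitude depolarizing strength (pA/pF).
#' @param rect integer vector `c(i0, i1, j0, j1)` (0-based, inclusive), or
#'   `NULL` when `nodes` is given.
#' @param nodes explicit 1-based node ids (column-major), alternative to
#'   `rect`.
#' @return a `tissue_stimulus` list.
#' @export
tissue_stimulus <- function(start, duration, amplitude, rect = NULL,
                            nodes = NULL) {
  stopifnot(duration > 0, xor(is.null(rect), is.null(nodes)))
  structure(list(start = start, dur = duration, amp = -amplitude,
                 rect = rect, nodes = nodes), class = "tissue_stimulus")
}

.stim_nodes <- function(stim, grid) {
  if (!is.null(stim$nodes)) return(as.integer(stim$nodes) - 1L)
  r <- stim$rect
  if (r[1] < 0 || r[3] < 0 || r[2] >= grid$nx || r[4] >= grid$ny)
    stop("stimulus support outside the grid")
  as.integer(as.vector(outer((r[1]:r[2]), (r[3]:r[4]) * grid$nx, `+`)))
}

# explicit-stability check for the forward-Euler scheme
.check_stability <- function(grid, dt) {
  cp <- grid$coupling
  dxcm <- grid$dx * 0.1
  if (dt > dxcm^2 / (4 * cp$D))
    stop(sprintf("dt = %g ms violates the diffusion stability bound %g ms",
                 dt, dxcm^2 / (4 * cp$D)))
  # fibroblast relaxation rate (worst case: all couplings active)
  rate <- (cp$fib$G_f + max(grid$ggap) + 4 * cp$G_ff +
           4 * (cp$G_mf + cp$G_fm)) / cp$fib$C_f
  if (rate > 0 && dt > 2 / rate)
    stop(sprintf("dt = %g ms unstable for the fibroblast layer (limit %g ms)",
                 dt, 2 / rate))
  invisible(TRUE)
}

#' Advance a bilayer grid in time
#'
#' Forward-Euler stepping of the coupled layers (fixed row-major traversal:
#' runs are reproducible bit for bit).  Optionally records probe traces,
#' field snapshots (`V_m`, and `V_f` / `I_Na` on request) at given times,
#' and supports a piecewise-constant schedule of diffusion multipliers
#' (used by the spiral-initiation protocol).
#'
#' @param grid a [bilayer_grid()].
#' @param t_end absolute end time (ms); stepping starts at `grid$t`.
#' @param stimuli list of [tissue_stimulus()] (times are absolute).
#' @param dt step (ms); checked against the explicit stability bound.
#' @param probes 2-column matrix of 0-based `(i, j)` node indices, or `NULL`.
#' @param sample_every probe sampling stride in steps.
#' @param snapshot_times absolute times (ms) at which to store fields.
#' @param snapshot_fields subset of `c("V_m", "V_f", "I_Na")`.  The `I_Na`
#'   field stores the peak |I_Na| per node over the `ina_hold` ms preceding
#'   each snapshot: the instantaneous sodium-current line of a travelling
#'   front can be narrower than one lattice cell, and the short hold paints
#'   it as a contiguous line for the tip tracker.
#' @param ina_hold hold window (ms) for the `I_Na` snapshot field.
#' @param d_schedule matrix with columns (from-time ms, multiplier) applied
#'   to `D`, or `NULL`.
#' @param pure_diffusion disable all reactions and couplings (diffusion-only
#'   stepping of `V_m`; used for conservation checks).
#' @return a `tissue_run` list: `grid` (advanced), `probes` (data frame),
#'   `snapshots` (an `mf_archive`), `t_end`.
#' @export
run_tissue <- function(grid, t_end, stimuli = list(), dt = 0.02,
                       probes = NULL, sample_every = 1L,
                       snapshot_times = numeric(0),
                       snapshot_fields = "V_m", ina_hold = 2,
                       d_schedule = NULL, pure_diffusion = FALSE) {
  stopifnot(inherits(grid, "bilayer_grid"), t_end > grid$t)
  .check_stability(grid, dt)
  cp <- grid$coupling
  if (is.null(probes)) probes <- matrix(integer(0), 0, 2)
  probe_ids <- if (nrow(probes)) .node_id(grid, probes[, 1], probes[, 2]) - 1L
               else integer(0)
  stim_list <- lapply(stimuli, function(s)
    list(start = s$start, dur = s$dur, amp = s$amp,
         idx = .stim_nodes(s, grid)))
  if (is.null(d_schedule)) d_schedule <- matrix(numeric(0), 0, 2)

  opts <- list(nx = grid$nx, ny = grid$ny, dx_mm = grid$dx, D = cp$D,
               dt = dt, Cm = cp$C_m, Cf = cp$fib$C_f, Gf = cp$fib$G_f,
               Ef = cp$fib$E_f, Gff = cp$G_ff, Gmf = cp$G_mf, Gfm = cp$G_fm,
               pure_diffusion = isTRUE(pure_diffusion),
               sample_every = as.integer(sample_every),
               probes = as.integer(probe_ids),
               snap_times = as.numeric(snapshot_times),
               snap_vf = "V_f" %in% snapshot_fields,
               snap_ina = "I_Na" %in% snapshot_fields,
               ina_hold = ina_hold,
               d_schedule = d_schedule)

  out <- .cpp_run_tissue(grid$state, grid$vf, grid$mask, grid$ggap,
                         unclass(cp$params), opts, stim_list,
                         grid$t, t_end)

  grid$state <- out$state
  colnames(grid$state) <- .state_names
  grid$vf <- out$vf
  grid$t <- out$t_end

  pr <- data.frame(t = out$probe_t)
  if (length(probe_ids)) {
    vm <- out$probe_vm
    colnames(vm) <- paste0("V_m_", seq_len(ncol(vm)))
    pr <- cbind(pr, vm)
    if (any(grid$mask)) {
      vf <- out$probe_vf
      colnames(vf) <- paste0("V_f_", seq_len(ncol(vf)))
      pr <- cbind(pr, vf)
    }
  }

  arch <- NULL
  if (length(snapshot_times)) {
    frames <- lapply(seq_along(out$snap_t), function(k) {
      fr <- list(V_m = out$snap_vm[[k]])
      if (opts$snap_vf && !is.null(out$snap_vf[[k]])) fr$V_f <- out$snap_vf[[k]]
      if (opts$snap_ina) fr$I_Na <- out$snap_ina[[k]]
      fr
    })
    arch <- snapshot_archive(out$snap_t, frames, grid$nx, grid$ny, grid$dx)
  }

  structure(list(grid = grid, probes = pr, snapshots = arch,
                 t_end = out$t_end), class = "tissue_run")
}

#' Single tissue step
#'
#' Convenience wrapper: advances the grid by `n_steps` of size `dt`.
#'
#' @inheritParams run_tissue
#' @param n_steps number of steps.
#' @return the advanced `bilayer_grid`.
#' @export
step_tissue <- function(grid, stimuli = list(), dt = 0.02, n_steps = 1L) {
  run_tissue(grid, grid$t + dt * n_steps, stimuli = stimuli, dt = dt)$grid
}
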