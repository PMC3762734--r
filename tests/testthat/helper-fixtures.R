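# Shared, lazily computed fixtures.  The spiral runs are the expensive part
# of the suite; they are computed once per session and reused by the
# protocol, analysis and acceptance tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, compute(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# developed control spiral on the rescaled 200x200 domain (myocytes only)
spiral_fixture <- function() {
  fixture("spiral200", function() {
    grid <- scaled_spiral_grid(200)
    initiate_spiral(grid, spiral_protocol_scaled(), verify = FALSE)
  })
}

# control-case spiral continuation with probe + snapshot record (shared by
# the tracker-agreement, period and acceptance tests)
spiral_run_fixture <- function() {
  fixture("spiral200_run", function() {
    g <- spiral_fixture()$grid
    # regular 25 ms frames for trajectory/period work, plus two bursts of
    # 2 ms-spaced frames: the isopotential cross-check tracker needs the
    # finite-difference dV/dt over a short interval (over 25 ms it locates
    # the rotation centre, not the instantaneous tip).  On burst frames the
    # sodium-current line is too short for endpoint tracking, so the
    # trajectory tests use the regular frames only.
    t_reg <- seq(g$t + 25, g$t + 1150, by = 25)
    t_burst <- g$t + c(501, 503, 505, 507, 509, 601, 603, 605, 607, 609)
    times <- sort(unique(c(t_reg, t_burst)))
    run <- run_tissue(g, g$t + 1150, probes = rbind(c(160L, 160L)),
                      snapshot_times = times,
                      snapshot_fields = c("V_m", "I_Na"), sample_every = 10L)
    list(run = run, regular = run$snapshots$t %in% t_reg)
  })
}

# subset of an archive by frame index
archive_subset <- function(a, idx) {
  snapshot_archive(a$t[idx], a$frames[idx], a$nx, a$ny, a$dx, a$meta)
}

# rotation period for a zero-sided MF sheet at a given G_gap, from the
# shared spiral initial condition (3+ rotations observed at a probe)
spiral_period <- function(ggap) {
  fixture(paste0("period_", ggap), function() {
    g <- spiral_fixture()$grid
    if (ggap > 0) {
      g <- attach_fibroblasts(g, coupling_config("zero_sided", G_gap = ggap,
                                                 D = g$coupling$D))
    }
    run <- run_tissue(g, g$t + 1150, probes = rbind(c(160L, 160L)),
                      sample_every = 10L)
    rotation_period(beat_statistics(run$probes$V_m_1, 0.2))
  })
}

# a synthetic triangle-pulse "action potential" whose morphology has a
# closed form: rest, linear rise, linear plateau decay, linear tail
synthetic_ap <- function(dt = 0.1) {
  t <- seq(0, 500, by = dt)
  v <- rep(-80, length(t))
  rise <- t >= 50 & t < 52          # -80 -> +40 over 2 ms (60 mV/ms)
  v[rise] <- -80 + (t[rise] - 50) * 60
  fall <- t >= 52 & t < 352         # +40 -> -80 over 300 ms (-0.4 mV/ms)
  v[fall] <- 40 - (t[fall] - 52) * 0.4
  structure(data.frame(t = t, V_m = v),
            class = c("mf_trace", "data.frame"),
            regime = "excitable", stim_onset = 50, dt = dt)
}

# paired mesh-control outcomes on the zero-sided MF sheet (shared by the
# protocol and acceptance tests)
control_outcomes <- function() {
  fixture("control_pair", function() {
    g <- spiral_fixture()$grid
    g <- attach_fibroblasts(g, coupling_config("zero_sided", G_gap = 8,
                                               D = g$coupling$D))
    list(ctl = run_control(g, control_mesh(blocks = 4, amplitude = 30,
                                           duration = 400), t_max = 900),
         null = run_control(g, control_mesh(blocks = 4, amplitude = 0,
                                            duration = 400), t_max = 700))
  })
}
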