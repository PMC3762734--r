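test_that("no-flux Laplacian: constant field, interior spike, edges", {
  f <- matrix(3.7, 8, 6)
  expect_true(all(laplacian_noflux(f, 0.5) == 0))
  f <- matrix(0, 7, 7)
  f[4, 4] <- 1
  l <- laplacian_noflux(f, 2)
  expect_equal(l[4, 4], -4 / 4)
  expect_equal(l[3, 4], 1 / 4)
  expect_equal(l[4, 5], 1 / 4)
  expect_equal(sum(l), 0)          # mirrored ghosts conserve the integral
})

test_that("pure diffusion conserves the field integral to 1e-10 per 1000 steps", {
  grid <- bilayer_grid(40, 40, coupling = coupling_config(G_gap = 0),
                       fibroblasts = FALSE)
  # radially symmetric pulse
  vm <- outer(1:40, 1:40, function(i, j) -86 + 60 * exp(-((i - 20)^2 + (j - 20)^2) / 20))
  grid$state[, "V"] <- as.vector(vm)
  s0 <- sum(grid$state[, "V"])
  run <- run_tissue(grid, 1000 * 0.02, pure_diffusion = TRUE,
                    sample_every = 1000L)
  s1 <- sum(run$grid$state[, "V"])
  expect_lt(abs(s1 - s0) / abs(s0), 1e-10)
})

test_that("zero-sided sheet with G_gap = 0 equals the myocyte-only control bitwise", {
  stim <- tissue_stimulus(0, 3, 150, rect = c(0, 2, 0, 4))
  g1 <- bilayer_grid(60, 5, coupling = coupling_config("zero_sided", G_gap = 0),
                     fibroblasts = TRUE)
  g2 <- bilayer_grid(60, 5, coupling = coupling_config("zero_sided", G_gap = 0),
                     fibroblasts = FALSE)
  r1 <- run_tissue(g1, 40, stimuli = list(stim), sample_every = 500L)
  r2 <- run_tissue(g2, 40, stimuli = list(stim), sample_every = 500L)
  expect_identical(r1$grid$state, r2$grid$state)
})

test_that("two-sided coupling with zero cross conductances equals one-sided", {
  stim <- tissue_stimulus(0, 3, 150, rect = c(0, 2, 0, 4))
  c1 <- coupling_config("one_sided", G_gap = 4, G_ff = 1)
  c2 <- coupling_config("two_sided", G_gap = 4, G_ff = 1, G_mf = 0, G_fm = 0)
  r1 <- run_tissue(bilayer_grid(60, 5, coupling = c1), 40,
                   stimuli = list(stim), sample_every = 500L)
  r2 <- run_tissue(bilayer_grid(60, 5, coupling = c2), 40,
                   stimuli = list(stim), sample_every = 500L)
  expect_identical(r1$grid$state, r2$grid$state)
  expect_identical(r1$grid$vf, r2$grid$vf)
})

test_that("one tissue step matches an independent R evaluation; exchanges sum to zero", {
  # independent oracle: the bilayer update equations recoded in R with
  # myocyte_currents(); also verifies the pairwise antisymmetry of every
  # exchange term by explicit summation
  cp <- coupling_config("two_sided", G_gap = 8, G_ff = 1, G_mf = 2, G_fm = 3)
  nx <- 5; ny <- 4
  grid <- bilayer_grid(nx, ny, coupling = cp)
  # perturb the fields so no term is trivially zero
  set.seed(7)
  grid$state[, "V"] <- grid$state[, "V"] + runif(nx * ny, -5, 5)
  grid$vf <- grid$vf + runif(nx * ny, -5, 5)
  vm <- matrix(grid$state[, "V"], nx, ny)
  vf <- matrix(grid$vf, nx, ny)

  dt <- 0.02
  dxcm <- grid$dx * 0.1
  iion <- apply(cbind(grid$state), 1, function(s)
    myocyte_currents(stats::setNames(s, colnames(grid$state)))[["I_ion"]])
  lap <- laplacian_noflux(vm, 1)            # neighbour-difference sum
  nb_sum <- function(f) {
    out <- matrix(0, nx, ny)
    out[-1, ] <- out[-1, ] + f[-nx, ]
    out[-nx, ] <- out[-nx, ] + f[-1, ]
    out[, -1] <- out[, -1] + f[, -ny]
    out[, -ny] <- out[, -ny] + f[, -1]
    out
  }
  deg <- nb_sum(matrix(1, nx, ny))
  gx <- cp$G_mf + cp$G_fm
  cross_m <- gx * (nb_sum(vf) - deg * vm)   # into the myocyte, pA
  cross_f <- gx * (nb_sum(vm) - deg * vf)   # into the fibroblast, pA
  gap_m <- grid$ggap * as.vector(vm - vf)
  expect_lt(abs(sum(cross_m) + sum(cross_f)), 1e-9)  # pairwise antisymmetry
  # total current leaving the myocyte at a node: on-site gap flow minus the
  # incoming cross-layer current
  vm_expect <- as.vector(vm) + dt * (-iion + cp$D / dxcm^2 * as.vector(lap) -
    (gap_m - as.vector(cross_m)) / cp$C_m)
  ff <- cp$fib
  lap_f <- nb_sum(vf) - deg * vf
  vf_expect <- as.vector(vf) + dt * (-ff$G_f * (as.vector(vf) - ff$E_f) +
    grid$ggap * as.vector(vm - vf) + cp$G_ff * as.vector(lap_f) +
    as.vector(cross_f)) / ff$C_f

  stepped <- step_tissue(grid, dt = dt)
  expect_equal(stepped$state[, "V"], vm_expect, tolerance = 1e-7)
  expect_equal(stepped$vf, vf_expect, tolerance = 1e-10)
})

test_that("conduction velocity scales as the square root of D", {
  # a continuum (cable-equation) property: tested on a refined lattice,
  # since at the working spacing the discrete front is slowed a few
  # percent more at the smaller D
  cv1 <- run_plane_wave(coupling_config(G_gap = 0), nx = 300, ny = 5,
                        dx = 0.1125, dt = 0.005, fibroblasts = FALSE)$cv_cm_s
  cv4 <- run_plane_wave(coupling_config(G_gap = 0, D = 4 * 0.00154),
                        nx = 300, ny = 5, dx = 0.1125, dt = 0.005,
                        fibroblasts = FALSE)$cv_cm_s
  expect_equal(cv4 / cv1, 2, tolerance = 0.05)
})

test_that("the stability bound is checked before stepping", {
  grid <- bilayer_grid(10, 10, coupling = coupling_config(G_gap = 0))
  expect_error(run_tissue(grid, 1, dt = 0.2), "stability")
})

test_that("patch geometry maps mm to nodes by rounding", {
  cp <- coupling_config("zero_sided", G_gap = 8)
  grid <- bilayer_grid(200, 200, coupling = cp, fibroblasts = FALSE)
  # side 33.75 mm at dx = 0.225 mm is exactly 150 x 150 nodes
  g <- set_patch(grid, inhomogeneity_spec(c(0, 0), 33.75, cp))
  expect_identical(sum(g$mask), 150L * 150L)
  expect_identical(g$patch$nodes, 150)
  # a 56.25 mm corner lands on node index 250
  grid2 <- bilayer_grid(300, 300, coupling = cp, fibroblasts = FALSE)
  g2 <- set_patch(grid2, inhomogeneity_spec(c(56.25, 56.25), 2.25, cp))
  expect_identical(g2$patch$i0, 250)
  # a zero-side patch changes nothing
  expect_identical(set_patch(grid, inhomogeneity_spec(c(0, 0), 0, cp)), grid)
  # out-of-bounds patch refused
  expect_error(set_patch(grid, inhomogeneity_spec(c(40, 40), 33.75, cp)),
               "outside")
})
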