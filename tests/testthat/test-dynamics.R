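test_that("leapfrog reproduces free and uniformly accelerated motion", {
  st <- system_state(matrix(0, 1, 3), velocities = matrix(c(1, 0, 0), 1, 3))
  m <- 2
  for (i in 1:100)
    st <- leapfrog_step(st, matrix(0, 1, 3), m, 0.001)
  expect_equal(st$positions[1, ], c(0.1, 0, 0), tolerance = 1e-12)

  # constant force: leapfrog positions follow the exact quadratic
  f <- matrix(c(0, 0, 10), 1, 3)
  st <- system_state(matrix(0, 1, 3))
  dt <- 0.001
  # start from rest at t = 0: the stored velocity is v(-dt/2) = -a dt / 2
  st$velocities <- matrix(c(0, 0, -10 / m * dt / 2), 1, 3)
  for (i in 1:200) st <- leapfrog_step(st, f, m, dt)
  t_end <- 200 * dt
  expect_equal(st$positions[1, 3], 0.5 * (10 / m) * t_end^2,
               tolerance = 1e-10)
  expect_error(leapfrog_step(st, matrix(NaN, 1, 3), m, dt), "non-finite")
})

test_that("a leapfrog harmonic oscillator keeps its period over 10000 steps", {
  k <- 1000; m <- 4; dt <- 0.0005
  st <- system_state(matrix(c(0.05, 0, 0), 1, 3))
  x <- numeric(10000)
  for (i in 1:10000) {
    st <- leapfrog_step(st, matrix(c(-k * st$positions[1, 1], 0, 0), 1, 3),
                        m, dt)
    x[i] <- st$positions[1, 1]
  }
  # period from zero crossings (rising)
  s <- sign(x)
  crossings <- which(diff(s) == 2)
  periods <- diff(crossings) * dt
  expected <- 2 * pi * sqrt(m / k)
  omega_dt <- sqrt(k / m) * dt
  expect_equal(mean(periods), expected,
               tolerance = omega_dt^2)   # O(dt^2) accuracy
})

test_that("weak coupling leaves a system at target T and P untouched", {
  cfg <- run_config(dt = 0.001, ensemble = "NPT", T0 = 300, tau_T = 0.1,
                    P0 = 1, tau_P = 0.5)
  st <- system_state(matrix(rnorm(30), 10, 3),
                     velocities = matrix(rnorm(30), 10, 3),
                     box = c(2, 2, 2))
  out <- couple_baths(st, 300, 1 * qmmm_constants$atm, cfg)
  expect_equal(out$velocities, st$velocities, tolerance = 1e-12)
  expect_equal(out$box, st$box, tolerance = 1e-12)
  expect_error(couple_baths(st, 0, NULL, cfg), "zero instantaneous")
})

test_that("a free-particle gas relaxes to T0 with time constant tau_T", {
  # non-interacting atoms: temperature relaxation is exactly exponential
  n <- 125
  atoms <- data.frame(index = 1:n, atomic_number = 18, mass = 40,
                      charge = 0, lj_type = 1, charge_group = 1:n)
  top <- topology(atoms, lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  grid <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 0.6 + 0.3
  st <- system_state(grid, box = c(3, 3, 3))
  st$velocities <- maxwell_velocities(top$atoms$mass, 600, 21)  # 2 x T0
  cfg <- run_config(dt = 0.001, n_steps = 200, ensemble = "NVT", T0 = 300,
                    tau_T = 0.1, seed = 21, sample_interval = 20,
                    com_removal_interval = 0)
  params <- mm_params(rf_cutoff = 1.0, rf_epsilon = 1)
  sim <- run_simulation(top, st, cfg, params)
  t_series <- sim$energies$temperature
  dev0 <- t_series[1] - 300
  dev_end <- t_series[length(t_series)] - 300   # after 0.2 ps = 2 tau
  expect_equal(dev_end / dev0, exp(-2), tolerance = 0.15)
})

test_that("zero-step runs return the initial state with one record", {
  wb <- build_water_box(27, seed = 7)
  cfg <- run_config(dt = 0.002, n_steps = 0, T0 = 0)
  params <- mm_params(rf_cutoff = 0.45, rf_epsilon = 61,
                      pairlist_cutoff = 0.45)
  sim <- run_simulation(wb$topology, wb$state, cfg, params)
  expect_equal(nrow(sim$energies), 1)
  # positions may be wrapped by whole-box lattice vectors only
  delta <- sim$final_state$positions - wb$state$positions
  expect_lt(max(abs(delta - round(delta / wb$state$box[1]) *
                      wb$state$box[1])), 1e-12)
})

test_that("NVT water holds its target temperature", {
  # group-based single-range cutoffs run slightly warm (pair-list update
  # noise); the tolerance reflects that documented bias
  wb <- build_water_box(216, seed = 8)
  params <- mm_params(rf_cutoff = 0.9, rf_epsilon = 61,
                      pairlist_cutoff = 0.9)
  cfg <- run_config(dt = 0.002, n_steps = 3000, ensemble = "NVT", T0 = 300,
                    tau_T = 0.1, seed = 22, sample_interval = 100,
                    com_removal_interval = 1000)
  sim <- run_simulation(wb$topology, wb$state, cfg, params)
  late <- sim$energies[sim$energies$time > 2, ]
  expect_lt(abs(mean(late$temperature) - 300), 12)
})

test_that("restarting from a checkpoint reproduces the trajectory bit for bit", {
  wb <- build_water_box(27, seed = 9)
  params <- mm_params(rf_cutoff = 0.45, rf_epsilon = 61,
                      pairlist_cutoff = 0.45)
  mk_cfg <- function(n) run_config(dt = 0.002, n_steps = n, ensemble = "NVE",
                                   T0 = 300, seed = 23,
                                   sample_interval = 10,
                                   com_removal_interval = 0)
  full <- run_simulation(wb$topology, wb$state, mk_cfg(100), params)
  part1 <- run_simulation(wb$topology, wb$state, mk_cfg(50), params)
  part2 <- run_simulation(wb$topology, part1$final_state, mk_cfg(50), params)
  expect_identical(full$final_state$positions, part2$final_state$positions)
  expect_identical(full$final_state$velocities, part2$final_state$velocities)
})

test_that("a PBC visibility violation terminates the run with the step", {
  # a QM zone spanning two distant whole molecules violates rule (a)
  wb <- build_water_box(27, seed = 10)
  qz <- qmzone(0, 1, data.frame(index = c(1:3, 40:42),
                                atomic_number = rep(c(8L, 1L, 1L), 2),
                                link_mm = 0L))
  mock <- mock_qm_params(6, charges = rep(0, 6))
  cfg <- run_config(dt = 0.002, n_steps = 10, T0 = 300, seed = 24)
  params <- mm_params(rf_cutoff = 0.45, rf_epsilon = 61,
                      pairlist_cutoff = 0.45)
  expect_error(
    run_simulation(wb$topology, wb$state, cfg, params, qz,
                   embedding_config("EE", qmmm_cutoff = 0.1),
                   mock_qm_backend(mock)),
    class = "miniqmmm_pbc_violation")
})

test_that("the dihedral scan hits every target within a hundredth of a degree", {
  # a butane-like toy with a single cosine dihedral term: the relaxed
  # profile must reproduce the term's analytic shape
  atoms <- data.frame(index = 1:4, atomic_number = 6, mass = 12, charge = 0,
                      lj_type = 1, charge_group = 1:4)
  kphi <- 5.92
  top <- topology(atoms,
                  bonds = data.frame(i = 1:3, j = 2:4, b0 = 0.153, kb = 3e5),
                  angles = data.frame(i = c(1, 2), j = c(2, 3), k = c(3, 4),
                                      theta0 = 111, ktheta = 450),
                  propers = data.frame(i = 1, j = 2, k = 3, l = 4, m = 3,
                                       delta = 0, kphi = kphi),
                  exclusions = list(2:4, c(1, 3, 4), c(1, 2, 4), 1:3),
                  lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  st <- system_state(rbind(c(0, 0, 0), c(0.153, 0, 0),
                           c(0.21, 0.14, 0), c(0.27, 0.2, 0.12)))
  sc <- scan_config(c(1, 2, 3, 4), angles = seq(-150, 180, by = 30))
  params <- mm_params(rf_cutoff = 2, rf_epsilon = 1)
  prof <- minimize_with_dihedral_restraint(top, st, sc, params)
  expect_lte(max(prof$deviation), 0.01)
  expect_equal(min(prof$energy_rel), 0)
  analytic <- kphi * (1 + cos(3 * prof$target * pi / 180))
  expect_equal(prof$energy_rel, analytic - min(analytic), tolerance = 0.02)
})
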