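test_that("a bond at its reference length has zero energy and force", {
  sys <- bond_system(kb = 1000, b0 = 0.1, stretch = 0)
  out <- compute_bonded(sys$topology, sys$state)
  expect_equal(out$energies$bond, 0, tolerance = 1e-14)
  expect_equal(max(abs(out$forces)), 0, tolerance = 1e-10)
})

test_that("a displaced harmonic bond matches the closed form kb d^2 / 2", {
  d <- 0.013
  sys <- bond_system(kb = 2500, b0 = 0.1, stretch = d)
  out <- compute_bonded(sys$topology, sys$state)
  expect_equal(out$energies$bond, 0.5 * 2500 * d^2, tolerance = 1e-12)
})

test_that("analytic forces match finite differences on a random small molecule", {
  fix <- build_toy_tripeptide(seed = 3)
  params <- tripeptide_params()
  f <- mm_forces(fix$topology, fix$state$positions, params)
  err <- fd_max_error(function(p) mm_energy(fix$topology, p, params),
                      f, fix$state$positions)
  expect_lt(err / max(abs(f)), 1e-6)
})

test_that("degenerate bonded geometries raise errors naming the term", {
  sys <- bond_system()
  st <- sys$state
  st$positions[2, ] <- st$positions[1, ]
  expect_error(compute_bonded(sys$topology, st), "bond 1-2")

  atoms <- data.frame(index = 1:3, atomic_number = 6, mass = 12, charge = 0,
                      lj_type = 1, charge_group = 1:3)
  top <- topology(atoms,
                  angles = data.frame(i = 1, j = 2, k = 3, theta0 = 109,
                                      ktheta = 400),
                  lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  st <- system_state(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0)))
  expect_error(compute_bonded(top, st), "angle 1-2-3")
})

test_that("reaction-field Coulomb has the analytic limits", {
  p1 <- mm_params(rf_cutoff = 1.2, rf_epsilon = 1)
  expect_equal(p1$crf, 0)
  p61 <- mm_params(rf_cutoff = 1.4, rf_epsilon = 61)
  expect_equal(p61$crf, 120 / 123, tolerance = 1e-12)

  # two unit charges: eps = 1 reduces to the shifted Coulomb k(1/r - 1/Rc)
  atoms <- data.frame(index = 1:2, atomic_number = 1, mass = 1,
                      charge = c(1, 1), lj_type = 1, charge_group = c(1, 2))
  top <- topology(atoms, lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  r <- 0.7
  st <- system_state(rbind(c(0, 0, 0), c(r, 0, 0)))
  pairs <- build_pairlist(top, st, p1)
  nb <- compute_nonbonded_rf(top, st, pairs, p1)
  k <- qmmm_constants$coulomb_k
  expect_equal(nb$energies$coulomb, k * (1 / r - 1 / 1.2), tolerance = 1e-12)

  # any pair exactly at the cutoff: the shift cancels, V = 0
  st_rc <- system_state(rbind(c(0, 0, 0), c(1.4, 0, 0)))
  pairs_rc <- build_pairlist(top, st_rc, mm_params(rf_cutoff = 1.4,
                                                   rf_epsilon = 61,
                                                   pairlist_cutoff = 1.5))
  nb_rc <- compute_nonbonded_rf(top, st_rc, pairs_rc,
                                mm_params(rf_cutoff = 1.4, rf_epsilon = 61,
                                          pairlist_cutoff = 1.5))
  expect_equal(nb_rc$energies$coulomb, 0, tolerance = 1e-10)
})

test_that("pair distances below the overlap threshold abort", {
  atoms <- data.frame(index = 1:2, atomic_number = 1, mass = 1,
                      charge = c(1, -1), lj_type = 1, charge_group = c(1, 2))
  top <- topology(atoms, lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  st <- system_state(rbind(c(0, 0, 0), c(0.01, 0, 0)))
  params <- mm_params(rf_cutoff = 1.0, rf_epsilon = 1)
  pairs <- build_pairlist(top, st, params)
  expect_error(compute_nonbonded_rf(top, st, pairs, params), "overlap")
})

test_that("charge-group pair list applies the cutoff and minimum image", {
  wb <- build_water_box(2, density = 300, seed = 1)
  top <- wb$topology
  place <- function(sep, box) {
    pos <- wb$state$positions
    # move molecule 2 to a set O-O separation along x from molecule 1
    shift <- pos[1, ] + c(sep, 0, 0) - pos[4, ]
    pos[4:6, ] <- pos[4:6, ] + rep(shift, each = 3)
    system_state(pos, box = box)
  }
  params <- mm_params(rf_cutoff = 1.4, rf_epsilon = 61)
  p_close <- build_pairlist(top, place(1.0, c(4, 4, 4)), params)
  expect_equal(length(p_close$i), 9)        # all intermolecular pairs
  p_far <- build_pairlist(top, place(1.6, c(4, 4, 4)), params)
  expect_equal(length(p_far$i), 0)
  # separation 2.6 nm in a 3.0 nm box: minimum image 0.4 nm
  p_pbc <- build_pairlist(top, place(2.6, c(3, 3, 3)), params)
  expect_equal(length(p_pbc$i), 9)
  expect_error(build_pairlist(top, place(1.0, c(2, 2, 2)), params),
               "half the smallest box edge")
})

test_that("SHAKE restores constraints and leaves satisfied ones unchanged", {
  wb <- build_water_box(8, seed = 2)
  params <- mm_params(rf_cutoff = 0.5, rf_epsilon = 61)
  ref <- wb$state$positions
  spc <- spc_constants()

  trial <- ref
  trial[2, ] <- ref[1, ] + 1.1 * (ref[2, ] - ref[1, ])   # O-H stretched 10%
  trial[3, ] <- ref[1, ] + 1.1 * (ref[3, ] - ref[1, ])
  sh <- apply_shake(wb$topology, ref, trial, params)
  expect_equal(sqrt(sum((sh$positions[1, ] - sh$positions[2, ])^2)),
               spc$d_oh, tolerance = 1e-4)
  expect_equal(sqrt(sum((sh$positions[1, ] - sh$positions[3, ])^2)),
               spc$d_oh, tolerance = 1e-4)

  sh_id <- apply_shake(wb$topology, ref, ref, params)
  expect_equal(sh_id$positions, ref, tolerance = 1e-14)
})

test_that("SHAKE residuals stay within tolerance for random perturbations", {
  wb <- build_water_box(4, density = 500, seed = 3)
  params <- mm_params(rf_cutoff = 0.5, rf_epsilon = 61)
  cons <- wb$topology$constraints
  ref <- wb$state$positions
  set.seed(42)
  worst <- 0
  for (rep in 1:200) {
    trial <- ref + matrix(rnorm(length(ref), sd = 0.01), nrow(ref), 3)
    sh <- apply_shake(wb$topology, ref, trial, params)
    d <- sqrt(rowSums((sh$positions[cons$i, ] - sh$positions[cons$j, ])^2))
    worst <- max(worst, abs(d^2 - cons$d0^2) / cons$d0^2)
  }
  expect_lte(worst, params$shake_tol * 1.0001)
})

test_that("forces sum to zero and exert no net torque in vacuum", {
  fix <- build_toy_tripeptide(seed = 4)
  params <- tripeptide_params()
  f <- mm_forces(fix$topology, fix$state$positions, params)
  expect_lt(max(abs(colSums(f))), 1e-9 * max(abs(f)))
  pos <- fix$state$positions
  torque <- colSums(cbind(pos[, 2] * f[, 3] - pos[, 3] * f[, 2],
                          pos[, 3] * f[, 1] - pos[, 1] * f[, 3],
                          pos[, 1] * f[, 2] - pos[, 2] * f[, 1]))
  expect_lt(max(abs(torque)), 1e-8 * max(abs(f)))
})

test_that("energy is invariant under rigid translation and box wrapping", {
  fix <- build_toy_tripeptide(seed = 5)
  params <- tripeptide_params()
  e0 <- mm_energy(fix$topology, fix$state$positions, params)
  e1 <- mm_energy(fix$topology,
                  fix$state$positions + rep(c(1.3, -0.7, 2.1), each = 19),
                  params)
  expect_equal(e0, e1, tolerance = 1e-12)

  wb <- build_water_box(27, seed = 6)
  paramsw <- mm_params(rf_cutoff = 0.45, rf_epsilon = 61,
                       pairlist_cutoff = 0.45)
  st <- wb$state
  e0 <- {
    pairs <- build_pairlist(wb$topology, st, paramsw)
    nb <- compute_nonbonded_rf(wb$topology, st, pairs, paramsw)
    nb$energies$lj + nb$energies$coulomb
  }
  # wrap one whole molecule by a lattice vector
  st2 <- st
  st2$positions[1:3, ] <- st2$positions[1:3, ] +
    rep(c(st$box[1], 0, 0), each = 3)
  e1 <- {
    pairs <- build_pairlist(wb$topology, st2, paramsw)
    nb <- compute_nonbonded_rf(wb$topology, st2, pairs, paramsw)
    nb$energies$lj + nb$energies$coulomb
  }
  expect_equal(e0, e1, tolerance = 1e-9)
})
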