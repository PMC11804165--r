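# shared helpers: finite-difference oracle, tiny topologies, cached runs

# central finite-difference check of analytic forces against an energy
# closure; returns the maximum absolute error over all coordinates
fd_max_error <- function(energy_fn, forces, positions, h = 1e-6,
                         atoms = seq_len(nrow(positions))) {
  err <- 0
  for (a in atoms) {
    for (k in 1:3) {
      p1 <- positions; p1[a, k] <- p1[a, k] + h
      p2 <- positions; p2[a, k] <- p2[a, k] - h
      f_num <- -(energy_fn(p1) - energy_fn(p2)) / (2 * h)
      err <- max(err, abs(f_num - forces[a, k]))
    }
  }
  err
}

# minimal three-atom chain M-Q-Q used for boundary validation examples
chain_mqq <- function(link_mm = 1L) {
  atoms <- data.frame(index = 1:3, atomic_number = 6, mass = 12,
                      charge = 0, lj_type = 1, charge_group = 1:3)
  top <- topology(atoms,
                  bonds = data.frame(i = c(1, 2), j = c(2, 3), b0 = 0.15,
                                     kb = 1e5),
                  lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  qm <- qmzone(0, 1, data.frame(index = c(2L, 3L), atomic_number = 6,
                                link_mm = c(link_mm, 0L)))
  list(topology = top, qmzone = qm)
}

# a single harmonic bond between two unit-mass-ish atoms
bond_system <- function(kb = 1000, b0 = 0.1, mass = c(12, 12), stretch = 0) {
  atoms <- data.frame(index = 1:2, atomic_number = 6, mass = mass,
                      charge = 0, lj_type = 1, charge_group = c(1, 2))
  top <- topology(atoms, bonds = data.frame(i = 1, j = 2, b0 = b0, kb = kb),
                  lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  pos <- rbind(c(0, 0, 0), c(b0 + stretch, 0, 0))
  list(topology = top, state = system_state(pos))
}

# full MM energy of a vacuum system (bonded + nonbonded, fresh pair list)
mm_energy <- function(top, pos, params, box = NULL) {
  st <- system_state(pos, box = box)
  pairs <- build_pairlist(top, st, params)
  b <- compute_bonded(top, st)
  nb <- compute_nonbonded_rf(top, st, pairs, params)
  sum(unlist(b$energies)) + nb$energies$lj + nb$energies$coulomb
}

mm_forces <- function(top, pos, params, box = NULL) {
  st <- system_state(pos, box = box)
  pairs <- build_pairlist(top, st, params)
  compute_bonded(top, st)$forces +
    compute_nonbonded_rf(top, st, pairs, params)$forces
}

# vacuum parameters for the toy tripeptide
tripeptide_params <- function() {
  mm_params(rf_cutoff = 2.5, rf_epsilon = 1, pairlist_cutoff = 2.5)
}
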