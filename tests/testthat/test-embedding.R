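test_that("charge scaling matches its analytic values and bounds", {
  q <- c(-0.82, 0.41, 1.0)
  expect_identical(scale_mm_charges(q, c(0.1, 0.5, 1), 0), q)   # s = 0: off
  expect_identical(scale_mm_charges(q, c(0.1, 0.5, 1), -2), q)
  # s d = 1 halves the charge (arctan(1) = pi/4)
  expect_equal(scale_mm_charges(1, 0.5, 2), 0.5, tolerance = 1e-12)
  # s d -> infinity recovers the full charge
  expect_equal(scale_mm_charges(q, rep(1e9, 3), 10), q, tolerance = 1e-8)
  # 0 <= |q'| <= |q|, monotone non-decreasing in d
  d <- seq(0, 3, by = 0.05)
  qs <- scale_mm_charges(rep(-0.82, length(d)), d, 1.7)
  expect_true(all(abs(qs) <= 0.82 + 1e-12))
  expect_true(all(diff(abs(qs)) >= -1e-12))
  expect_equal(qs[1], 0)
})

test_that("periodic visibility distinguishes the three constructed cases", {
  cfg <- embedding_config("EE", qmmm_cutoff = 1.4)
  # compact QM water in a large box: ok
  wb <- build_water_box(2, density = 50, seed = 1)
  st <- system_state(wb$state$positions, box = c(3.5, 3.5, 3.5))
  expect_true(check_periodic_visibility(st, water_qmzone(1), cfg)$ok)

  # two QM atoms 1.9 nm apart in a 3.0 nm box: rule (a)
  atoms <- data.frame(index = 1:2, atomic_number = 6, mass = 12, charge = 0,
                      lj_type = 1, charge_group = 1:2)
  top2 <- topology(atoms, lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
  st2 <- system_state(rbind(c(0, 0, 0), c(1.9, 0, 0)), box = c(3, 3, 3))
  qz2 <- qmzone(0, 1, data.frame(index = 1:2, atomic_number = 6,
                                 link_mm = 0L))
  v <- check_periodic_visibility(st2, qz2, cfg)
  expect_false(v$ok)
  expect_equal(v$rule, "a")
  expect_setequal(v$atoms, c(1, 2))

  # QM diameter 0.5, cutoff 1.4, box 3.0: 1.9 > 1.5 violates rule (b)
  st3 <- system_state(rbind(c(0, 0, 0), c(0.5, 0, 0)), box = c(3, 3, 3))
  v3 <- check_periodic_visibility(st3, qz2, cfg)
  expect_false(v3$ok)
  expect_equal(v3$rule, "b")
})

test_that("gathering respects atomic and charge-group inclusion rules", {
  wb <- build_water_box(2, density = 50, seed = 2)
  top <- wb$topology
  qz <- water_qmzone(1)
  box <- c(6, 6, 6)
  # fully deterministic geometry: QM water around (1,1,1), MM water along +x
  place <- function(d_o, d_h = NULL) {
    pos <- wb$state$positions
    pos[1, ] <- c(1, 1, 1)
    pos[2, ] <- c(1.06, 1.08, 1)
    pos[3, ] <- c(0.94, 1.08, 1)
    if (is.null(d_h)) d_h <- d_o + 0.08
    pos[4, ] <- c(1 + d_o, 1, 1)
    pos[5, ] <- c(1 + d_h, 1, 1)
    pos[6, ] <- c(1 + d_h, 1.04, 1)
    system_state(pos, box = box)
  }
  cfg_a <- embedding_config("EE", qmmm_cutoff = 1.4, gathering = "atomic")
  cfg_g <- embedding_config("EE", qmmm_cutoff = 1.4,
                            gathering = "charge-group")

  # whole molecule ~1.0 nm away: all 3 atoms in both modes
  expect_equal(nrow(gather_point_charges(top, place(1.0), qz, cfg_a)), 3)
  expect_equal(nrow(gather_point_charges(top, place(1.0), qz, cfg_g)), 3)

  # straddling: O inside the cutoff, both hydrogens outside
  st <- place(1.30, 1.48)
  got_a <- gather_point_charges(top, st, qz, cfg_a)
  got_g <- gather_point_charges(top, st, qz, cfg_g)
  expect_equal(got_a$atom, 4)            # atomic mode: O only
  expect_setequal(got_g$atom, 4:6)       # group mode: whole group

  # group center beyond the cutoff: excluded in group mode
  expect_equal(nrow(gather_point_charges(top, place(1.55), qz, cfg_g)), 0)
})

test_that("link MM atoms are hidden from the gathered point charges", {
  fix <- build_toy_tripeptide(seed = 1)
  cfg <- embedding_config("EE", qmmm_cutoff = 2.5)
  pcs <- gather_point_charges(fix$topology, fix$state, fix$qmzone, cfg)
  expect_false(6 %in% pcs$atom)          # C-alpha, the M1 atom
  expect_true(all(setdiff(1:19, c(fix$qmzone$qm_atoms$index, 6)) %in%
                    pcs$atom))
})

test_that("force recovery reproduces the Coulomb constant and handles zero charge", {
  params <- mm_params(rf_cutoff = 2, rf_epsilon = 1)
  pcs <- structure(list(atom = 1L, x = 1, y = 0, z = 0, q = 1, d = 1),
                   class = c("point_charge_set", "data.frame"),
                   row.names = 1L)
  qm_pos <- matrix(0, 1, 3)
  res <- structure(list(energy = 0, qm_forces = matrix(0, 1, 3),
                        mm_response = list(mode = "charges", values = 1),
                        updated_qm_charges = NULL), class = "qm_result")
  out <- recover_mm_forces(pcs, res, qm_pos, params)
  # two unit charges 1 nm apart: repulsive, magnitude k = 138.9354
  expect_equal(out$mm_forces[1, ], c(qmmm_constants$coulomb_k, 0, 0),
               tolerance = 1e-10)
  expect_equal(out$qm_forces[1, ], -out$mm_forces[1, ], tolerance = 1e-10)

  # zero charge in field mode feels no force whatever the field
  pcs0 <- pcs; pcs0$q <- 0
  res_f <- structure(list(energy = 0, qm_forces = matrix(0, 1, 3),
                          mm_response = list(mode = "field",
                                             values = matrix(c(5, 2, 1), 1)),
                          updated_qm_charges = NULL), class = "qm_result")
  out0 <- recover_mm_forces(pcs0, res_f, qm_pos, params)
  expect_equal(out0$mm_forces, matrix(0, 1, 3))
})

test_that("the three MM-response recovery modes agree through full assembly", {
  fix <- build_toy_tripeptide(seed = 2)
  params <- tripeptide_params()
  cfg <- embedding_config("EE", qmmm_cutoff = 2.0)
  outs <- lapply(c("forces", "field", "charges"), function(m)
    assemble_qmmm(fix$topology, fix$state, fix$qmzone, cfg,
                  mock_qm_backend(tripeptide_mock_params(fix), m), params))
  fmax <- max(abs(outs[[1]]$forces))
  expect_lt(max(abs(outs[[1]]$forces - outs[[2]]$forces)) / fmax, 1e-8)
  expect_lt(max(abs(outs[[1]]$forces - outs[[3]]$forces)) / fmax, 1e-8)
  expect_equal(outs[[1]]$report$total, outs[[2]]$report$total,
               tolerance = 1e-10)
  expect_equal(outs[[1]]$report$total, outs[[3]]$report$total,
               tolerance = 1e-10)
})

test_that("MECC with an MM-mirroring mock equals the pure-MM engine", {
  wb <- build_water_box(27, density = 900, seed = 4, flexible = TRUE)
  qz <- water_qmzone(1)
  cfg <- embedding_config("MECC")
  params <- mm_params(rf_cutoff = 0.45, rf_epsilon = 61,
                      pairlist_cutoff = 0.45)
  out <- assemble_qmmm(wb$topology, wb$state, qz, cfg,
                       mock_qm_backend(mock_mm_mirror(wb$topology, qz)),
                       params)
  e_mm <- mm_energy(wb$topology, wb$state$positions, params,
                    box = wb$state$box)
  f_mm <- mm_forces(wb$topology, wb$state$positions, params,
                    box = wb$state$box)
  expect_equal(out$report$total, e_mm,
               tolerance = 1e-10 * max(1, abs(e_mm)))
  expect_lt(max(abs(out$forces - f_mm)), 1e-10 * max(abs(f_mm)))
})

test_that("EE with an empty gathered set equals MECC with zero QM charges", {
  # isolated flexible water in vacuum: no MM atoms at all
  wb <- build_water_box(2, density = 50, seed = 5, flexible = "all")
  atoms <- wb$topology$atoms[1:3, ]
  top1 <- topology(atoms,
                   bonds = wb$topology$bonds[wb$topology$bonds$i <= 3, ],
                   angles = wb$topology$angles[wb$topology$angles$j <= 3, ],
                   exclusions = wb$topology$exclusions[1:3],
                   lj_c6 = wb$topology$lj_c6, lj_c12 = wb$topology$lj_c12)
  st <- system_state(wb$state$positions[1:3, ])
  qz <- water_qmzone(1)
  params <- mm_params(rf_cutoff = 1.0, rf_epsilon = 61)
  mock <- mock_mm_mirror(top1, qz)
  ee <- assemble_qmmm(top1, st, qz, embedding_config("EE", qmmm_cutoff = 1),
                      mock_qm_backend(mock), params)
  mecc <- assemble_qmmm(top1, st, qz, embedding_config("MECC"),
                        mock_qm_backend(mock), params)
  expect_equal(ee$report$total, mecc$report$total, tolerance = 1e-12)
  expect_equal(ee$forces, mecc$forces, tolerance = 1e-12)
})

test_that("MEDC warns and applies the geometry-dependent charge rule", {
  wb <- build_water_box(27, seed = 6, flexible = TRUE)
  qz <- water_qmzone(1)
  params <- mm_params(rf_cutoff = 0.45, rf_epsilon = 61,
                      pairlist_cutoff = 0.45)
  mock <- mock_mm_mirror(wb$topology, qz)
  mock$alpha <- 0.5
  cfg <- embedding_config("MEDC")
  expect_warning(
    out <- assemble_qmmm(wb$topology, wb$state, qz, cfg,
                         mock_qm_backend(mock), params),
    "charge-derivative")
  # charges follow q0 + alpha * sum(b - b0) at the current geometry
  pos <- wb$state$positions
  b <- mock$bonds
  s <- sum(sqrt(rowSums((pos[qz$qm_atoms$index[b$i], ] -
                           pos[qz$qm_atoms$index[b$j], ])^2)) - b$b0)
  expect_equal(out$updated_charges, mock$charges + 0.5 * s,
               tolerance = 1e-10)
})

test_that("total force vanishes in MECC and EE assemblies", {
  fix <- build_toy_tripeptide(seed = 3)
  params <- tripeptide_params()
  for (scheme in c("MECC", "EE")) {
    cfg <- embedding_config(scheme, qmmm_cutoff = 2.0)
    out <- assemble_qmmm(fix$topology, fix$state, fix$qmzone, cfg,
                         mock_qm_backend(tripeptide_mock_params(fix)),
                         params)
    expect_lt(max(abs(colSums(out$forces))), 1e-9 * max(abs(out$forces)))
  }
})

test_that("constrain_qm_bonds reinstates the QM zone's distance constraints", {
  wb <- build_water_box(27, seed = 12)       # rigid SPC: constraints only
  qz <- water_qmzone(1)
  off <- miniqmmm:::prepare_qmmm_system(wb$topology, qz,
                                        embedding_config("MECC"))
  expect_equal(nrow(off$constraints), 26 * 3)     # QM water unconstrained
  on <- miniqmmm:::prepare_qmmm_system(
    wb$topology, qz, embedding_config("MECC", constrain_qm_bonds = TRUE))
  expect_equal(nrow(on$constraints), 27 * 3)      # reinstated
})

test_that("scheme codes map to the documented embedding schemes", {
  expect_equal(embedding_config(-1)$scheme, "MECC")
  expect_equal(embedding_config(1)$scheme, "MEDC")
  expect_equal(embedding_config(2)$scheme, "EE")
  expect_error(embedding_config(5), "unrecognized")
})
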