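# Leapfrog dynamics with weak-coupling thermostat/barostat, SHAKE, per-step
# QM/MM assembly and periodic-visibility checks; steepest-descent minimizer
# and the constrained dihedral-scan driver.

#' Simulation run configuration
#'
#' @param dt time step (ps); 0.0005 ps = 0.5 fs by default.
#' @param n_steps number of integration steps.
#' @param ensemble `"NVE"`, `"NVT"`, or `"NPT"`.
#' @param T0 reference temperature (K).
#' @param tau_T temperature-coupling relaxation time (ps).
#' @param P0 reference pressure (atm).
#' @param tau_P pressure-coupling relaxation time (ps).
#' @param compressibility isothermal compressibility ((kJ/mol/nm^3)^-1).
#' @param com_removal_interval steps between center-of-mass motion resets.
#' @param seed integer seed for the Maxwell-Boltzmann velocity draw.
#' @param sample_interval steps between trajectory/energy records (overridden
#'   by the embedding configuration's `write_frequency` in QM/MM runs).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(dt = 0.0005, n_steps = 1000L,
                       ensemble = c("NVE", "NVT", "NPT"), T0 = 300,
                       tau_T = 0.1, P0 = 1, tau_P = 0.5,
                       compressibility = 4.575e-4,
                       com_removal_interval = 1000L, seed = 42L,
                       sample_interval = 100L) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, n_steps >= 0)
  if (ensemble != "NVE" && tau_T <= dt)
    stop("temperature coupling requires tau_T > dt")
  if (ensemble == "NPT" && tau_P <= dt)
    stop("pressure coupling requires tau_P > dt")
  structure(list(dt = dt, n_steps = as.integer(n_steps), ensemble = ensemble,
                 T0 = T0, tau_T = tau_T, P0 = P0, tau_P = tau_P,
                 compressibility = compressibility,
                 com_removal_interval = as.integer(com_removal_interval),
                 seed = as.integer(seed),
                 sample_interval = as.integer(sample_interval)),
            class = "run_config")
}

#' One leapfrog integration step
#'
#' \deqn{v(t + dt/2) = v(t - dt/2) + f(t) \, dt / m, \qquad
#'       r(t + dt) = r(t) + v(t + dt/2) \, dt}
#'
#' @param state a [system_state()] (velocities at `t - dt/2`).
#' @param forces n x 3 forces (kJ/mol/nm) at the current positions.
#' @param masses atom masses (u).
#' @param dt time step (ps).
#' @return Updated [system_state()].
#' @export
leapfrog_step <- function(state, forces, masses, dt) {
  if (any(!is.finite(forces))) stop("non-finite forces in leapfrog step")
  v <- state$velocities + forces * (dt / masses)
  state$velocities <- v
  state$positions <- state$positions + v * dt
  state$time <- state$time + dt
  state
}

kinetic_energy <- function(velocities, masses) {
  0.5 * sum(masses * rowSums(velocities^2))
}

instantaneous_temperature <- function(velocities, masses, ndf) {
  2 * kinetic_energy(velocities, masses) / (ndf * qmmm_constants$kB)
}

#' Weak-coupling temperature and pressure baths
#'
#' Berendsen-type first-order relaxation: velocities are scaled by
#' \eqn{\lambda = \sqrt{1 + (dt/\tau_T)(T_0/T - 1)}} and, under NPT, box and
#' coordinates by \eqn{\mu = (1 - (dt/\tau_P) \kappa (P_0 - P))^{1/3}}.
#'
#' @param state a [system_state()].
#' @param t_inst instantaneous temperature (K); `NULL` skips the thermostat.
#' @param p_inst instantaneous pressure (kJ/mol/nm^3); `NULL` skips the
#'   barostat.
#' @param cfg a [run_config()].
#' @param groups optional list of atom-index vectors coupled to separate
#'   heat baths, each scaled with its own temperature (`t_inst` must then be
#'   a vector of the same length).
#' @return Updated [system_state()].
#' @export
couple_baths <- function(state, t_inst, p_inst, cfg, groups = NULL) {
  if (!is.null(t_inst)) {
    if (any(t_inst <= 0))
      stop("temperature coupling with zero instantaneous temperature")
    if (is.null(groups)) {
      lambda <- sqrt(1 + (cfg$dt / cfg$tau_T) * (cfg$T0 / t_inst - 1))
      state$velocities <- state$velocities * lambda
    } else {
      for (g in seq_along(groups)) {
        lambda <- sqrt(1 + (cfg$dt / cfg$tau_T) * (cfg$T0 / t_inst[g] - 1))
        state$velocities[groups[[g]], ] <-
          state$velocities[groups[[g]], ] * lambda
      }
    }
  }
  if (!is.null(p_inst)) {
    p0 <- cfg$P0 * qmmm_constants$atm
    mu <- (1 - (cfg$dt / cfg$tau_P) * cfg$compressibility *
             (p0 - p_inst))^(1 / 3)
    state$positions <- state$positions * mu
    state$box <- state$box * mu
  }
  state
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param masses atom masses (u).
#' @param T0 temperature (K).
#' @param seed integer seed.
#' @return n x 3 velocity matrix (nm/ps) with zero total momentum.
#' @export
maxwell_velocities <- function(masses, T0, seed) {
  set.seed(seed)
  n <- length(masses)
  sd <- sqrt(qmmm_constants$kB * T0 / masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  sweep(v, 2, colSums(v * masses) / sum(masses))
}

# shift every charge group by a lattice vector so its center lies in [0, box)
wrap_groups <- function(topology, state) {
  if (is.null(state$box)) return(state)
  g <- topology$atoms$charge_group
  cent <- rowsum(state$positions, g) /
    as.vector(rowsum(rep(1, length(g)), g))
  shift <- -floor(sweep(cent, 2, state$box, "/")) %*% diag(state$box)
  state$positions <- state$positions + shift[match(g, sort(unique(g))), ]
  state
}

remove_com_motion <- function(state, masses, rotations = FALSE) {
  vcom <- colSums(state$velocities * masses) / sum(masses)
  state$velocities <- sweep(state$velocities, 2, vcom)
  if (rotations) {
    com <- colSums(state$positions * masses) / sum(masses)
    rp <- sweep(state$positions, 2, com)
    l <- colSums(masses * cbind(
      rp[, 2] * state$velocities[, 3] - rp[, 3] * state$velocities[, 2],
      rp[, 3] * state$velocities[, 1] - rp[, 1] * state$velocities[, 3],
      rp[, 1] * state$velocities[, 2] - rp[, 2] * state$velocities[, 1]))
    r2 <- rowSums(rp^2)
    inertia <- diag(colSums(masses * r2) - colSums(masses * rp^2)) -
      (t(rp * masses) %*% rp - diag(colSums(masses * rp^2)))
    omega <- tryCatch(solve(inertia, l), error = function(e) c(0, 0, 0))
    state$velocities <- state$velocities - cbind(
      omega[2] * rp[, 3] - omega[3] * rp[, 2],
      omega[3] * rp[, 1] - omega[1] * rp[, 3],
      omega[1] * rp[, 2] - omega[2] * rp[, 1])
  }
  state
}

#' Run a molecular dynamics simulation
#'
#' Leapfrog dynamics with, per step: scheduled pair-list refresh, capping-atom
#' placement and QM/MM assembly (when a QM zone is present), chain-rule cap
#' force distribution, SHAKE, integration, weak-coupling baths, scheduled
#' center-of-mass motion removal, and the periodic-visibility check (the run
#' terminates on a violation, reporting the step). Initial velocities are
#' drawn from a Maxwell-Boltzmann distribution at `T0` using the configured
#' seed when the supplied state carries zero velocities; a state with
#' velocities (e.g. a checkpoint) continues deterministically.
#'
#' @param topology a [topology()] (unpruned; pruning is applied internally
#'   when a QM zone is given).
#' @param state initial [system_state()].
#' @param run_cfg a [run_config()].
#' @param params an [mm_params()].
#' @param qmzone optional [qmzone()] for QM/MM runs.
#' @param embed_cfg an [embedding_config()] (required with `qmzone`).
#' @param backend a `qm_backend` (required with `qmzone`).
#' @return List with `energies` (data.frame of decomposed energies,
#'   temperature, pressure, density per record), `trajectory` (a
#'   `"trajectory"` object), `final_state`, and `removed` (pruned terms).
#' @export
run_simulation <- function(topology, state, run_cfg, params = mm_params(),
                           qmzone = NULL, embed_cfg = NULL, backend = NULL) {
  qm <- !is.null(qmzone)
  if (qm && (is.null(embed_cfg) || is.null(backend)))
    stop("QM/MM runs require an embedding configuration and a backend")
  system <- NULL
  top <- topology
  removed <- NULL
  constraints <- topology$constraints
  if (qm) {
    system <- prepare_qmmm_system(topology, qmzone, embed_cfg)
    top <- system$topology
    removed <- system$removed
    constraints <- system$constraints
    if (embed_cfg$scheme == "MEDC")
      warning(paste("MEDC dynamic charges: no charge-derivative forces are",
                    "computed; this scheme is discouraged for longer",
                    "simulations"), call. = FALSE)
  }
  masses <- top$atoms$mass
  n <- nrow(top$atoms)
  ncons <- nrow(constraints)
  ndf <- 3 * n - ncons - 3
  write_every <- if (qm) embed_cfg$write_frequency else run_cfg$sample_interval

  if (all(state$velocities == 0) && run_cfg$T0 > 0)
    state$velocities <- maxwell_velocities(masses, run_cfg$T0, run_cfg$seed)

  eval_forces <- function(st, pairs, first) {
    if (qm) {
      out <- assemble_qmmm(system, st, qmzone, embed_cfg, backend, params,
                           pairs = pairs, first_step = first,
                           medc_warn = FALSE)
      list(report = out$report, forces = out$forces, virial = out$virial)
    } else {
      bonded <- compute_bonded(top, st)
      nb <- compute_nonbonded_rf(top, st, pairs, params)
      rep <- energy_report(bond = bonded$energies$bond,
                           angle = bonded$energies$angle,
                           proper = bonded$energies$proper,
                           improper = bonded$energies$improper,
                           lj_mm = nb$energies$lj,
                           coulomb_rf_mm = nb$energies$coulomb)
      list(report = rep, forces = bonded$forces + nb$forces,
           virial = bonded$virial + nb$virial)
    }
  }

  records <- list()
  frames <- list()
  frame_boxes <- list()
  frame_times <- numeric(0)
  record <- function(time, positions, box, report, kin) {
    t_now <- 2 * kin / (ndf * qmmm_constants$kB)
    vol <- if (is.null(box)) NA_real_ else prod(box)
    dens <- if (is.na(vol)) NA_real_ else sum(masses) * 1.66053906660 / vol
    rec <- c(list(time = time), unclass(report),
             list(kinetic = kin, total_energy = report$total + kin,
                  temperature = t_now, volume = vol, density = dens))
    records[[length(records) + 1]] <<- rec
    frames[[length(frames) + 1]] <<- positions
    frame_boxes[length(frame_boxes) + 1] <<- list(box)  # box may be NULL
    frame_times <<- c(frame_times, time)
  }

  pairs <- NULL
  pbc_context <- function(expr, step) {
    tryCatch(expr, miniqmmm_pbc_violation = function(e) {
      stop_miniqmmm("miniqmmm_pbc_violation",
                    sprintf("step %d: %s", step, conditionMessage(e)),
                    list(step = step))
    }, error = function(e) {
      if (inherits(e, "miniqmmm_error")) stop(e)
      stop(sprintf("step %d: %s", step, conditionMessage(e)), call. = FALSE)
    })
  }

  state <- wrap_groups(top, state)
  pairs <- build_pairlist(top, state, params)
  if (run_cfg$n_steps == 0) {
    fe <- pbc_context(eval_forces(state, pairs, first = TRUE), 0L)
    record(state$time, state$positions, state$box, fe$report,
           kinetic_energy(state$velocities, masses))
    return(list(energies = do.call(rbind, lapply(records, as.data.frame)),
                trajectory = structure(list(positions = frames,
                                            boxes = frame_boxes,
                                            times = frame_times),
                                       class = "trajectory"),
                final_state = state, removed = removed))
  }

  dt <- run_cfg$dt
  for (step in seq_len(run_cfg$n_steps)) {
    if (step > 1 && (step - 1) %% params$pairlist_update_interval == 0) {
      state <- wrap_groups(top, state)
      pairs <- build_pairlist(top, state, params)
    }
    fe <- pbc_context(eval_forces(state, pairs, first = step == 1), step)

    v_old <- state$velocities
    v_new <- v_old + fe$forces * (dt / masses)

    if (run_cfg$ensemble %in% c("NVT", "NPT")) {
      # temperature from the last constrained half-step velocities: the
      # unconstrained trial velocities carry spurious kinetic energy along
      # the constraint directions that SHAKE removes again
      t_inst <- instantaneous_temperature(v_old, masses, ndf)
      lambda <- sqrt(1 + (dt / run_cfg$tau_T) * (run_cfg$T0 / t_inst - 1))
      v_new <- v_new * lambda
    }

    r_old <- state$positions
    r_new <- r_old + v_new * dt
    virial_c <- 0
    if (ncons > 0) {
      sh <- cpp_shake(r_old, r_new, as.integer(constraints$i),
                      as.integer(constraints$j), constraints$d0, 1 / masses,
                      params$shake_tol, params$shake_maxit)
      r_new <- sh$positions
      v_new <- (r_new - r_old) / dt
      virial_c <- -sh$gsum / dt^2
    }

    # record at time t: potential at r(t), kinetic centered on t as the mean
    # of the adjacent half-step kinetic energies
    if ((step - 1) %% write_every == 0) {
      kin <- 0.5 * (kinetic_energy(v_old, masses) +
                      kinetic_energy(v_new, masses))
      record(state$time, r_old, state$box, fe$report, kin)
    }

    state$positions <- r_new
    state$velocities <- v_new
    state$time <- state$time + dt

    if (run_cfg$ensemble == "NPT") {
      kin <- kinetic_energy(v_new, masses)
      vol <- prod(state$box)
      p_inst <- (2 * kin + fe$virial + virial_c) / (3 * vol)
      state <- couple_baths(state, NULL, p_inst, run_cfg)
    }

    if (run_cfg$com_removal_interval > 0 &&
        step %% run_cfg$com_removal_interval == 0)
      state <- remove_com_motion(state, masses,
                                 rotations = is.null(state$box))
  }

  # closing record at t = n dt, centered by one extra (constrained) step
  fe <- pbc_context(eval_forces(state, pairs, first = FALSE),
                    run_cfg$n_steps)
  v_next <- state$velocities + fe$forces * (dt / masses)
  if (ncons > 0) {
    r_try <- state$positions + v_next * dt
    sh <- cpp_shake(state$positions, r_try, as.integer(constraints$i),
                    as.integer(constraints$j), constraints$d0, 1 / masses,
                    params$shake_tol, params$shake_maxit)
    v_next <- (sh$positions - state$positions) / dt
  }
  kin <- 0.5 * (kinetic_energy(state$velocities, masses) +
                  kinetic_energy(v_next, masses))
  record(state$time, state$positions, state$box, fe$report, kin)

  energies <- do.call(rbind, lapply(records, as.data.frame))
  list(energies = energies,
       trajectory = structure(list(positions = frames, boxes = frame_boxes,
                                   times = frame_times),
                              class = "trajectory"),
       final_state = state, removed = removed)
}

#' Relative energy drift of a run
#'
#' Linear-regression slope of the total energy over the run, times the run
#' length, relative to the larger of |mean total energy| and the mean kinetic
#' energy.
#'
#' @param energies the `energies` data.frame of [run_simulation()].
#' @return Dimensionless relative drift.
#' @export
energy_drift <- function(energies) {
  if (nrow(energies) < 2) return(0)
  fit <- stats::lm(total_energy ~ time, data = energies)
  span <- diff(range(energies$time))
  abs(stats::coef(fit)[2] * span) /
    max(abs(mean(energies$total_energy)), mean(energies$kinetic))
}

#' Dihedral-scan configuration
#'
#' @param atoms integer quadruple `(i, j, k, l)` of the scanned torsion.
#' @param angles grid of target angles (degrees, in (-180, 180]).
#' @param k_restraint initial harmonic restraint force constant
#'   (kJ/mol/rad^2); iteratively doubled until the final torsion is within
#'   `angle_tol` of the target.
#' @param angle_tol convergence criterion on |final - target| (degrees).
#' @param max_tighten maximum number of restraint-stiffening rounds.
#' @param sd_maxit maximum steepest-descent iterations per round.
#' @param sd_ftol force-component convergence threshold (kJ/mol/nm).
#' @param sd_step0 initial steepest-descent displacement (nm).
#' @return Object of class `"scan_config"`.
#' @export
scan_config <- function(atoms, angles = seq(-180, 165, by = 15),
                        k_restraint = 50000, angle_tol = 0.01,
                        max_tighten = 10L, sd_maxit = 5000L, sd_ftol = 1,
                        sd_step0 = 1e-4) {
  stopifnot(length(atoms) == 4)
  angles <- wrap_angle(angles)   # equivalent representatives in (-180, 180]
  structure(list(atoms = as.integer(atoms), angles = angles,
                 k_restraint = k_restraint, angle_tol = angle_tol,
                 max_tighten = as.integer(max_tighten),
                 sd_maxit = as.integer(sd_maxit), sd_ftol = sd_ftol,
                 sd_step0 = sd_step0), class = "scan_config")
}

# atoms reachable from `start` through the bond graph without passing
# through `blocked`
bonded_component <- function(bonds, n, start, blocked) {
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  seen <- c(blocked, start)
  frontier <- start
  while (length(frontier)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, frontier)
  }
  setdiff(seen, blocked)
}

# rigidly rotate `moving` atoms about the axis from pos[j,] to pos[k,]
rotate_about_bond <- function(pos, j, k, moving, angle_deg) {
  axis <- pos[k, ] - pos[j, ]
  axis <- axis / vec_norm(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  rel <- sweep(pos[moving, , drop = FALSE], 2, pos[k, ])
  # Rodrigues rotation
  dot <- as.vector(rel %*% axis)
  crossm <- cbind(axis[2] * rel[, 3] - axis[3] * rel[, 2],
                  axis[3] * rel[, 1] - axis[1] * rel[, 3],
                  axis[1] * rel[, 2] - axis[2] * rel[, 1])
  rot <- ct * rel + st * crossm + (1 - ct) * outer(dot, axis)
  pos[moving, ] <- sweep(rot, 2, pos[k, ], FUN = "+")
  pos
}

# steepest descent with adaptive step on an energy/force closure
sd_minimize <- function(eval_fn, pos, step0, maxit, ftol) {
  cur <- eval_fn(pos)
  step <- step0
  for (it in seq_len(maxit)) {
    fmax <- max(abs(cur$forces))
    if (fmax < ftol) break
    trial <- pos + (step / fmax) * cur$forces
    nxt <- eval_fn(trial)
    if (nxt$energy < cur$energy) {
      pos <- trial
      cur <- nxt
      step <- step * 1.2
    } else {
      step <- step * 0.5
      if (step < 1e-10) break   # stalled: no descent direction at resolution
    }
  }
  list(positions = pos, energy = cur$energy, forces = cur$forces,
       iterations = it)
}

#' Relaxed potential-energy scan over a restrained torsion
#'
#' For each grid angle the system is energy-minimized by steepest descent
#' under a harmonic restraint on the scanned torsion. The restraint is
#' iteratively stiffened (force constant doubled) until the final torsion is
#' within `angle_tol` (default 0.01 degrees) of its target. The returned
#' profile is the potential energy without the restraint term, shifted so
#' that its minimum is zero. Each grid point starts from the previous
#' relaxed geometry.
#'
#' @param topology a [topology()].
#' @param state starting [system_state()].
#' @param scan_cfg a [scan_config()].
#' @param params an [mm_params()].
#' @param qmzone,embed_cfg,backend optional QM/MM setup as in
#'   [run_simulation()].
#' @return data.frame with `target`, `angle` (relaxed torsion, degrees),
#'   `energy` (kJ/mol), `energy_rel` (profile shifted to min 0), and
#'   `deviation` (|angle - target|, degrees).
#' @export
minimize_with_dihedral_restraint <- function(topology, state, scan_cfg,
                                             params = mm_params(),
                                             qmzone = NULL, embed_cfg = NULL,
                                             backend = NULL) {
  qm <- !is.null(qmzone)
  system <- NULL
  top <- topology
  if (qm) {
    system <- prepare_qmmm_system(topology, qmzone, embed_cfg)
    top <- system$topology
  }
  ii <- scan_cfg$atoms

  # one pair list for the whole scan: minimization displacements are small
  # compared to the cutoff margin (and in vacuum the list is complete)
  pairs <- build_pairlist(top, state, params)

  raw_eval <- function(pos) {
    st <- system_state(pos, box = state$box)
    if (qm) {
      out <- assemble_qmmm(system, st, qmzone, embed_cfg, backend, params,
                           pairs = pairs, medc_warn = FALSE)
      list(energy = out$report$total, forces = out$forces)
    } else {
      bonded <- compute_bonded(top, st)
      nb <- compute_nonbonded_rf(top, st, pairs, params)
      list(energy = sum(unlist(bonded$energies)) + nb$energies$lj +
             nb$energies$coulomb,
           forces = bonded$forces + nb$forces)
    }
  }

  restrained_eval <- function(target_deg, k) {
    function(pos) {
      base <- raw_eval(pos)
      g <- dihedral_geometry(pos[ii[1], ], pos[ii[2], ], pos[ii[3], ],
                             pos[ii[4], ])
      dphi <- deg2rad(wrap_angle(rad2deg(g$phi) - target_deg))
      gr <- dihedral_gradient(g)
      f <- base$forces
      dV <- k * dphi
      f[ii[1], ] <- f[ii[1], ] - dV * gr$d1
      f[ii[2], ] <- f[ii[2], ] - dV * gr$d2
      f[ii[3], ] <- f[ii[3], ] - dV * gr$d3
      f[ii[4], ] <- f[ii[4], ] - dV * gr$d4
      list(energy = base$energy + 0.5 * k * dphi^2, forces = f)
    }
  }

  pos <- state$positions
  # the subtree rotated to pre-set each target angle: everything on the
  # k-side of the central j-k bond (connectivity from the unpruned topology)
  rot_atoms <- bonded_component(topology$bonds, nrow(topology$atoms),
                                ii[3], ii[2])
  out <- data.frame(target = scan_cfg$angles, angle = NA_real_,
                    energy = NA_real_, deviation = NA_real_)
  for (p in seq_along(scan_cfg$angles)) {
    target <- scan_cfg$angles[p]
    cur <- dihedral_angle(pos[ii[1], ], pos[ii[2], ], pos[ii[3], ],
                          pos[ii[4], ])
    pos <- rotate_about_bond(pos, ii[2], ii[3], rot_atoms,
                             wrap_angle(target - cur))
    k <- scan_cfg$k_restraint
    done <- FALSE
    for (round in seq_len(scan_cfg$max_tighten)) {
      res <- sd_minimize(restrained_eval(target, k), pos, scan_cfg$sd_step0,
                         scan_cfg$sd_maxit, scan_cfg$sd_ftol)
      pos <- res$positions
      ang <- dihedral_angle(pos[ii[1], ], pos[ii[2], ], pos[ii[3], ],
                            pos[ii[4], ])
      dev <- abs(wrap_angle(ang - target))
      if (dev <= scan_cfg$angle_tol) {
        done <- TRUE
        break
      }
      k <- k * 2
    }
    if (!done)
      stop(sprintf("dihedral scan did not converge at target %g deg (deviation %.4f deg)",
                   target, dev))
    out$angle[p] <- ang
    out$deviation[p] <- dev
    out$energy[p] <- raw_eval(pos)$energy
  }
  out$energy_rel <- out$energy - min(out$energy)
  out
}
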