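# Embedding schemes: point-charge gathering, charge scaling, periodic
# visibility, MM-force recovery, and the combined QM/MM evaluation.

#' Embedding configuration
#'
#' @param scheme embedding scheme: one of `"MECC"`, `"MEDC"`, `"EE"`, or the
#'   corresponding integer code (-1 = MECC, 1 = MEDC, 2 = EE).
#' @param qmmm_cutoff cutoff (nm) for gathering MM point charges in
#'   electrostatic embedding.
#' @param gathering `"atomic"` (an MM atom enters iff its minimum-image
#'   distance to any QM atom is within the cutoff) or `"charge-group"`
#'   (a whole charge group enters iff its geometric center is).
#' @param lj_within_qm apply Lennard-Jones interactions between QM atoms.
#' @param constrain_qm_bonds constrain pruned QM-QM bonds at their
#'   force-field lengths.
#' @param charge_scaling_s scaling parameter `s` (1/nm) of the distance-based
#'   MM-charge damping \eqn{q' = q \, (2/\pi) \arctan(s d)}; values <= 0
#'   disable scaling.
#' @param write_frequency steps between trajectory/energy records during a
#'   simulation.
#' @return Object of class `"embedding_config"`.
#' @export
embedding_config <- function(scheme = "MECC", qmmm_cutoff = 1.4,
                             gathering = c("atomic", "charge-group"),
                             lj_within_qm = FALSE, constrain_qm_bonds = FALSE,
                             charge_scaling_s = 0, write_frequency = 100L) {
  if (is.numeric(scheme)) {
    scheme <- switch(as.character(as.integer(scheme)),
                     "-1" = "MECC", "1" = "MEDC", "2" = "EE",
                     stop(sprintf("unrecognized embedding scheme code %s",
                                  scheme)))
  }
  scheme <- match.arg(scheme, c("MECC", "MEDC", "EE"))
  gathering <- match.arg(gathering)
  if (scheme == "EE" && qmmm_cutoff <= 0)
    stop("electrostatic embedding requires a positive qmmm_cutoff")
  if (!is.finite(charge_scaling_s)) stop("charge_scaling_s must be finite")
  structure(list(scheme = scheme, qmmm_cutoff = qmmm_cutoff,
                 gathering = gathering, lj_within_qm = isTRUE(lj_within_qm),
                 constrain_qm_bonds = isTRUE(constrain_qm_bonds),
                 charge_scaling_s = charge_scaling_s,
                 write_frequency = as.integer(write_frequency)),
            class = "embedding_config")
}

#' Scale MM charges by distance to the QM zone
#'
#' \deqn{q' = q \, (2/\pi) \arctan(s d)}
#' for `s > 0`; charges are returned unchanged for `s <= 0`. Scaled charges
#' satisfy \eqn{0 \le |q'| \le |q|} and increase monotonically with the
#' distance `d` to the closest QM atom, damping over-polarization by MM
#' charges close to the QM zone.
#'
#' @param charges MM charges (e).
#' @param d distances (nm) to the closest QM atom, same length as `charges`.
#' @param s scaling parameter (1/nm).
#' @return Scaled charges.
#' @export
scale_mm_charges <- function(charges, d, s) {
  if (s <= 0) return(charges)
  if (any(d < 0)) stop("distances must be non-negative")
  charges * (2 / pi) * atan(s * d)
}

#' Check periodic visibility of the QM zone
#'
#' Under periodic boundaries no QM atom may interact with a periodic copy of
#' another QM atom, and every MM atom must present a single consistent image
#' to all QM atoms. A sufficient condition is checked every step: (a) the
#' diameter of the QM zone (its physical extent at the supplied coordinates,
#' molecules kept whole) is below half the smallest box edge - beyond that, a
#' QM atom is closer to the periodic copy of another QM atom than to the atom
#' itself; and (b) for electrostatic embedding, diameter + gathering cutoff
#' is below half the smallest box edge.
#'
#' @param state a [system_state()] with a periodic box.
#' @param qmzone a [qmzone()].
#' @param config an [embedding_config()].
#' @return List with `ok` (logical); on violation also `rule` (`"a"` or
#'   `"b"`), the offending `atoms`, and a `message`.
#' @export
check_periodic_visibility <- function(state, qmzone, config) {
  if (is.null(state$box)) return(list(ok = TRUE))
  half <- min(state$box) / 2
  idx <- qmzone$qm_atoms$index
  pos <- state$positions[idx, , drop = FALSE]
  diam <- 0
  worst <- c(idx[1], idx[1])
  if (length(idx) > 1) {
    for (a in seq_len(length(idx) - 1)) {
      d <- sweep(pos[(a + 1):length(idx), , drop = FALSE], 2, pos[a, ])
      dn <- sqrt(rowSums(d * d))
      m <- which.max(dn)
      if (dn[m] > diam) {
        diam <- dn[m]
        worst <- c(idx[a], idx[a + m])
      }
    }
  }
  if (diam >= half) {
    return(list(ok = FALSE, rule = "a", atoms = worst,
                message = sprintf("QM atoms %d and %d are %.3f nm apart (>= half box edge %.3f nm): a QM atom sees a periodic copy of another QM atom",
                                  worst[1], worst[2], diam, half)))
  }
  if (config$scheme == "EE" && diam + config$qmmm_cutoff >= half) {
    return(list(ok = FALSE, rule = "b", atoms = worst,
                message = sprintf("QM-zone diameter %.3f nm + cutoff %.3f nm >= half box edge %.3f nm: MM atoms may present inconsistent periodic images to the QM atoms",
                                  diam, config$qmmm_cutoff, half)))
  }
  list(ok = TRUE, diameter = diam)
}

# QM-zone positions gathered into one connected image: each QM atom is
# represented by its minimum image relative to the first QM atom.
gather_qm_positions <- function(state, qm_idx) {
  pos <- state$positions[qm_idx, , drop = FALSE]
  if (is.null(state$box) || length(qm_idx) == 1) return(pos)
  ref <- pos[1, ]
  shift <- min_image(sweep(pos, 2, ref), state$box)
  sweep(shift, 2, ref, FUN = "+")
}

#' Gather MM point charges for electrostatic embedding
#'
#' Collects the MM atoms visible to the QM zone as point charges, at the
#' periodic image closest to the QM zone. In `"atomic"` mode an MM atom is
#' included iff its minimum-image distance to any QM atom is within the
#' cutoff; in `"charge-group"` mode a whole charge group is included iff its
#' geometric center is. Link MM atoms (the atoms taking part in a QM-MM
#' bond) are completely hidden from the QM calculation. Charges are scaled
#' by [scale_mm_charges()] with each atom's distance to the closest QM atom.
#'
#' @param topology a [topology()].
#' @param state a [system_state()].
#' @param qmzone a [qmzone()].
#' @param config an [embedding_config()] with scheme `"EE"`.
#' @return Object of class `"point_charge_set"`: data.frame with columns
#'   `atom` (topology index), `x, y, z` (gathered positions, nm), `q`
#'   (possibly scaled charge, e), `d` (distance to the closest QM atom, nm).
#' @export
gather_point_charges <- function(topology, state, qmzone, config) {
  qm_idx <- qmzone$qm_atoms$index
  n <- nrow(topology$atoms)
  is_qm <- rep(FALSE, n)
  is_qm[qm_idx] <- TRUE
  hidden <- qmzone$qm_atoms$link_mm[qmzone$qm_atoms$link_mm > 0]

  pcs <- function(atom, x, y, z, q, d) {
    structure(list(atom = atom, x = x, y = y, z = z, q = q, d = d),
              class = c("point_charge_set", "data.frame"),
              row.names = seq_along(atom))
  }

  qm_pos <- gather_qm_positions(state, qm_idx)
  qm_center <- colMeans(qm_pos)

  mm_idx <- which(!is_qm)
  if (!length(mm_idx))
    return(pcs(integer(0), numeric(0), numeric(0), numeric(0), numeric(0),
               numeric(0)))

  # single consistent image: place every MM atom at its minimum image
  # relative to the QM-zone center (guaranteed consistent for all QM atoms
  # by the periodic-visibility check)
  mm_pos <- state$positions[mm_idx, , drop = FALSE]
  if (!is.null(state$box)) {
    rel <- cbind(mm_pos[, 1] - qm_center[1], mm_pos[, 2] - qm_center[2],
                 mm_pos[, 3] - qm_center[3])
    shift <- min_image(rel, state$box)
    mm_pos <- cbind(shift[, 1] + qm_center[1], shift[, 2] + qm_center[2],
                    shift[, 3] + qm_center[3])
  }

  # distance of every MM atom to its closest QM atom
  dmin <- rep(Inf, length(mm_idx))
  for (a in seq_len(nrow(qm_pos))) {
    d2 <- (mm_pos[, 1] - qm_pos[a, 1])^2 + (mm_pos[, 2] - qm_pos[a, 2])^2 +
      (mm_pos[, 3] - qm_pos[a, 3])^2
    dmin <- pmin(dmin, d2)
  }
  dmin <- sqrt(dmin)

  if (config$gathering == "atomic") {
    keep <- dmin <= config$qmmm_cutoff
  } else {
    groups <- topology$atoms$charge_group[mm_idx]
    gx <- rowsum(mm_pos, groups)
    gn <- as.vector(rowsum(rep(1, length(mm_idx)), groups))
    gcent <- gx / gn
    gd <- rep(Inf, nrow(gcent))
    for (a in seq_len(nrow(qm_pos))) {
      d2 <- (gcent[, 1] - qm_pos[a, 1])^2 + (gcent[, 2] - qm_pos[a, 2])^2 +
        (gcent[, 3] - qm_pos[a, 3])^2
      gd <- pmin(gd, d2)
    }
    keep_group <- rownames(gx)[sqrt(gd) <= config$qmmm_cutoff]
    keep <- as.character(groups) %in% keep_group
  }
  keep[mm_idx %in% hidden] <- FALSE

  pcs(mm_idx[keep], mm_pos[keep, 1], mm_pos[keep, 2], mm_pos[keep, 3],
      scale_mm_charges(topology$atoms$charge[mm_idx[keep]], dmin[keep],
                       config$charge_scaling_s),
      dmin[keep])
}

#' Recover forces on MM atoms from a QM result
#'
#' Renders the backend's MM response as forces: pass-through for the
#' `forces` representation; \eqn{f_i = q_i E_i} with the gathered (scaled)
#' charge for the `field` representation; and the pairwise Coulomb sum
#' \eqn{f_{ij} = k q_i q_j r_{ij} / d_{ij}^3} over all QM-MM pairs for the
#' `charges` representation, in which case equal-and-opposite forces on the
#' QM (and capping) atoms are returned as well.
#'
#' @param point_charges a [gather_point_charges()] result.
#' @param result a `qm_result`.
#' @param qm_positions (nqm + ncap) x 3 gathered QM-zone positions (nm).
#' @param params an [mm_params()] (Coulomb constant).
#' @return List with `mm_forces` (one row per point charge), `qm_forces`
#'   (reciprocal forces, non-zero only for the `charges` representation), and
#'   `energy` (the pairwise Coulomb energy for `charges`, else 0; informative
#'   only, the backend already accounts for the coupling energy).
#' @export
recover_mm_forces <- function(point_charges, result, qm_positions, params) {
  npc <- nrow(point_charges)
  mode <- result$mm_response$mode
  values <- result$mm_response$values
  qm_forces <- matrix(0, nrow(qm_positions), 3)
  if (npc == 0)
    return(list(mm_forces = matrix(0, 0, 3), qm_forces = qm_forces,
                energy = 0))
  if (mode %in% c("forces", "field")) {
    if (is.null(values) || nrow(values) != npc)
      stop(sprintf("MM response (%s) has %d rows, expected %d", mode,
                   if (is.null(values)) 0L else nrow(values), npc))
  }
  if (mode == "forces") {
    return(list(mm_forces = values, qm_forces = qm_forces, energy = 0))
  }
  if (mode == "field") {
    return(list(mm_forces = point_charges$q * values, qm_forces = qm_forces,
                energy = 0))
  }
  # charges representation: pairwise Coulomb over all M x N QM-MM pairs
  if (length(values) != nrow(qm_positions))
    stop(sprintf("MM response (charges) has %d entries, expected %d",
                 length(values), nrow(qm_positions)))
  k <- params$coulomb_k
  pcpos <- cbind(point_charges$x, point_charges$y, point_charges$z)
  mm_forces <- matrix(0, npc, 3)
  energy <- 0
  for (a in seq_len(nrow(qm_positions))) {
    if (values[a] == 0) next
    d <- cbind(pcpos[, 1] - qm_positions[a, 1],
               pcpos[, 2] - qm_positions[a, 2],
               pcpos[, 3] - qm_positions[a, 3])   # r_i - r_a
    r2 <- rowSums(d * d)
    r <- sqrt(r2)
    energy <- energy + sum(k * values[a] * point_charges$q / r)
    fi <- (k * values[a] * point_charges$q / (r2 * r)) * d
    mm_forces <- mm_forces + fi
    qm_forces[a, ] <- qm_forces[a, ] - colSums(fi)
  }
  list(mm_forces = mm_forces, qm_forces = qm_forces, energy = energy)
}

# Prepare a QM/MM system: validate links, prune the topology, assemble the
# link table and the constraint set actually integrated.
prepare_qmmm_system <- function(topology, qmzone, config) {
  report <- validate_system(topology, qmzone)
  pruned <- prune_topology(topology, qmzone)
  constraints <- pruned$topology$constraints
  if (config$constrain_qm_bonds) {
    # constrain QM-QM bonds at their force-field lengths, and keep any
    # distance constraints the pruning removed from the QM zone
    qm_bonds <- topology$bonds[
      topology$bonds$i %in% qmzone$qm_atoms$index &
      topology$bonds$j %in% qmzone$qm_atoms$index, , drop = FALSE]
    if (nrow(qm_bonds))
      constraints <- rbind(constraints,
                           data.frame(i = qm_bonds$i, j = qm_bonds$j,
                                      d0 = qm_bonds$b0))
    constraints <- rbind(constraints, pruned$removed_constraints)
  }
  list(topology = pruned$topology, removed = pruned$removed,
       links = report$links, constraints = constraints,
       ex = excluded_pairs(pruned$topology))
}

# Split a pair list into interaction classes according to the embedding
# scheme. Returns per-pair c6/c12/qq vectors for the classical calculation,
# split into MM-MM and QM-involving classes.
classify_pairs <- function(topology, pairs, config, qm_mask, charges) {
  nq <- qm_mask[pairs$i] + qm_mask[pairs$j]
  lj <- pair_lj_coefs(topology, pairs$i, pairs$j)
  c6 <- lj$c6; c12 <- lj$c12
  qq <- charges[pairs$i] * charges[pairs$j]

  # QM-QM: LJ only if requested, never classical Coulomb
  c6[nq == 2 & !config$lj_within_qm] <- 0
  c12[nq == 2 & !config$lj_within_qm] <- 0
  qq[nq == 2] <- 0
  # QM-MM Coulomb handled by the QM program in EE
  if (config$scheme == "EE") qq[nq == 1] <- 0
  list(nqm = nq, c6 = c6, c12 = c12, qq = qq)
}

#' Assemble one QM/MM energy and force evaluation
#'
#' Runs the backend on the QM zone (with capping atoms placed along the
#' declared links) and combines it with the classical force field according
#' to the embedding scheme: in mechanical embedding (MECC/MEDC) the QM-MM
#' interaction is entirely classical with the topology (or dynamically
#' updated) QM charges and no point charges are sent to the backend; in
#' electrostatic embedding (EE) the gathered, optionally scaled MM point
#' charges enter the QM calculation and the classical QM-MM Coulomb terms
#' (including their reaction-field parts) are excluded. QM-MM Lennard-Jones
#' interactions are always classical. Capping-atom forces are redistributed
#' to the link atoms by the chain rule. Dynamic charges (MEDC) emit a
#' warning: no charge-derivative forces are computed, so long simulations
#' are discouraged.
#'
#' @param system a `prepare_qmmm_system()` result (pruned topology + links)
#'   or a [topology()] plus `qmzone` to prepare on the fly.
#' @param state a [system_state()].
#' @param qmzone a [qmzone()].
#' @param config an [embedding_config()].
#' @param backend a `qm_backend`.
#' @param params an [mm_params()].
#' @param pairs optional prepared [build_pairlist()] result.
#' @param first_step flag forwarded to the backend request.
#' @param medc_warn set `FALSE` to silence the per-call MEDC warning (the
#'   dynamics driver warns once per run instead).
#' @return List with `report` (an [energy_report()]), `forces` (n x 3),
#'   `virial`, `updated_charges` (MEDC), and `point_charges` (EE).
#' @export
assemble_qmmm <- function(system, state, qmzone, config, backend, params,
                          pairs = NULL, first_step = FALSE, medc_warn = TRUE) {
  if (inherits(system, "topology"))
    system <- prepare_qmmm_system(system, qmzone, config)
  top <- system$topology
  n <- nrow(top$atoms)
  qm_idx <- qmzone$qm_atoms$index
  qm_mask <- rep(0L, n)
  qm_mask[qm_idx] <- 1L

  if (!is.null(state$box)) {
    vis <- check_periodic_visibility(state, qmzone, config)
    if (!vis$ok)
      stop_miniqmmm("miniqmmm_pbc_violation", vis$message,
                    list(rule = vis$rule, atoms = vis$atoms))
  }

  # --- QM request -----------------------------------------------------------
  qm_pos <- gather_qm_positions(state, qm_idx)
  links <- system$links
  nlink <- nrow(links)
  cap_pos <- NULL
  link_geom <- vector("list", nlink)
  if (nlink > 0) {
    cap_pos <- matrix(0, nlink, 3)
    for (r in seq_len(nlink)) {
      iq <- which(qm_idx == links$qm[r])
      r_qm <- qm_pos[iq, ]
      d_mm <- state$positions[links$mm[r], ] - state$positions[links$qm[r], ]
      if (!is.null(state$box)) d_mm <- min_image(d_mm, state$box)
      r_mm <- r_qm + d_mm
      cap_pos[r, ] <- place_capping_atom(r_qm, r_mm, qmzone$cap_length)
      link_geom[[r]] <- list(r_qm = r_qm, r_mm = r_mm, iq = iq)
    }
  }
  all_pos <- rbind(qm_pos, cap_pos)
  elements <- c(qmzone$qm_atoms$atomic_number, rep(1L, nlink))
  is_cap <- c(rep(FALSE, length(qm_idx)), rep(TRUE, nlink))

  pcs <- NULL
  if (config$scheme == "EE")
    pcs <- gather_point_charges(top, state, qmzone, config)
  request <- qm_request(elements, all_pos, is_cap,
                        point_charges = if (!is.null(pcs) && nrow(pcs)) pcs
                                        else NULL,
                        first_step = first_step)
  result <- backend$evaluate(request)
  if (nrow(result$qm_forces) != length(elements))
    stop("QM backend returned forces for the wrong number of atoms")

  updated_charges <- NULL
  charges <- top$atoms$charge
  if (config$scheme == "MEDC") {
    if (is.null(result$updated_qm_charges))
      stop("MEDC requires the backend to return updated QM charges")
    updated_charges <- result$updated_qm_charges[seq_along(qm_idx)]
    charges[qm_idx] <- updated_charges
    if (medc_warn)
      warning(paste("MEDC dynamic charges: no charge-derivative forces are",
                    "computed; this scheme is discouraged for longer",
                    "simulations"), call. = FALSE)
  }

  # --- classical part -------------------------------------------------------
  if (is.null(pairs)) pairs <- build_pairlist(top, state, params)
  box <- if (is.null(state$box)) numeric(0) else state$box
  cls <- classify_pairs(top, pairs, config, qm_mask, charges)
  kq <- params$coulomb_k * cls$qq

  mm_sel <- cls$nqm == 0
  qm_sel <- !mm_sel
  nb_mm <- cpp_lj_rf(state$positions, pairs$i[mm_sel], pairs$j[mm_sel],
                     cls$c6[mm_sel], cls$c12[mm_sel], kq[mm_sel], box,
                     params$crf, params$rf_cutoff, params$overlap_dist)
  nb_qm <- cpp_lj_rf(state$positions, pairs$i[qm_sel], pairs$j[qm_sel],
                     cls$c6[qm_sel], cls$c12[qm_sel], kq[qm_sel], box,
                     params$crf, params$rf_cutoff, params$overlap_dist)

  # excluded-pair reaction-field terms (kept for intra-QM pairs: the
  # continuum response applies to all charges; dropped for QM-MM pairs in EE)
  ex <- system$ex %||% excluded_pairs(top)
  exq <- params$coulomb_k * charges[ex$i] * charges[ex$j]
  ex_nqm <- qm_mask[ex$i] + qm_mask[ex$j]
  if (config$scheme == "EE") exq[ex_nqm == 1] <- 0
  rf_ex <- cpp_rf_excluded(state$positions, ex$i, ex$j, exq, box, params$crf,
                           params$rf_cutoff)

  bonded <- compute_bonded(top, state)

  forces <- nb_mm$forces + nb_qm$forces + rf_ex$forces + bonded$forces
  virial <- nb_mm$virial + nb_qm$virial + rf_ex$virial + bonded$virial

  # --- scatter QM forces ----------------------------------------------------
  qm_forces_total <- result$qm_forces
  pc_forces <- NULL
  if (config$scheme == "EE" && !is.null(pcs) && nrow(pcs)) {
    recov <- recover_mm_forces(pcs, result, all_pos, params)
    pc_forces <- recov$mm_forces
    forces[pcs$atom, ] <- forces[pcs$atom, ] + pc_forces
    qm_forces_total <- qm_forces_total + recov$qm_forces
  }

  # Virial of the QM evaluation: QM atoms, caps, and gathered point charges
  # form one connected cluster at consistent-image coordinates whose total
  # force vanishes (isolated-system momentum conservation), so sum(f . r)
  # over the cluster is well defined.
  virial <- virial + sum(qm_forces_total * all_pos)
  if (!is.null(pc_forces))
    virial <- virial + sum(pc_forces * cbind(pcs$x, pcs$y, pcs$z))

  nqm_atoms <- length(qm_idx)
  forces[qm_idx, ] <- forces[qm_idx, ] +
    qm_forces_total[seq_len(nqm_atoms), , drop = FALSE]
  if (nlink > 0) {
    for (r in seq_len(nlink)) {
      fl <- qm_forces_total[nqm_atoms + r, ]
      g <- link_geom[[r]]
      dist <- distribute_capping_force(g$r_qm, g$r_mm, qmzone$cap_length, fl)
      forces[links$qm[r], ] <- forces[links$qm[r], ] + dist$f_qm
      forces[links$mm[r], ] <- forces[links$mm[r], ] + dist$f_mm
    }
  }

  ereport <- energy_report(
    bond = bonded$energies$bond, angle = bonded$energies$angle,
    proper = bonded$energies$proper, improper = bonded$energies$improper,
    lj_mm = nb_mm$elj, coulomb_rf_mm = nb_mm$ecoul,
    qm_internal = result$energy,
    qmmm_lj = nb_qm$elj, qmmm_coulomb = nb_qm$ecoul + rf_ex$energy)

  list(report = ereport, forces = forces, virial = virial,
       updated_charges = updated_charges, point_charges = pcs,
       request = request, result = result)
}
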