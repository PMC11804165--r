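# Core domain types: topology, QM-zone specification, system state, energy
# report, and the combined validation of a topology + QM zone.

#' Create a molecular topology
#'
#' A topology bundles the static description of the system: atoms, harmonic
#' bonded terms, the Lennard-Jones table, exclusions, and holonomic distance
#' constraints. All indices are 1-based topology indices.
#'
#' @param atoms data.frame with columns `index`, `atomic_number`, `mass` (u),
#'   `charge` (e), `lj_type` (integer key into the LJ table), `charge_group`
#'   (integer id; groups must be contiguous runs of indices).
#' @param bonds data.frame `i, j, b0, kb`: harmonic bonds,
#'   \eqn{V = k_b (r - b_0)^2 / 2}, `b0` in nm, `kb` in kJ/mol/nm^2.
#' @param angles data.frame `i, j, k, theta0, ktheta` with `j` central,
#'   \eqn{V = k_\theta (\theta - \theta_0)^2 / 2}, `theta0` in degrees,
#'   `ktheta` in kJ/mol/rad^2.
#' @param propers data.frame `i, j, k, l, m, delta, kphi` with central axis
#'   `j`-`k`, \eqn{V = k_\phi (1 + \cos(m\phi - \delta))}, `delta` in degrees.
#' @param impropers data.frame `i, j, k, l, xi0, kxi` with `i` central,
#'   \eqn{V = k_\xi (\xi - \xi_0)^2 / 2}, `xi0` in degrees, `kxi` in
#'   kJ/mol/rad^2.
#' @param exclusions list of integer vectors, one per atom, of excluded
#'   nonbonded partners (stored symmetrically).
#' @param lj_c6,lj_c12 square matrices indexed by `lj_type` with pairwise
#'   C6 (kJ/mol nm^6) and C12 (kJ/mol nm^12) coefficients.
#' @param constraints data.frame `i, j, d0`: distance constraints in nm.
#'
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, bonds = NULL, angles = NULL, propers = NULL,
                     impropers = NULL, exclusions = NULL, lj_c6, lj_c12,
                     constraints = NULL) {
  n <- nrow(atoms)
  if (!identical(as.integer(atoms$index), seq_len(n)))
    stop("atom indices must be unique and contiguous from 1")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (!is.matrix(lj_c6) || !is.matrix(lj_c12) ||
      any(dim(lj_c6) != dim(lj_c12)))
    stop("lj_c6 and lj_c12 must be square matrices of equal size")
  if (any(atoms$lj_type < 1 | atoms$lj_type > nrow(lj_c6)))
    stop("every lj_type must have an entry in the LJ table")
  cg <- as.integer(atoms$charge_group)
  if (any(diff(cg) < 0) || any(!diff(cg) %in% c(0L, 1L)))
    stop("charge groups must be contiguous runs of atom indices")

  empty <- function(x, cols) {
    if (is.null(x) || nrow(x) == 0)
      as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    else x
  }
  bonds <- empty(bonds, c("i", "j", "b0", "kb"))
  angles <- empty(angles, c("i", "j", "k", "theta0", "ktheta"))
  propers <- empty(propers, c("i", "j", "k", "l", "m", "delta", "kphi"))
  impropers <- empty(impropers, c("i", "j", "k", "l", "xi0", "kxi"))
  constraints <- empty(constraints, c("i", "j", "d0"))

  idx_cols <- list(bonds[c("i", "j")], angles[c("i", "j", "k")],
                   propers[c("i", "j", "k", "l")],
                   impropers[c("i", "j", "k", "l")], constraints[c("i", "j")])
  for (tab in idx_cols) {
    ii <- unlist(tab, use.names = FALSE)
    if (length(ii) && (any(ii < 1) || any(ii > n)))
      stop("bonded/constraint term references a non-existent atom")
  }

  if (is.null(exclusions)) exclusions <- rep(list(integer(0)), n)
  # symmetrize and add bonded pairs (bonded atoms never interact nonbonded)
  excl <- lapply(exclusions, as.integer)
  add_pair <- function(i, j) {
    excl[[i]] <<- union(excl[[i]], j)
    excl[[j]] <<- union(excl[[j]], i)
  }
  for (ii in seq_len(n)) for (jj in excl[[ii]]) add_pair(ii, jj)
  if (nrow(bonds)) for (b in seq_len(nrow(bonds))) add_pair(bonds$i[b], bonds$j[b])
  if (nrow(constraints))
    for (b in seq_len(nrow(constraints))) add_pair(constraints$i[b], constraints$j[b])
  excl <- lapply(excl, sort)

  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 propers = propers, impropers = impropers,
                 exclusions = excl, lj_c6 = lj_c6, lj_c12 = lj_c12,
                 constraints = constraints),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d bonds, %d angles, %d propers, %d impropers, %d constraints\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$propers),
              nrow(x$impropers), nrow(x$constraints)))
  invisible(x)
}

#' Specify a QM zone
#'
#' @param net_charge integer net charge of the QM zone (e).
#' @param multiplicity integer spin multiplicity, >= 1.
#' @param qm_atoms data.frame with columns `index` (topology index),
#'   `atomic_number`, and `link_mm` (topology index of the covalently bonded
#'   MM partner, or 0/NA for no link).
#' @param cap_length distance (nm) between a capping hydrogen and its QM atom.
#'
#' @return An object of class `"qmzone"`.
#' @export
qmzone <- function(net_charge, multiplicity, qm_atoms, cap_length = 0.109) {
  if (nrow(qm_atoms) == 0) stop("QM zone must contain at least one atom")
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if (cap_length <= 0) stop("cap_length must be positive")
  if (is.null(qm_atoms$link_mm)) qm_atoms$link_mm <- 0L
  qm_atoms$link_mm[is.na(qm_atoms$link_mm)] <- 0L
  structure(list(net_charge = as.integer(net_charge),
                 multiplicity = as.integer(multiplicity),
                 qm_atoms = qm_atoms, cap_length = cap_length),
            class = "qmzone")
}

#' Create a system state
#'
#' @param positions n x 3 matrix of positions (nm).
#' @param velocities n x 3 matrix of velocities (nm/ps); defaults to zero.
#' @param box rectangular box edge lengths (nm, length 3), or `NULL` for
#'   vacuum.
#' @param time simulation time (ps).
#'
#' @return An object of class `"system_state"`.
#' @export
system_state <- function(positions, velocities = NULL, box = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  if (!all(dim(velocities) == dim(positions)))
    stop("velocities must match positions in shape")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      stop("box must be three positive edge lengths")
  }
  structure(list(positions = positions, velocities = velocities, box = box,
                 time = time), class = "system_state")
}

#' Assemble an energy report
#'
#' The decomposed potential-energy terms of one QM/MM evaluation; `total` is
#' always the sum of the components.
#'
#' @param bond,angle,proper,improper bonded-term energies (kJ/mol).
#' @param lj_mm,coulomb_rf_mm MM-MM nonbonded energies (kJ/mol).
#' @param qm_internal energy returned by the QM backend (kJ/mol).
#' @param qmmm_lj,qmmm_coulomb classical QM-MM coupling energies (kJ/mol).
#'
#' @return An object of class `"energy_report"` with a `total` component.
#' @export
energy_report <- function(bond = 0, angle = 0, proper = 0, improper = 0,
                          lj_mm = 0, coulomb_rf_mm = 0, qm_internal = 0,
                          qmmm_lj = 0, qmmm_coulomb = 0) {
  comps <- c(bond = bond, angle = angle, proper = proper, improper = improper,
             lj_mm = lj_mm, coulomb_rf_mm = coulomb_rf_mm,
             qm_internal = qm_internal, qmmm_lj = qmmm_lj,
             qmmm_coulomb = qmmm_coulomb)
  structure(c(as.list(comps), list(total = sum(comps))),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%14s %12.4f kJ/mol\n", nm, x[[nm]]))
  invisible(x)
}

#' Validate a topology against a QM-zone specification
#'
#' Checks the covalent boundary between QM and MM zones: every bond between a
#' QM atom and an MM atom must carry a declared link, a QM atom may carry at
#' most one link, and a link partner must be an MM atom covalently bonded to
#' its QM atom. On success, returns the list of bonded terms slated for
#' removal from the classical calculation (as computed by
#' [prune_topology()]).
#'
#' @param topology a [topology()] object.
#' @param qmzone a [qmzone()] object.
#'
#' @return A list with elements `removed` (data.frame of term descriptors) and
#'   `links` (data.frame `qm`, `mm`).
#' @export
validate_system <- function(topology, qmzone) {
  qm_idx <- qmzone$qm_atoms$index
  n <- nrow(topology$atoms)
  if (any(qm_idx < 1 | qm_idx > n))
    stop("QM zone references a non-existent atom")
  is_qm <- rep(FALSE, n)
  is_qm[qm_idx] <- TRUE

  # at most a single link per QM atom
  if (anyDuplicated(qm_idx)) {
    dup <- qm_idx[duplicated(qm_idx)][1]
    stop_miniqmmm("miniqmmm_duplicate_link",
                  sprintf("QM atom %d carries more than one declared link", dup))
  }

  links <- qmzone$qm_atoms[qmzone$qm_atoms$link_mm > 0,
                           c("index", "link_mm")]
  names(links) <- c("qm", "mm")

  bonded_pairs <- rbind(topology$bonds[c("i", "j")],
                        stats::setNames(topology$constraints[c("i", "j")],
                                        c("i", "j")))

  if (nrow(links)) {
    for (r in seq_len(nrow(links))) {
      qa <- links$qm[r]; ma <- links$mm[r]
      if (is_qm[ma])
        stop_miniqmmm("miniqmmm_link_partner_is_qm",
                      sprintf("link partner %d of QM atom %d is itself a QM atom",
                              ma, qa))
      hit <- (bonded_pairs$i == qa & bonded_pairs$j == ma) |
             (bonded_pairs$i == ma & bonded_pairs$j == qa)
      if (!any(hit))
        stop_miniqmmm("miniqmmm_missing_link",
                      sprintf("link partner %d of QM atom %d is not covalently bonded to it in the topology",
                              ma, qa))
    }
    # an MM atom linked to two different QM atoms is rejected (conservative)
    if (anyDuplicated(links$mm))
      stop_miniqmmm("miniqmmm_duplicate_link",
                    sprintf("MM atom %d is the link partner of more than one QM atom",
                            links$mm[duplicated(links$mm)][1]))
  }

  # every QM-MM bond must have a declared link
  if (nrow(bonded_pairs)) {
    cross <- xor(is_qm[bonded_pairs$i], is_qm[bonded_pairs$j])
    for (r in which(cross)) {
      qa <- if (is_qm[bonded_pairs$i[r]]) bonded_pairs$i[r] else bonded_pairs$j[r]
      ma <- if (is_qm[bonded_pairs$i[r]]) bonded_pairs$j[r] else bonded_pairs$i[r]
      declared <- any(links$qm == qa & links$mm == ma)
      if (!declared)
        stop_miniqmmm("miniqmmm_missing_link",
                      sprintf("QM atom %d is bonded to MM atom %d but no link is declared",
                              qa, ma))
    }
  }

  pr <- prune_topology(topology, qmzone)
  list(removed = pr$removed, links = links)
}
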