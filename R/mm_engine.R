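# Classical force field: harmonic bonded terms, Lennard-Jones + generalized
# reaction-field nonbonded interactions, charge-group pair list, SHAKE.

#' Parameters of the classical energy model
#'
#' @param rf_cutoff reaction-field cutoff \eqn{R_C} (nm).
#' @param rf_epsilon relative dielectric permittivity \eqn{\epsilon_{RF}} of
#'   the continuum beyond the cutoff (>= 1; 61 for SPC water).
#' @param pairlist_cutoff charge-group pair-list cutoff (nm); defaults to the
#'   reaction-field cutoff (single-range scheme).
#' @param pairlist_update_interval steps between pair-list rebuilds.
#' @param shake_tol relative SHAKE tolerance on squared constraint lengths.
#' @param shake_maxit maximum SHAKE iterations.
#' @param coulomb_k Coulomb constant \eqn{1/(4\pi\epsilon_0)} in
#'   kJ mol^-1 nm e^-2.
#' @param overlap_dist pair distances below this (nm) abort with an overlap
#'   error.
#'
#' @return Object of class `"mm_params"`. The reaction-field constant
#'   \eqn{C_{RF} = (2\epsilon_{RF} - 2) / (2\epsilon_{RF} + 1)} (zero ionic
#'   strength) is precomputed as `$crf`.
#' @export
mm_params <- function(rf_cutoff = 1.4, rf_epsilon = 61,
                      pairlist_cutoff = rf_cutoff,
                      pairlist_update_interval = 5L, shake_tol = 1e-4,
                      shake_maxit = 500L, coulomb_k = qmmm_constants$coulomb_k,
                      overlap_dist = 0.05) {
  stopifnot(rf_epsilon >= 1, rf_cutoff > 0, pairlist_cutoff >= rf_cutoff)
  structure(list(rf_cutoff = rf_cutoff, rf_epsilon = rf_epsilon,
                 pairlist_cutoff = pairlist_cutoff,
                 pairlist_update_interval = as.integer(pairlist_update_interval),
                 shake_tol = shake_tol, shake_maxit = as.integer(shake_maxit),
                 coulomb_k = coulomb_k, overlap_dist = overlap_dist,
                 crf = (2 * rf_epsilon - 2) / (2 * rf_epsilon + 1)),
            class = "mm_params")
}

#' Build the nonbonded pair list
#'
#' Charge-group based: a pair of groups is listed when the minimum-image
#' distance between their geometric centers is within the cutoff; the group
#' pairs are expanded to atom pairs with topological exclusions removed.
#'
#' @param topology a [topology()] object.
#' @param state a [system_state()].
#' @param params an [mm_params()] object.
#'
#' @return Object of class `"pair_list"`: list with integer vectors `i`, `j`.
#' @export
build_pairlist <- function(topology, state, params) {
  box <- state$box
  if (!is.null(box) && params$pairlist_cutoff > min(box) / 2)
    stop(sprintf("pair-list cutoff %.3f nm exceeds half the smallest box edge (%.3f nm)",
                 params$pairlist_cutoff, min(box) / 2))
  pl <- cpp_build_pairlist(state$positions,
                           as.integer(topology$atoms$charge_group),
                           if (is.null(box)) numeric(0) else box,
                           params$pairlist_cutoff, topology$exclusions)
  structure(pl, class = "pair_list")
}

# all excluded pairs (i < j), used for the reaction-field excluded-pair terms
excluded_pairs <- function(topology) {
  i <- rep.int(seq_along(topology$exclusions),
               vapply(topology$exclusions, length, 1L))
  j <- unlist(topology$exclusions, use.names = FALSE)
  keep <- i < j
  list(i = i[keep], j = j[keep])
}

# per-pair LJ coefficients from the topology table
pair_lj_coefs <- function(topology, i, j) {
  ti <- topology$atoms$lj_type[i]; tj <- topology$atoms$lj_type[j]
  idx <- cbind(ti, tj)
  list(c6 = topology$lj_c6[idx], c12 = topology$lj_c12[idx])
}

#' Nonbonded energy and forces: Lennard-Jones + reaction-field Coulomb
#'
#' Evaluates, over a prepared pair list,
#' \deqn{V(r) = C_{12}/r^{12} - C_6/r^6 + k q_i q_j \left( 1/r +
#'   C_{RF} r^2 / (2 R_C^3) - (1 + C_{RF}/2)/R_C \right)}
#' which vanishes at the cutoff for the plain-Coulomb part. The constant and
#' \eqn{r^2}-dependent reaction-field terms are also applied to excluded
#' (intramolecular) pairs, keeping the dielectric response of the continuum
#' consistent for all charges.
#'
#' @param topology a [topology()] object.
#' @param state a [system_state()].
#' @param pairs a [build_pairlist()] result.
#' @param params an [mm_params()].
#' @param charges optional per-atom charge vector overriding the topology
#'   charges.
#'
#' @return List with `energies` (`lj`, `coulomb`; the excluded-pair
#'   reaction-field contribution is part of `coulomb`), `forces` (n x 3), and
#'   the scalar pair `virial`.
#' @export
compute_nonbonded_rf <- function(topology, state, pairs, params,
                                 charges = NULL) {
  q <- charges %||% topology$atoms$charge
  box <- if (is.null(state$box)) numeric(0) else state$box
  lj <- pair_lj_coefs(topology, pairs$i, pairs$j)
  qq <- params$coulomb_k * q[pairs$i] * q[pairs$j]
  nb <- cpp_lj_rf(state$positions, pairs$i, pairs$j, lj$c6, lj$c12, qq, box,
                  params$crf, params$rf_cutoff, params$overlap_dist)
  ex <- excluded_pairs(topology)
  exq <- params$coulomb_k * q[ex$i] * q[ex$j]
  rf <- cpp_rf_excluded(state$positions, ex$i, ex$j, exq, box, params$crf,
                        params$rf_cutoff)
  list(energies = list(lj = nb$elj, coulomb = nb$ecoul + rf$energy),
       forces = nb$forces + rf$forces, virial = nb$virial + rf$virial)
}

# ---- bonded terms -----------------------------------------------------------

dihedral_geometry <- function(r1, r2, r3, r4) {
  b1 <- r2 - r1; b2 <- r3 - r2; b3 <- r4 - r3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- vec_norm(b2)
  cross12 <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
               n1[1] * n2[2] - n1[2] * n2[1])
  phi <- atan2(sum(cross12 * b2) / nb2, sum(n1 * n2))
  list(phi = phi, b1 = b1, b2 = b2, b3 = b3, n1 = n1, n2 = n2, nb2 = nb2)
}

# gradient of the dihedral angle w.r.t. the four positions
dihedral_gradient <- function(g) {
  p <- -(g$nb2 / sum(g$n1 * g$n1)) * g$n1
  q <- (g$nb2 / sum(g$n2 * g$n2)) * g$n2
  sv <- sum(g$b1 * g$b2) / (g$nb2^2)
  sw <- sum(g$b3 * g$b2) / (g$nb2^2)
  list(d1 = p, d2 = -(1 + sv) * p + sw * q, d3 = -(1 + sw) * q + sv * p,
       d4 = q)
}

#' Signed dihedral angle of four positions
#'
#' Standard convention: the angle between the plane through atoms 1,2,3 and
#' the plane through atoms 2,3,4, signed, in degrees in (-180, 180].
#'
#' @param r1,r2,r3,r4 positions (length-3 numerics, nm).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(r1, r2, r3, r4) {
  rad2deg(dihedral_geometry(r1, r2, r3, r4)$phi)
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# vectorized dihedral geometry + angle gradient over term tables
dihedral_geometry_vec <- function(pos, i, j, k, l) {
  b1 <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  b2 <- pos[k, , drop = FALSE] - pos[j, , drop = FALSE]
  b3 <- pos[l, , drop = FALSE] - pos[k, , drop = FALSE]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  phi <- atan2(rowSums(vcross(n1, n2) * b2) / nb2, rowSums(n1 * n2))
  n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
  p <- -(nb2 / n1sq) * n1
  q <- (nb2 / n2sq) * n2
  sv <- rowSums(b1 * b2) / nb2^2
  sw <- rowSums(b3 * b2) / nb2^2
  list(phi = phi, n1sq = n1sq, n2sq = n2sq,
       d1 = p, d2 = -(1 + sv) * p + sw * q, d3 = -(1 + sw) * q + sv * p,
       d4 = q)
}

#' Bonded energies and forces
#'
#' Harmonic bonds and angles, cosine proper dihedrals
#' \eqn{k_\phi (1 + \cos(m\phi - \delta))}, and harmonic improper dihedrals.
#' Forces are exact negative gradients. Degenerate geometries (zero-length
#' bond vectors, collinear angles, collapsed dihedral planes) raise an error
#' naming the term.
#'
#' @param topology a [topology()] object (already pruned when part of a QM/MM
#'   system).
#' @param state a [system_state()].
#'
#' @return List with `energies` (`bond`, `angle`, `proper`, `improper`),
#'   `forces` (n x 3), and the scalar `virial` (valid for whole molecules).
#' @export
compute_bonded <- function(topology, state) {
  pos <- state$positions
  n <- nrow(pos)
  forces <- matrix(0, n, 3)
  e <- c(bond = 0, angle = 0, proper = 0, improper = 0)
  virial <- 0

  # aggregate per-term forces onto atoms (indices may repeat)
  add_forces <- function(idx, mat) {
    forces <<- cpp_accumulate(forces, as.integer(idx), mat)
    virial <<- virial + sum(mat * pos[idx, , drop = FALSE])
  }

  bt <- topology$bonds
  if (nrow(bt)) {
    d <- pos[bt$i, , drop = FALSE] - pos[bt$j, , drop = FALSE]
    rn <- sqrt(rowSums(d^2))
    if (any(rn < 1e-10)) {
      r <- which(rn < 1e-10)[1]
      stop(sprintf("degenerate bond %d-%d: zero-length bond vector",
                   bt$i[r], bt$j[r]))
    }
    e["bond"] <- sum(0.5 * bt$kb * (rn - bt$b0)^2)
    fs <- -bt$kb * (rn - bt$b0) / rn
    add_forces(bt$i, fs * d)
    add_forces(bt$j, -fs * d)
  }

  at <- topology$angles
  if (nrow(at)) {
    rij <- pos[at$i, , drop = FALSE] - pos[at$j, , drop = FALSE]
    rkj <- pos[at$k, , drop = FALSE] - pos[at$j, , drop = FALSE]
    nij <- sqrt(rowSums(rij^2)); nkj <- sqrt(rowSums(rkj^2))
    cth <- pmin(1, pmax(-1, rowSums(rij * rkj) / (nij * nkj)))
    sth <- sqrt(1 - cth^2)
    if (any(sth < 1e-8)) {
      r <- which(sth < 1e-8)[1]
      stop(sprintf("degenerate angle %d-%d-%d: collinear geometry",
                   at$i[r], at$j[r], at$k[r]))
    }
    dth <- acos(cth) - deg2rad(at$theta0)
    e["angle"] <- sum(0.5 * at$ktheta * dth^2)
    coef <- at$ktheta * dth / sth
    fi <- coef * ((rkj / nkj - cth * rij / nij) / nij)
    fk <- coef * ((rij / nij - cth * rkj / nkj) / nkj)
    add_forces(at$i, fi)
    add_forces(at$k, fk)
    add_forces(at$j, -(fi + fk))
  }

  dihedral_class <- function(tab, dV_fun, e_fun, label) {
    g <- dihedral_geometry_vec(pos, tab$i, tab$j, tab$k, tab$l)
    if (any(g$n1sq < 1e-14) || any(g$n2sq < 1e-14)) {
      r <- which(g$n1sq < 1e-14 | g$n2sq < 1e-14)[1]
      stop(sprintf("degenerate %s dihedral %d-%d-%d-%d: collinear atoms",
                   label, tab$i[r], tab$j[r], tab$k[r], tab$l[r]))
    }
    dV <- dV_fun(g$phi)
    add_forces(tab$i, -dV * g$d1)
    add_forces(tab$j, -dV * g$d2)
    add_forces(tab$k, -dV * g$d3)
    add_forces(tab$l, -dV * g$d4)
    e_fun(g$phi)
  }

  pt <- topology$propers
  if (nrow(pt)) {
    e["proper"] <- dihedral_class(pt,
      function(phi) -pt$kphi * pt$m * sin(pt$m * phi - deg2rad(pt$delta)),
      function(phi) sum(pt$kphi * (1 + cos(pt$m * phi - deg2rad(pt$delta)))),
      "proper")
  }

  it <- topology$impropers
  if (nrow(it)) {
    e["improper"] <- dihedral_class(it,
      function(phi) it$kxi * deg2rad(wrap_angle(rad2deg(phi) - it$xi0)),
      function(phi)
        sum(0.5 * it$kxi * deg2rad(wrap_angle(rad2deg(phi) - it$xi0))^2),
      "improper")
  }

  list(energies = as.list(e), forces = forces, virial = virial)
}

#' Restore distance constraints with SHAKE
#'
#' Iteratively corrects trial positions along the reference constraint
#' directions until every constrained distance is within the relative
#' tolerance of its target.
#'
#' @param topology a [topology()] object whose `constraints` are applied.
#' @param reference n x 3 positions before the unconstrained step.
#' @param trial n x 3 trial positions after the unconstrained step.
#' @param params an [mm_params()] (uses `shake_tol`, `shake_maxit`).
#' @param constraints optional data.frame `i, j, d0` overriding the topology
#'   constraint list.
#'
#' @return List with corrected `positions`, `iterations`, and `gsum` (the
#'   accumulated \eqn{\sum \gamma |r_{ref}|^2}, from which the constraint
#'   virial follows as \eqn{-\sum \gamma |r_{ref}|^2 / dt^2}).
#' @export
apply_shake <- function(topology, reference, trial, params,
                        constraints = NULL) {
  cons <- constraints %||% topology$constraints
  if (nrow(cons) == 0) stop("no constraints to apply")
  invmass <- 1 / topology$atoms$mass
  cpp_shake(reference, trial, as.integer(cons$i), as.integer(cons$j),
            cons$d0, invmass, params$shake_tol, params$shake_maxit)
}
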