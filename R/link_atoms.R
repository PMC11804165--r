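# Link-atom scheme: capping-atom placement, chain-rule force redistribution,
# and pruning of bonded terms at the QM/MM boundary.

#' Place a capping hydrogen along a QM-MM link
#'
#' The capping atom sits on the ray from the QM atom towards its MM link
#' partner, at the fixed user-specified distance `d`:
#' \deqn{r_L = r_{QM} + d \, (r_{MM} - r_{QM}) / |r_{MM} - r_{QM}|}
#'
#' @param r_qm,r_mm positions (nm) of the QM atom and its MM link partner.
#' @param d cap length (nm).
#'
#' @return The cap position (length-3 numeric).
#' @export
place_capping_atom <- function(r_qm, r_mm, d) {
  v <- r_mm - r_qm
  dn <- vec_norm(v)
  if (dn < 1e-10) stop("QM and MM link atoms coincide; cap position undefined")
  r_qm + d * v / dn
}

#' Distribute the force on a capping atom to its QM and MM link atoms
#'
#' The cap position is a function of the link atoms' positions only, so the
#' force it carries is redistributed by the chain rule,
#' \eqn{f^{L}_{MM} = J_{MM}^T f_L}, \eqn{f^{L}_{QM} = f_L - f^{L}_{MM}}, with
#' \deqn{J_{MM} = (d / d_{MM-QM}) (I - \hat r \hat r^T)}
#' where \eqn{\hat r} is the unit vector from the QM atom to the MM atom.
#' The two components always sum to the cap force exactly; a cap force
#' parallel to the link axis goes entirely to the QM atom.
#'
#' @param r_qm,r_mm positions (nm) of the link atoms.
#' @param d cap length (nm).
#' @param f_l force on the capping atom (kJ/mol/nm, length 3).
#'
#' @return List with `f_mm`, `f_qm` (the distributed components) and the
#'   geometry used (`d_mm_qm`, `rhat`).
#' @export
distribute_capping_force <- function(r_qm, r_mm, d, f_l) {
  v <- r_mm - r_qm
  dmq <- vec_norm(v)
  if (dmq < 1e-10) stop("QM and MM link atoms coincide; cap force undefined")
  rhat <- v / dmq
  ratio <- d / dmq
  # J_MM^T f_L = ratio * (f_L - (f_L . rhat) rhat); J is symmetric
  f_mm <- ratio * (f_l - sum(f_l * rhat) * rhat)
  list(f_mm = f_mm, f_qm = f_l - f_mm, d_mm_qm = dmq, rhat = rhat)
}

#' Prune bonded terms fully delegated to the QM calculation
#'
#' Removes from the classical topology exactly the bonded terms that the QM
#' calculation describes: bonds with both atoms QM; angles whose central atom
#' is QM; proper dihedrals whose two central atoms are both QM; improper
#' dihedrals whose central (first) atom is QM. Bonds crossing the boundary are
#' kept (they define the links). Distance constraints between two QM atoms
#' are removed as well; the embedding configuration may reinstate them.
#'
#' @param topology a [topology()] object.
#' @param qmzone a [qmzone()] object.
#'
#' @return List with `topology` (the reduced topology), `removed` (data.frame
#'   with columns `class` and `atoms`, one row per removed term), and
#'   `removed_constraints`.
#' @export
prune_topology <- function(topology, qmzone) {
  n <- nrow(topology$atoms)
  is_qm <- rep(FALSE, n)
  is_qm[qmzone$qm_atoms$index] <- TRUE

  removed <- list()
  note <- function(class, tab, rows) {
    if (!any(rows)) return()
    at <- apply(tab[rows, intersect(c("i", "j", "k", "l"), names(tab)),
                    drop = FALSE],
                1, paste, collapse = "-")
    removed[[length(removed) + 1]] <<- data.frame(class = class,
                                                  atoms = unname(at))
  }

  top <- topology
  rb <- is_qm[top$bonds$i] & is_qm[top$bonds$j]
  note("bond", top$bonds, rb)
  top$bonds <- top$bonds[!rb, , drop = FALSE]

  ra <- is_qm[top$angles$j]
  note("angle", top$angles, ra)
  top$angles <- top$angles[!ra, , drop = FALSE]

  rp <- is_qm[top$propers$j] & is_qm[top$propers$k]
  note("proper", top$propers, rp)
  top$propers <- top$propers[!rp, , drop = FALSE]

  ri <- is_qm[top$impropers$i]
  note("improper", top$impropers, ri)
  top$impropers <- top$impropers[!ri, , drop = FALSE]

  rc <- is_qm[top$constraints$i] & is_qm[top$constraints$j]
  removed_constraints <- top$constraints[rc, , drop = FALSE]
  top$constraints <- top$constraints[!rc, , drop = FALSE]

  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(class = character(0), atoms = character(0))
  list(topology = top, removed = removed,
       removed_constraints = removed_constraints)
}
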