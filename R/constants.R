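# Physical constants in the internal unit system (nm, ps, u, e, K, kJ/mol).

#' Physical constants used by the engine
#'
#' @description
#' Named list of constants in the internal unit system (lengths in nm, time in
#' ps, masses in u, charges in e, energies in kJ/mol, temperatures in K):
#' \describe{
#'   \item{coulomb_k}{\eqn{1/(4\pi\epsilon_0)} = 138.9354 kJ mol\eqn{^{-1}}
#'     nm e\eqn{^{-2}}}
#'   \item{kB}{Boltzmann constant, 0.0083144621 kJ mol\eqn{^{-1}} K\eqn{^{-1}}}
#'   \item{R}{molar gas constant, identical to \code{kB} in kJ/mol units}
#'   \item{atm}{1 atmosphere expressed in kJ mol\eqn{^{-1}} nm\eqn{^{-3}}}
#'   \item{c_cm_per_ps}{speed of light in cm/ps, for wavenumber conversion}
#'   \item{hartree_kjmol}{Hartree in kJ/mol (CODATA)}
#'   \item{avogadro}{Avogadro constant in mol\eqn{^{-1}}}
#' }
#' @export
qmmm_constants <- list(
  coulomb_k    = 138.9354,
  kB           = 0.0083144621,
  R            = 0.0083144621,
  atm          = 101325 * 1e-27 * 6.02214076e23 / 1000, # = 0.06102 kJ/mol/nm^3
  c_cm_per_ps  = 2.99792458e-2,                         # speed of light, cm/ps
  hartree_kjmol = 2625.4996394799,
  avogadro     = 6.02214076e23
)

# `%||%` helper
`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimum-image convention for a rectangular box. `d` is an n x 3 displacement
# matrix (or length-3 vector); `box` is NULL for vacuum.
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
  } else {
    d - box * round(d / box)
  }
}

vec_norm <- function(v) sqrt(sum(v * v))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap an angle in degrees to (-180, 180]
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

stop_miniqmmm <- function(class, msg, data = list()) {
  cond <- structure(
    class = c(class, "miniqmmm_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), data)
  )
  stop(cond)
}
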