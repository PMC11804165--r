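# The QM-engine contract: request/result types, unit conversion, an analytic
# mock backend, and the file protocol used to drive external QM programs.

#' Unit-conversion table for a QM program
#'
#' Conversion factors from the QM program's units to the internal units
#' (nm, kJ/mol, kJ/mol/nm, e). Data read from a QM program are multiplied by
#' the factors; data written to it are divided by them.
#'
#' @param length,energy,force,charge positive conversion factors.
#' @return Object of class `"unit_table"`.
#' @examples
#' # a program using Angstrom and Hartree
#' unit_table(length = 0.1, energy = 2625.4996,
#'            force = 26254.996, charge = 1)
#' @export
unit_table <- function(length = 1, energy = 1, force = 1, charge = 1) {
  tab <- c(length = length, energy = energy, force = force, charge = charge)
  if (any(tab <= 0)) stop("unit factors must be positive")
  structure(as.list(tab), class = "unit_table")
}

#' Convert a value between QM-program and internal units
#'
#' @param value numeric value(s).
#' @param kind one of `"length"`, `"energy"`, `"force"`, `"charge"`.
#' @param table a [unit_table()].
#' @param direction `"to_internal"` multiplies by the factor (QM program ->
#'   internal), `"to_qm"` divides (internal -> QM program).
#' @return Converted value(s).
#' @export
convert_units <- function(value, kind, table,
                          direction = c("to_internal", "to_qm")) {
  direction <- match.arg(direction)
  if (!kind %in% names(table)) stop(sprintf("unknown quantity kind '%s'", kind))
  f <- table[[kind]]
  if (direction == "to_internal") value * f else value / f
}

#' Build a QM request
#'
#' The geometry handed to a QM backend: elements and positions of the QM
#' atoms followed by the capping atoms, plus the gathered MM point charges
#' (empty for mechanical embedding).
#'
#' @param elements integer atomic numbers, QM atoms first, then caps.
#' @param positions (nqm + ncap) x 3 positions (nm).
#' @param is_cap logical vector flagging the capping atoms.
#' @param point_charges data.frame `x, y, z, q` or NULL.
#' @param first_step flag toggling initial-guess directives in file backends.
#' @return Object of class `"qm_request"`.
#' @export
qm_request <- function(elements, positions, is_cap = rep(FALSE, length(elements)),
                       point_charges = NULL, first_step = FALSE) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(elements),
            length(is_cap) == length(elements), all(is.finite(positions)))
  structure(list(elements = as.integer(elements), positions = positions,
                 is_cap = as.logical(is_cap), point_charges = point_charges,
                 first_step = isTRUE(first_step)),
            class = "qm_request")
}

#' Parameters of the analytic mock QM backend
#'
#' The mock stands in for an external QM program: an intramolecular MM-style
#' potential (harmonic bonds/angles, cosine dihedrals, harmonic impropers)
#' over the request atoms (QM atoms + caps, indexed in request order), plus
#' fixed internal point charges that interact with external point charges via
#' plain Coulomb. An optional geometry-dependent charge rule
#' \eqn{q_a = q_a^0 + \alpha \sum_{bonds}(b - b_0)} mimics
#' dynamically-updated charges; as in real charge-update schemes, no
#' charge-derivative forces are computed.
#'
#' @param n_atoms number of request atoms the parameters describe.
#' @param bonds,angles,propers,impropers term tables in the same layout as
#'   [topology()], with indices referring to request atom order.
#' @param charges internal point charges (e), one per request atom.
#' @param alpha charge-rule coefficient (e/nm); 0 disables the rule.
#' @return Object of class `"mock_qm_params"`.
#' @export
mock_qm_params <- function(n_atoms, bonds = NULL, angles = NULL,
                           propers = NULL, impropers = NULL,
                           charges = rep(0, n_atoms), alpha = 0) {
  stopifnot(length(charges) == n_atoms)
  structure(list(n_atoms = as.integer(n_atoms), bonds = bonds,
                 angles = angles, propers = propers, impropers = impropers,
                 charges = as.numeric(charges), alpha = alpha),
            class = "mock_qm_params")
}

# mini topology over the request atoms, reusing the bonded machinery
mock_topology <- function(params) {
  n <- params$n_atoms
  atoms <- data.frame(index = seq_len(n), atomic_number = 1, mass = 1,
                      charge = 0, lj_type = 1, charge_group = 1)
  topology(atoms, bonds = params$bonds, angles = params$angles,
           propers = params$propers, impropers = params$impropers,
           lj_c6 = matrix(0, 1, 1), lj_c12 = matrix(0, 1, 1))
}

mock_current_charges <- function(params, positions) {
  q <- params$charges
  if (params$alpha != 0 && !is.null(params$bonds) && nrow(params$bonds)) {
    b <- params$bonds
    s <- 0
    for (r in seq_len(nrow(b))) {
      s <- s + vec_norm(positions[b$i[r], ] - positions[b$j[r], ]) - b$b0[r]
    }
    q <- q + params$alpha * s
  }
  q
}

#' Evaluate the analytic mock QM backend
#'
#' Energy is the intramolecular potential plus the plain Coulomb interaction
#' \eqn{\sum_a \sum_i k q_a q_i / r_{ai}} between internal charges and
#' external point charges; forces are exact negative gradients (treating the
#' internal charges as geometry-independent constants). The MM response is
#' rendered in one of three representations: forces on the point charges,
#' the electric field at their positions, or the internal charges themselves
#' (in which case the engine recovers the pairwise forces and the returned
#' QM forces exclude the external-coupling contribution, which the engine
#' accumulates on both sides).
#'
#' @param request a [qm_request()].
#' @param params a [mock_qm_params()].
#' @param response_mode one of `"forces"`, `"field"`, `"charges"`.
#' @return Object of class `"qm_result"`: list with `energy`, `qm_forces`,
#'   `mm_response` (list `mode`, `values`), `updated_qm_charges`.
#' @export
evaluate_mock_qm <- function(request, params,
                             response_mode = c("forces", "field", "charges"),
                             .topology = NULL) {
  if (length(response_mode) > 1 || !response_mode %in%
        c("forces", "field", "charges"))
    response_mode <- match.arg(response_mode)
  if (length(request$elements) != params$n_atoms)
    stop(sprintf("mock parameters describe %d atoms but request has %d",
                 params$n_atoms, length(request$elements)))
  pos <- request$positions
  top <- .topology %||% mock_topology(params)
  intra <- compute_bonded(top, system_state(pos))
  energy <- sum(unlist(intra$energies))
  qm_forces <- intra$forces
  qcur <- mock_current_charges(params, pos)

  pc <- request$point_charges
  mm_values <- NULL
  if (!is.null(pc) && nrow(pc)) {
    k <- qmmm_constants$coulomb_k
    pcpos <- cbind(pc$x, pc$y, pc$z)
    pcq <- pc$q
    npc <- nrow(pcpos)
    pc_forces <- matrix(0, npc, 3)
    pc_field <- matrix(0, npc, 3)
    coupling_forces <- matrix(0, params$n_atoms, 3)
    ecoul <- 0
    for (a in seq_len(params$n_atoms)) {
      if (qcur[a] == 0) next
      d <- cbind(pcpos[, 1] - pos[a, 1], pcpos[, 2] - pos[a, 2],
                 pcpos[, 3] - pos[a, 3])    # r_i - r_a
      r2 <- rowSums(d * d)
      r <- sqrt(r2)
      ecoul <- ecoul + sum(k * qcur[a] * pcq / r)
      # field at point charge i from internal charge a
      efld <- (k * qcur[a] / (r2 * r)) * d
      pc_field <- pc_field + efld
      fi <- pcq * efld
      pc_forces <- pc_forces + fi
      coupling_forces[a, ] <- coupling_forces[a, ] - colSums(fi)
    }
    energy <- energy + ecoul
    if (response_mode != "charges") qm_forces <- qm_forces + coupling_forces
    mm_values <- switch(response_mode,
      forces = pc_forces,
      field = {
        bad <- pcq == 0 & sqrt(rowSums(pc_forces^2)) > 0
        if (any(bad))
          stop(sprintf("field representation ill-defined: zero charge with nonzero force at point charge %d",
                       which(bad)[1]))
        pc_field
      },
      charges = qcur)
  } else if (response_mode == "charges") {
    mm_values <- qcur
  }

  structure(list(energy = energy, qm_forces = qm_forces,
                 mm_response = list(mode = response_mode, values = mm_values),
                 updated_qm_charges = qcur),
            class = "qm_result")
}

#' In-process mock QM backend
#'
#' @param params a [mock_qm_params()].
#' @param response_mode MM-response representation, see [evaluate_mock_qm()].
#' @return Object of class `"qm_backend"` with an `$evaluate(request)`
#'   closure returning a `qm_result` in internal units.
#' @export
mock_qm_backend <- function(params, response_mode = "forces") {
  mtop <- mock_topology(params)
  structure(list(
    kind = "mock", response_mode = response_mode, params = params,
    evaluate = function(request) evaluate_mock_qm(request, params,
                                                  response_mode,
                                                  .topology = mtop)),
    class = "qm_backend")
}

# ---- file protocol ----------------------------------------------------------

#' Write a QM input file
#'
#' Deterministic plain-text dialect: the header template verbatim (with the
#' token `@GUESS@` replaced by `first` or `restart` according to the
#' `first_step` flag), a `$coordinates <n>` section with one
#' `element x y z` line per atom (capping atoms flagged by a `*` suffix on
#' the element number), a `$pointcharges <m>` section with `x y z q` lines
#' (omitted when empty), and `$end`. All numbers are in the QM program's
#' units.
#'
#' @param request a [qm_request()] (internal units).
#' @param header character vector of template header lines.
#' @param path output file path.
#' @param units a [unit_table()].
#' @return `path`, invisibly.
#' @export
write_qm_request <- function(request, header, path, units = unit_table()) {
  header <- sub("@GUESS@", if (request$first_step) "first" else "restart",
                header, fixed = TRUE)
  pos <- convert_units(request$positions, "length", units, "to_qm")
  lines <- c(header, sprintf("$coordinates %d", nrow(pos)))
  el <- paste0(request$elements, ifelse(request$is_cap, "*", ""))
  lines <- c(lines, sprintf("%-4s %.15e %.15e %.15e", el,
                            pos[, 1], pos[, 2], pos[, 3]))
  pc <- request$point_charges
  if (!is.null(pc) && nrow(pc)) {
    pq <- convert_units(pc$q, "charge", units, "to_qm")
    px <- convert_units(as.matrix(pc[, c("x", "y", "z")]), "length", units,
                        "to_qm")
    lines <- c(lines, sprintf("$pointcharges %d", nrow(pc)),
               sprintf("%.15e %.15e %.15e %.15e", px[, 1], px[, 2], px[, 3], pq))
  }
  lines <- c(lines, "$end")
  writeLines(lines, path)
  invisible(path)
}

#' Read a QM request file
#'
#' Parses the dialect written by [write_qm_request()] back into a
#' [qm_request()] in internal units. Used by the fake-executable fixture.
#'
#' @param path input file path.
#' @param units a [unit_table()].
#' @return A [qm_request()].
#' @export
read_qm_request <- function(path, units = unit_table()) {
  lines <- readLines(path)
  ic <- grep("^\\$coordinates", lines)
  if (length(ic) != 1) stop(sprintf("%s: missing $coordinates section", path))
  n <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  coord <- lines[(ic + 1):(ic + n)]
  fields <- strsplit(trimws(coord), "\\s+")
  el_raw <- vapply(fields, `[`, "", 1)
  is_cap <- grepl("\\*$", el_raw)
  elements <- as.integer(sub("\\*$", "", el_raw))
  pos <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (any(!is.finite(pos))) stop(sprintf("%s: non-numeric coordinate", path))
  pos <- convert_units(pos, "length", units, "to_internal")
  pc <- NULL
  ip <- grep("^\\$pointcharges", lines)
  if (length(ip) == 1) {
    m <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    vals <- t(vapply(strsplit(trimws(lines[(ip + 1):(ip + m)]), "\\s+"),
                     as.numeric, numeric(4)))
    pc <- data.frame(
      x = convert_units(vals[, 1], "length", units, "to_internal"),
      y = convert_units(vals[, 2], "length", units, "to_internal"),
      z = convert_units(vals[, 3], "length", units, "to_internal"),
      q = convert_units(vals[, 4], "charge", units, "to_internal"))
  }
  qm_request(elements, pos, is_cap, pc,
             first_step = any(grepl("\\bfirst\\b", lines[seq_len(ic - 1)])))
}

#' Write a QM result file
#'
#' Output dialect of the fake executable: `$energy` + one value,
#' `$qm_forces <n>` + force lines, `$mm_response <mode> <m>` + one line per
#' point charge (or per QM atom in `charges` mode), optional
#' `$qm_charges <n>`, and `$end`. Numbers in QM-program units.
#'
#' @param result a `qm_result` (internal units).
#' @param path output file path.
#' @param units a [unit_table()].
#' @return `path`, invisibly.
#' @export
write_qm_result <- function(result, path, units = unit_table()) {
  f <- convert_units(result$qm_forces, "force", units, "to_qm")
  lines <- c("$energy",
             sprintf("%.15e", convert_units(result$energy, "energy", units,
                                            "to_qm")),
             sprintf("$qm_forces %d", nrow(f)),
             sprintf("%.15e %.15e %.15e", f[, 1], f[, 2], f[, 3]))
  mr <- result$mm_response
  if (!is.null(mr$values)) {
    v <- mr$values
    if (mr$mode == "forces") {
      v <- convert_units(v, "force", units, "to_qm")
      lines <- c(lines, sprintf("$mm_response forces %d", nrow(v)),
                 sprintf("%.15e %.15e %.15e", v[, 1], v[, 2], v[, 3]))
    } else if (mr$mode == "field") {
      # field = force / charge
      v <- convert_units(convert_units(v, "charge", units, "to_internal"),
                         "force", units, "to_qm")
      lines <- c(lines, sprintf("$mm_response field %d", nrow(v)),
                 sprintf("%.15e %.15e %.15e", v[, 1], v[, 2], v[, 3]))
    } else {
      v <- convert_units(v, "charge", units, "to_qm")
      lines <- c(lines, sprintf("$mm_response charges %d", length(v)),
                 sprintf("%.15e", v))
    }
  }
  if (!is.null(result$updated_qm_charges)) {
    qc <- convert_units(result$updated_qm_charges, "charge", units, "to_qm")
    lines <- c(lines, sprintf("$qm_charges %d", length(qc)),
               sprintf("%.15e", qc))
  }
  lines <- c(lines, "$end")
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a QM result file
#'
#' @param path output file of the QM program.
#' @param n_qm expected number of QM + capping atoms.
#' @param n_pc expected number of point charges.
#' @param response_mode expected MM-response representation.
#' @param units a [unit_table()]; the result is converted to internal units.
#' @return A `qm_result`.
#' @export
read_qm_result <- function(path, n_qm, n_pc = 0,
                           response_mode = c("forces", "field", "charges"),
                           units = unit_table()) {
  response_mode <- match.arg(response_mode)
  if (!file.exists(path)) stop(sprintf("QM output file %s does not exist", path))
  lines <- readLines(path)

  grab_block <- function(tag, nrows, ncols) {
    ix <- grep(paste0("^\\$", tag, "\\b"), lines)
    if (length(ix) != 1)
      stop(sprintf("%s: missing $%s section", path, tag))
    declared <- strsplit(lines[ix], "\\s+")[[1]]
    got <- suppressWarnings(as.integer(declared[length(declared)]))
    if (!is.na(got) && got != nrows)
      stop(sprintf("%s line %d: $%s declares %d entries, expected %d",
                   path, ix, tag, got, nrows))
    if (ix + nrows > length(lines))
      stop(sprintf("%s: truncated $%s section (expected %d lines)", path, tag,
                   nrows))
    block <- lines[(ix + 1):(ix + nrows)]
    vals <- suppressWarnings(
      t(vapply(strsplit(trimws(block), "\\s+"),
               function(f) as.numeric(f[seq_len(ncols)]), numeric(ncols))))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(sprintf("%s line %d: non-numeric or truncated field in $%s",
                   path, ix + ((bad[1] - 1) %% nrows) + 1, tag))
    vals
  }

  energy <- grab_block("energy", 1, 1)[1, 1]
  qm_forces <- grab_block("qm_forces", n_qm, 3)
  mm_values <- NULL
  if (response_mode == "charges") {
    mm_values <- as.numeric(grab_block("mm_response", n_qm, 1))
  } else if (n_pc > 0) {
    mm_values <- grab_block("mm_response", n_pc, 3)
  }
  upd <- NULL
  if (any(grepl("^\\$qm_charges", lines)))
    upd <- convert_units(as.numeric(grab_block("qm_charges", n_qm, 1)),
                         "charge", units, "to_internal")

  mm_conv <- if (is.null(mm_values)) NULL else switch(response_mode,
    forces = convert_units(mm_values, "force", units, "to_internal"),
    field = convert_units(convert_units(mm_values, "force", units,
                                        "to_internal"),
                          "charge", units, "to_qm"),
    charges = convert_units(mm_values, "charge", units, "to_internal"))

  structure(list(
    energy = convert_units(energy, "energy", units, "to_internal"),
    qm_forces = convert_units(qm_forces, "force", units, "to_internal"),
    mm_response = list(mode = response_mode, values = mm_conv),
    updated_qm_charges = upd), class = "qm_result")
}

#' File-protocol QM backend
#'
#' Drives an external executable through the input/output dialect of
#' [write_qm_request()] / [read_qm_result()]: the engine writes the input
#' file, invokes `executable <input> <output>`, and parses the output.
#' When `input_path`/`output_path` are not given, uniquely named temporary
#' files are created (honoring `TMPDIR`) and removed after each call;
#' user-specified paths are kept for debugging.
#'
#' @param executable path to the QM program (or fake-executable fixture).
#' @param header character vector of header template lines.
#' @param units a [unit_table()] describing the program's units.
#' @param response_mode expected MM-response representation.
#' @param input_path,output_path optional fixed file paths.
#' @return Object of class `"qm_backend"`.
#' @export
file_qm_backend <- function(executable, header = character(),
                            units = unit_table(), response_mode = "forces",
                            input_path = NULL, output_path = NULL) {
  force(executable); force(units); force(response_mode)
  structure(list(
    kind = "file", response_mode = response_mode, executable = executable,
    evaluate = function(request) {
      keep <- !is.null(input_path)
      fin <- input_path %||% tempfile("qmin_", fileext = ".inp")
      fout <- output_path %||% tempfile("qmout_", fileext = ".out")
      if (!keep) on.exit(unlink(c(fin, fout)), add = TRUE)
      write_qm_request(request, header, fin, units)
      status <- suppressWarnings(
        system2(executable, args = c(fin, fout), stdout = FALSE,
                stderr = FALSE))
      if (status != 0)
        stop(sprintf("QM executable %s exited with status %d", executable,
                     status))
      n_pc <- if (is.null(request$point_charges)) 0 else
        nrow(request$point_charges)
      read_qm_result(fout, length(request$elements), n_pc, response_mode,
                     units)
    }), class = "qm_backend")
}

#' Entry point of the fake QM executable fixture
#'
#' Reads a QM input file, evaluates the mock potential, and writes the output
#' file. The generated fake executable calls this function; it exercises the
#' full subprocess/file pathway without any real QM dependency.
#'
#' @param input_path,output_path file paths handed to the executable.
#' @param params a [mock_qm_params()].
#' @param response_mode MM-response representation.
#' @param units a [unit_table()].
#' @return Invisibly, the `qm_result` written.
#' @export
fake_qm_main <- function(input_path, output_path, params,
                         response_mode = "forces", units = unit_table()) {
  request <- read_qm_request(input_path, units)
  result <- evaluate_mock_qm(request, params, response_mode)
  write_qm_result(result, output_path, units)
  invisible(result)
}
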