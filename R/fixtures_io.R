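# File formats, configuration blocks, and synthetic-system generators: SPC
# water boxes, a toy tripeptide with a QM sidechain, the QM-specification
# parser, coordinate I/O, and the fake external QM executable.

element_symbols <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                     "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar")

# ---- QM specification file --------------------------------------------------

#' Parse a QM-specification file
#'
#' Block-structured plain text (`BLOCKNAME` ... `END`). The `QMZONE` block
#' starts with a one-line header `net_charge multiplicity`; each following
#' atom line ignores its first 17 characters (cnf-style prefix) and then
#' lists the atom topology index, atomic number, and linked MM atom (0 for
#' none), whitespace-separated. `QMUNIT` holds the four conversion factors
#' (length, energy, force, charge), `CAPLEN` the capping bond length (nm),
#' and the optional `QMHEADER` / `QMBINARY` blocks the header template and
#' executable path of a file-protocol backend.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return List with `qmzone` (a [qmzone()]), `units` (a [unit_table()]),
#'   and `backend` (list with `header`, `binary`; possibly NULL).
#' @export
parse_qm_spec <- function(text) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n")[[1]]
  blocks <- list()
  i <- 1
  while (i <= length(text)) {
    name <- trimws(text[i])
    if (name == "" || startsWith(name, "#")) { i <- i + 1; next }
    end <- i + 1
    while (end <= length(text) && trimws(text[end]) != "END") end <- end + 1
    if (end > length(text))
      stop(sprintf("line %d: block %s has no END", i, name))
    blocks[[name]] <- list(lines = text[(i + 1):(end - 1)], start = i)
    i <- end + 1
  }
  if (is.null(blocks$QMZONE)) stop("missing QMZONE block")

  zl <- blocks$QMZONE$lines
  zstart <- blocks$QMZONE$start
  head_fields <- strsplit(trimws(zl[1]), "\\s+")[[1]]
  if (length(head_fields) != 2 || anyNA(suppressWarnings(as.numeric(head_fields))))
    stop(sprintf("line %d: QMZONE header must be 'net_charge multiplicity'",
                 zstart + 1))
  atoms <- list()
  for (r in seq_along(zl)[-1]) {
    line <- zl[r]
    if (trimws(line) == "") next
    if (nchar(line) < 18)
      stop(sprintf("line %d: QMZONE atom line shorter than the 17-character prefix",
                   zstart + r))
    fields <- strsplit(trimws(substring(line, 18)), "\\s+")[[1]]
    vals <- suppressWarnings(as.integer(fields))
    if (length(vals) != 3 || anyNA(vals))
      stop(sprintf("line %d: expected 'index atomic_number link' after the 17-character prefix",
                   zstart + r))
    atoms[[length(atoms) + 1]] <- data.frame(index = vals[1],
                                             atomic_number = vals[2],
                                             link_mm = vals[3])
  }
  if (!length(atoms)) stop("QMZONE block lists no atoms")
  qm_atoms <- do.call(rbind, atoms)

  units <- unit_table()
  if (!is.null(blocks$QMUNIT)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(
      paste(blocks$QMUNIT$lines, collapse = " ")), "\\s+")[[1]]))
    if (length(f) != 4 || anyNA(f))
      stop("QMUNIT block must hold four factors: length energy force charge")
    units <- unit_table(length = f[1], energy = f[2], force = f[3],
                        charge = f[4])
  }
  cap_length <- 0.109
  if (!is.null(blocks$CAPLEN))
    cap_length <- as.numeric(trimws(blocks$CAPLEN$lines[1]))

  backend <- NULL
  if (!is.null(blocks$QMHEADER) || !is.null(blocks$QMBINARY))
    backend <- list(header = blocks$QMHEADER$lines,
                    binary = if (!is.null(blocks$QMBINARY))
                      trimws(blocks$QMBINARY$lines[1]) else NULL)

  list(qmzone = qmzone(as.integer(head_fields[1]),
                       as.integer(head_fields[2]), qm_atoms, cap_length),
       units = units, backend = backend)
}

#' Parse a simulation-parameter file
#'
#' Block-structured plain text. The `QMMM` block holds, in order: the
#' embedding-scheme code `NTQMMM` (0 off, -1 MECC, 1 MEDC, 2 EE), the
#' gathering cutoff (nm), the write frequency `NTWQMMM` (steps), the
#' LJ-within-QM flag (0/1), the QM bond-constraint flag (0/1), the charge
#' scaling parameter `s` (1/nm, <= 0 off), and the gathering mode
#' (`atomic` or `group`). The `MD` block holds: ensemble (`NVE`/`NVT`/`NPT`),
#' time step (ps), step count, reference temperature (K), temperature
#' relaxation time (ps), reference pressure (atm), pressure relaxation time
#' (ps), and the random seed.
#'
#' @param text character vector of lines, or a single string with newlines.
#' @return List with `embedding` (an [embedding_config()], or `NULL` when
#'   `NTQMMM` is 0) and `run` (a [run_config()]).
#' @export
parse_sim_params <- function(text) {
  if (length(text) == 1 && grepl("\n", text))
    text <- strsplit(text, "\n")[[1]]
  grab <- function(name) {
    ix <- which(trimws(text) == name)
    if (length(ix) != 1) return(NULL)
    end <- ix + 1
    while (end <= length(text) && trimws(text[end]) != "END") end <- end + 1
    if (end > length(text)) stop(sprintf("block %s has no END", name))
    strsplit(trimws(paste(text[(ix + 1):(end - 1)], collapse = " ")),
             "\\s+")[[1]]
  }

  embedding <- NULL
  f <- grab("QMMM")
  if (!is.null(f)) {
    if (length(f) != 7)
      stop("QMMM block must hold: NTQMMM cutoff NTWQMMM lj_flag constraint_flag scaling gathering")
    code <- as.integer(f[1])
    if (code != 0L) {
      embedding <- embedding_config(
        scheme = code, qmmm_cutoff = as.numeric(f[2]),
        write_frequency = as.integer(f[3]),
        lj_within_qm = as.integer(f[4]) != 0,
        constrain_qm_bonds = as.integer(f[5]) != 0,
        charge_scaling_s = as.numeric(f[6]),
        gathering = if (f[7] %in% c("group", "charge-group")) "charge-group"
                    else "atomic")
    }
  }

  m <- grab("MD")
  if (is.null(m)) stop("missing MD block")
  if (length(m) != 8)
    stop("MD block must hold: ensemble dt n_steps T0 tau_T P0 tau_P seed")
  run <- run_config(ensemble = toupper(m[1]), dt = as.numeric(m[2]),
                    n_steps = as.integer(m[3]), T0 = as.numeric(m[4]),
                    tau_T = as.numeric(m[5]), P0 = as.numeric(m[6]),
                    tau_P = as.numeric(m[7]), seed = as.integer(m[8]))
  list(embedding = embedding, run = run)
}

# ---- coordinate I/O ---------------------------------------------------------

#' Write coordinates in extended XYZ format
#'
#' One frame: atom count, a comment line carrying the box (`box Lx Ly Lz
#' time t`, or `vacuum time t`), then `element x y z` lines in nm.
#'
#' @param state a [system_state()].
#' @param path output file.
#' @param elements atomic numbers (or symbols) per atom.
#' @param append append a trajectory frame instead of overwriting.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(state, path, elements, append = FALSE) {
  sym <- if (is.numeric(elements)) element_symbols[elements] else elements
  comment <- if (is.null(state$box)) sprintf("vacuum time %.6f", state$time)
             else sprintf("box %.6f %.6f %.6f time %.6f", state$box[1],
                          state$box[2], state$box[3], state$time)
  lines <- c(sprintf("%d", nrow(state$positions)), comment,
             sprintf("%-3s %12.5f %12.5f %12.5f", sym,
                     state$positions[, 1], state$positions[, 2],
                     state$positions[, 3]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Read extended XYZ coordinates
#'
#' @param path input file (one or more concatenated frames).
#' @param n_atoms optional expected atom count; mismatches raise an error.
#' @return List of [system_state()] objects, one per frame; elements are
#'   attached as attribute `"elements"`.
#' @export
read_coordinates <- function(path, n_atoms = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1; next }
    n <- as.integer(trimws(lines[i]))
    if (is.na(n)) stop(sprintf("%s line %d: expected atom count", path, i))
    if (!is.null(n_atoms) && n != n_atoms)
      stop(sprintf("%s line %d: frame has %d atoms, topology has %d", path, i,
                   n, n_atoms))
    comment <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    box <- NULL
    time <- 0
    if (comment[1] == "box") {
      box <- as.numeric(comment[2:4])
      if ("time" %in% comment)
        time <- as.numeric(comment[which(comment == "time") + 1])
    } else if (comment[1] == "vacuum" && "time" %in% comment) {
      time <- as.numeric(comment[which(comment == "time") + 1])
    }
    rows <- strsplit(trimws(lines[(i + 2):(i + 1 + n)]), "\\s+")
    pos <- t(vapply(rows, function(f) as.numeric(f[2:4]), numeric(3)))
    st <- system_state(pos, box = box, time = time)
    attr(st, "elements") <- vapply(rows, `[`, "", 1)
    frames[[length(frames) + 1]] <- st
    i <- i + 2 + n
  }
  frames
}

#' Write coordinates in a GRO-like fixed-width dialect
#'
#' @param state a [system_state()].
#' @param path output file.
#' @param elements atomic numbers or symbols.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_gro <- function(state, path, elements, title = "miniqmmm") {
  sym <- if (is.numeric(elements)) element_symbols[elements] else elements
  n <- nrow(state$positions)
  lines <- c(title, sprintf("%5d", n),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "MOL", sym,
                     seq_len(n), state$positions[, 1], state$positions[, 2],
                     state$positions[, 3]),
             if (is.null(state$box)) sprintf("%10.5f%10.5f%10.5f", 0, 0, 0)
             else sprintf("%10.5f%10.5f%10.5f", state$box[1], state$box[2],
                          state$box[3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO-like fixed-width coordinate file
#'
#' @param path input file.
#' @return A [system_state()] (box of all zeros is read as vacuum).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  body <- lines[3:(2 + n)]
  pos <- cbind(as.numeric(substring(body, 21, 28)),
               as.numeric(substring(body, 29, 36)),
               as.numeric(substring(body, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  if (all(box == 0)) box <- NULL
  system_state(pos, box = box)
}

# ---- synthetic systems ------------------------------------------------------

# exclusion sets from the bond graph: every pair within `depth` bonds
exclusions_from_bonds <- function(bonds, n, depth = 2) {
  adj <- rep(list(integer(0)), n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  excl <- rep(list(integer(0)), n)
  for (a in seq_len(n)) {
    seen <- a
    frontier <- a
    for (d in seq_len(depth)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, frontier)
    }
    excl[[a]] <- sort(setdiff(seen, a))
  }
  excl
}

#' SPC water model constants
#'
#' Canonical simple-point-charge water: charges -0.82/+0.41 e, O-O
#' Lennard-Jones sigma 0.3166 nm and epsilon 0.650 kJ/mol, rigid O-H bonds of
#' 0.1 nm and an H-H distance of 0.163299 nm (109.47 degree angle). The
#' flexible variant (used when a water molecule is made vibratile for
#' QM-mimicking tests) follows the SPC/Fw reparameterization: b0 = 0.1012
#' nm, kb = 443153 kJ/mol/nm^2, theta0 = 113.24 deg,
#' ktheta = 317.5656 kJ/mol/rad^2.
#'
#' @return Named list of the constants above.
#' @export
spc_constants <- function() {
  sigma <- 0.3166
  eps <- 0.650
  list(q_o = -0.82, q_h = 0.41, mass_o = 15.9994, mass_h = 1.008,
       c6_oo = 4 * eps * sigma^6, c12_oo = 4 * eps * sigma^12,
       d_oh = 0.1, d_hh = 2 * 0.1 * sin(deg2rad(109.47) / 2),
       theta_hoh = 109.47,
       flex_b0 = 0.1012, flex_kb = 443153,
       flex_theta0 = 113.24, flex_ktheta = 317.5656)
}

random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a periodic SPC water box
#'
#' Molecules are placed on a perturbed cubic lattice with random rigid-body
#' orientations; the box edge follows from the target density,
#' \eqn{L = (n m_w / (\rho N_A))^{1/3}}. The generated configuration is
#' deterministic for a fixed seed and guarantees a minimum intermolecular
#' O-O distance of 0.24 nm.
#'
#' @param n_molecules number of water molecules (>= 2).
#' @param density target mass density (kg/m^3).
#' @param seed integer seed.
#' @param flexible make molecule 1 flexible (harmonic bonds/angle instead of
#'   constraints), e.g. to treat it as the QM molecule with a mimicking
#'   backend; `"all"` makes every molecule flexible.
#' @return List with `topology`, `state`, and `elements` (atomic numbers);
#'   atoms are ordered O, H, H per molecule.
#' @export
build_water_box <- function(n_molecules, density = 997, seed = 1,
                            flexible = FALSE) {
  stopifnot(n_molecules >= 2)
  spc <- spc_constants()
  m_w <- spc$mass_o + 2 * spc$mass_h
  vol <- n_molecules * m_w * 1.66053906660 / density   # nm^3
  l <- vol^(1 / 3)
  nside <- ceiling(n_molecules^(1 / 3))
  spacing <- l / nside

  set.seed(seed)
  cells <- expand.grid(x = 0:(nside - 1), y = 0:(nside - 1),
                       z = 0:(nside - 1))[seq_len(n_molecules), ]
  centers <- (as.matrix(cells) + 0.5) * spacing +
    matrix(stats::runif(3 * n_molecules, -0.015, 0.015), n_molecules, 3)

  # rigid SPC geometry in the molecular frame, oxygen on the lattice site
  half <- deg2rad(spc$theta_hoh) / 2
  mol <- rbind(c(0, 0, 0),
               c(spc$d_oh * sin(half), 0, spc$d_oh * cos(half)),
               c(-spc$d_oh * sin(half), 0, spc$d_oh * cos(half)))

  pos <- matrix(0, 3 * n_molecules, 3)
  for (m in seq_len(n_molecules)) {
    rot <- random_rotation()
    pos[(3 * m - 2):(3 * m), ] <- mol %*% t(rot) +
      matrix(centers[m, ], 3, 3, byrow = TRUE)
  }

  # minimum intermolecular O-O distance
  o_idx <- seq(1, 3 * n_molecules, by = 3)
  omat <- pos[o_idx, , drop = FALSE]
  dmin <- Inf
  for (m in seq_len(n_molecules - 1)) {
    d <- min_image(sweep(omat[(m + 1):n_molecules, , drop = FALSE], 2,
                         omat[m, ]), rep(l, 3))
    dmin <- min(dmin, sqrt(min(rowSums(d * d))))
  }
  if (dmin < 0.24)
    stop(sprintf("density %g kg/m3 unachievable without overlap at n = %d (min O-O %.3f nm)",
                 density, n_molecules, dmin))

  which_flex <- if (identical(flexible, "all")) seq_len(n_molecules)
                else if (isTRUE(flexible)) 1L else integer(0)

  n_atoms <- 3 * n_molecules
  atoms <- data.frame(index = seq_len(n_atoms),
                      atomic_number = rep(c(8L, 1L, 1L), n_molecules),
                      mass = rep(c(spc$mass_o, spc$mass_h, spc$mass_h),
                                 n_molecules),
                      charge = rep(c(spc$q_o, spc$q_h, spc$q_h), n_molecules),
                      lj_type = rep(c(1L, 2L, 2L), n_molecules),
                      charge_group = rep(seq_len(n_molecules), each = 3))
  lj_c6 <- matrix(0, 2, 2); lj_c12 <- matrix(0, 2, 2)
  lj_c6[1, 1] <- spc$c6_oo; lj_c12[1, 1] <- spc$c12_oo

  bonds <- NULL; angles <- NULL; cons <- NULL
  for (m in seq_len(n_molecules)) {
    o <- 3 * m - 2
    if (m %in% which_flex) {
      bonds <- rbind(bonds, data.frame(i = o, j = c(o + 1, o + 2),
                                       b0 = spc$flex_b0, kb = spc$flex_kb))
      angles <- rbind(angles, data.frame(i = o + 1, j = o, k = o + 2,
                                         theta0 = spc$flex_theta0,
                                         ktheta = spc$flex_ktheta))
    } else {
      cons <- rbind(cons, data.frame(i = c(o, o, o + 1),
                                     j = c(o + 1, o + 2, o + 2),
                                     d0 = c(spc$d_oh, spc$d_oh, spc$d_hh)))
    }
  }
  excl <- lapply(seq_len(n_atoms), function(a) {
    o <- 3 * ((a - 1) %/% 3) + 1
    setdiff(o:(o + 2), a)
  })

  top <- topology(atoms, bonds = bonds, angles = angles, exclusions = excl,
                  lj_c6 = lj_c6, lj_c12 = lj_c12, constraints = cons)
  list(topology = top,
       state = system_state(pos, box = rep(l, 3)),
       elements = atoms$atomic_number)
}

#' QM zone selecting one water molecule
#'
#' @param mol_index which molecule of a [build_water_box()] system.
#' @return A [qmzone()] with no links (whole-molecule QM zone).
#' @export
water_qmzone <- function(mol_index = 1) {
  o <- 3 * mol_index - 2
  qmzone(0, 1, data.frame(index = c(o, o + 1, o + 2),
                          atomic_number = c(8L, 1L, 1L), link_mm = 0L))
}

#' Mock parameters mirroring the pruned terms of a QM zone
#'
#' Builds [mock_qm_params()] that reproduce, in request-atom order, exactly
#' the bonded terms [prune_topology()] removes. With this backend a
#' mechanical-embedding run is algebraically identical to the pure-MM run on
#' the unpartitioned system. Only QM zones whose removed terms lie entirely
#' inside the zone are supported (e.g. whole molecules).
#'
#' @param topology a [topology()].
#' @param qmzone a [qmzone()].
#' @return A [mock_qm_params()].
#' @export
mock_mm_mirror <- function(topology, qmzone) {
  pr <- prune_topology(topology, qmzone)
  qm_idx <- qmzone$qm_atoms$index
  loc <- function(ix) {
    out <- match(ix, qm_idx)
    if (anyNA(out))
      stop("mock_mm_mirror supports only QM zones whose removed terms are entirely intra-QM")
    out
  }
  orig <- topology
  in_qm <- function(tab, cols) {
    keep <- rep(TRUE, nrow(tab))
    for (cc in cols) keep <- keep & tab[[cc]] %in% qm_idx
    keep
  }
  rb <- orig$bonds[in_qm(orig$bonds, c("i", "j")), , drop = FALSE]
  ra <- orig$angles[orig$angles$j %in% qm_idx, , drop = FALSE]
  rp <- orig$propers[orig$propers$j %in% qm_idx &
                       orig$propers$k %in% qm_idx, , drop = FALSE]
  ri <- orig$impropers[orig$impropers$i %in% qm_idx, , drop = FALSE]
  remap <- function(tab, cols) {
    if (nrow(tab) == 0) return(NULL)
    for (cc in cols) tab[[cc]] <- loc(tab[[cc]])
    tab
  }
  mock_qm_params(length(qm_idx),
                 bonds = remap(rb, c("i", "j")),
                 angles = remap(ra, c("i", "j", "k")),
                 propers = remap(rp, c("i", "j", "k", "l")),
                 impropers = remap(ri, c("i", "j", "k", "l")),
                 charges = topology$atoms$charge[qm_idx])
}

# NeRF placement: position of a new atom at distance r from c_pos, angle
# theta with b_pos, dihedral phi with a_pos
place_zmatrix_atom <- function(c_pos, b_pos, a_pos, r, theta_deg, phi_deg) {
  th <- deg2rad(theta_deg); ph <- deg2rad(phi_deg)
  bc <- c_pos - b_pos; bc <- bc / vec_norm(bc)
  ab <- b_pos - a_pos
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / vec_norm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c_pos + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Build the toy tripeptide fixture
#'
#' An all-atom alanine-X-alanine-like chain (19 atoms) whose central
#' sidechain (C-beta + hydrogens, C-gamma + hydrogens) forms the QM zone,
#' linked to the classical backbone through the C-alpha - C-beta bond.
#' Following common force-field practice for aliphatic link atoms, the
#' boundary MM atom (C-alpha) carries zero charge. Full bonded terms cross
#' the boundary so that the pruning rules are exercised; the exact set of
#' terms delegated to the QM calculation ships as the attribute
#' `"expected_removed"` (the fixture's ground-truth manifest).
#'
#' @param seed integer seed for the small coordinate jitter.
#' @param cap_length capping-bond length (nm).
#' @return List with `topology`, `state`, `qmzone`, `elements`, and
#'   `scan_atoms` (the C - C-alpha - C-beta - C-gamma quadruple, atoms
#'   15-6-8-11); attribute `"expected_removed"` lists the pruned terms.
#' @export
build_toy_tripeptide <- function(seed = 1, cap_length = 0.109) {
  # z-matrix: atom, parent, angle ref, dihedral ref, r, theta, phi
  zmat <- rbind(
    c(4, 2, 1, 3, 0.133, 115, 180),   # N
    c(5, 4, 2, 1, 0.100, 119, 0),     # H(N)
    c(6, 4, 2, 1, 0.147, 122, 180),   # CA
    c(7, 6, 4, 2, 0.109, 108, -60),   # HA
    c(8, 6, 4, 2, 0.153, 111, 180),   # CB
    c(9, 8, 6, 4, 0.109, 109, 60),    # HB1
    c(10, 8, 6, 4, 0.109, 109, -60),  # HB2
    c(11, 8, 6, 4, 0.153, 112, 180),  # CG
    c(12, 11, 8, 6, 0.109, 109, 60),  # HG1
    c(13, 11, 8, 6, 0.109, 109, 180), # HG2
    c(14, 11, 8, 6, 0.109, 109, -60), # HG3
    c(15, 6, 4, 2, 0.153, 111, 60),   # C
    c(16, 15, 6, 4, 0.123, 121, -150),# O
    c(17, 15, 6, 4, 0.133, 115, 30),  # N
    c(18, 17, 15, 6, 0.100, 119, 0),  # H(N)
    c(19, 17, 15, 6, 0.147, 122, 180) # CH3
  )
  pos <- matrix(0, 19, 3)
  pos[1, ] <- c(0, 0, 0)                               # CH3 (ala1)
  pos[2, ] <- c(0.153, 0, 0)                           # C
  pos[3, ] <- pos[2, ] + 0.123 * c(cos(deg2rad(180 - 121)),
                                   sin(deg2rad(180 - 121)), 0)  # O
  for (r in seq_len(nrow(zmat))) {
    z <- zmat[r, ]
    pos[z[1], ] <- place_zmatrix_atom(pos[z[2], ], pos[z[3], ], pos[z[4], ],
                                      z[5], z[6], z[7])
  }
  set.seed(seed)
  pos <- pos + matrix(stats::runif(19 * 3, -0.002, 0.002), 19, 3)

  elements <- c(6, 6, 8, 7, 1, 6, 1, 6, 1, 1, 6, 1, 1, 1, 6, 8, 7, 1, 6)
  masses <- c(12.011, 12.011, 15.9994, 14.0067, 1.008, 12.011, 1.008, 12.011,
              1.008, 1.008, 12.011, 1.008, 1.008, 1.008, 12.011, 15.9994,
              14.0067, 1.008, 12.011)
  charges <- c(0, 0.45, -0.45, -0.31, 0.31, 0, 0, 0, 0, 0, 0, 0, 0, 0,
               0.45, -0.45, -0.31, 0.31, 0)
  # lj types: 1 C, 2 H, 3 O, 4 N
  lj_type <- c(1, 1, 3, 4, 2, 1, 2, 1, 2, 2, 1, 2, 2, 2, 1, 3, 4, 2, 1)
  charge_group <- c(1, 2, 2, 3, 3, 3, 3, 4, 4, 4, 5, 5, 5, 5, 6, 6, 7, 7, 7)

  sig <- c(0.336, 0.240, 0.296, 0.325)
  eps <- c(0.406, 0.100, 0.880, 0.710)
  c6i <- 4 * eps * sig^6
  c12i <- 4 * eps * sig^12
  lj_c6 <- sqrt(outer(c6i, c6i))
  lj_c12 <- sqrt(outer(c12i, c12i))

  kb_heavy <- 300000; kb_h <- 350000
  bond_tab <- rbind(
    c(1, 2, 0.153), c(2, 3, 0.123), c(2, 4, 0.133), c(4, 5, 0.100),
    c(4, 6, 0.147), c(6, 7, 0.109), c(6, 8, 0.153), c(8, 9, 0.109),
    c(8, 10, 0.109), c(8, 11, 0.153), c(11, 12, 0.109), c(11, 13, 0.109),
    c(11, 14, 0.109), c(6, 15, 0.153), c(15, 16, 0.123), c(15, 17, 0.133),
    c(17, 18, 0.100), c(17, 19, 0.147))
  is_h_bond <- bond_tab[, 2] %in% which(elements == 1) |
    bond_tab[, 1] %in% which(elements == 1)
  bonds <- data.frame(i = bond_tab[, 1], j = bond_tab[, 2],
                      b0 = bond_tab[, 3],
                      kb = ifelse(is_h_bond, kb_h, kb_heavy))

  angle_tab <- rbind(
    c(1, 2, 3, 121), c(1, 2, 4, 115), c(3, 2, 4, 124),
    c(2, 4, 5, 119), c(2, 4, 6, 122), c(5, 4, 6, 119),
    c(4, 6, 7, 108), c(4, 6, 8, 111), c(4, 6, 15, 111), c(7, 6, 8, 109),
    c(7, 6, 15, 109), c(8, 6, 15, 109),
    c(6, 8, 9, 109), c(6, 8, 10, 109), c(6, 8, 11, 112), c(9, 8, 10, 108),
    c(9, 8, 11, 110), c(10, 8, 11, 110),
    c(8, 11, 12, 109), c(8, 11, 13, 109), c(8, 11, 14, 109),
    c(12, 11, 13, 108), c(12, 11, 14, 108), c(13, 11, 14, 108),
    c(6, 15, 16, 121), c(6, 15, 17, 115), c(16, 15, 17, 124),
    c(15, 17, 18, 119), c(15, 17, 19, 122), c(18, 17, 19, 119))
  angles <- data.frame(i = angle_tab[, 1], j = angle_tab[, 2],
                       k = angle_tab[, 3], theta0 = angle_tab[, 4],
                       ktheta = 450)

  propers <- data.frame(
    i = c(1, 2, 15, 6, 4, 6), j = c(2, 4, 6, 8, 6, 15),
    k = c(4, 6, 8, 11, 15, 17), l = c(6, 15, 11, 12, 17, 19),
    m = c(2, 3, 3, 3, 3, 2), delta = c(180, 0, 0, 0, 0, 180),
    kphi = c(33.5, 2.0, 5.92, 5.92, 2.0, 33.5))

  imp_tab <- rbind(c(2, 1, 3, 4), c(4, 2, 5, 6), c(8, 6, 9, 10),
                   c(15, 6, 16, 17), c(17, 15, 18, 19))
  xi0 <- apply(imp_tab, 1, function(q)
    round(dihedral_angle(pos[q[1], ], pos[q[2], ], pos[q[3], ], pos[q[4], ]),
          1))
  impropers <- data.frame(i = imp_tab[, 1], j = imp_tab[, 2],
                          k = imp_tab[, 3], l = imp_tab[, 4], xi0 = xi0,
                          kxi = 167.36)

  atoms <- data.frame(index = 1:19, atomic_number = elements, mass = masses,
                      charge = charges, lj_type = lj_type,
                      charge_group = charge_group)
  top <- topology(atoms, bonds = bonds, angles = angles, propers = propers,
                  impropers = impropers,
                  exclusions = exclusions_from_bonds(bonds, 19, depth = 2),
                  lj_c6 = lj_c6, lj_c12 = lj_c12)

  qm <- qmzone(0, 1, data.frame(index = c(8, 9, 10, 11, 12, 13, 14),
                                atomic_number = c(6, 1, 1, 6, 1, 1, 1),
                                link_mm = c(6, 0, 0, 0, 0, 0, 0)),
               cap_length = cap_length)

  expected_removed <- list(
    bonds = rbind(c(8, 9), c(8, 10), c(8, 11), c(11, 12), c(11, 13),
                  c(11, 14)),
    angles = rbind(c(6, 8, 9), c(6, 8, 10), c(6, 8, 11), c(9, 8, 10),
                   c(9, 8, 11), c(10, 8, 11), c(8, 11, 12), c(8, 11, 13),
                   c(8, 11, 14), c(12, 11, 13), c(12, 11, 14), c(13, 11, 14)),
    propers = rbind(c(6, 8, 11, 12)),
    impropers = rbind(c(8, 6, 9, 10)))

  out <- list(topology = top, state = system_state(pos), qmzone = qm,
              elements = elements, scan_atoms = c(15, 6, 8, 11))
  attr(out, "expected_removed") <- expected_removed
  out
}

#' Mock QM parameters for the tripeptide sidechain
#'
#' Mirrors the bonded terms that pruning removes from the tripeptide,
#' substituting the capping atom for the boundary MM atom (C-alpha) in terms
#' that cross the link, and adds the cap bond itself. Small internal charges
#' (summing to zero) give the zone a dipole so that electrostatic embedding
#' has a non-trivial coupling.
#'
#' @param fixture a [build_toy_tripeptide()] result.
#' @return A [mock_qm_params()] over the 8 request atoms (7 QM + 1 cap).
#' @export
tripeptide_mock_params <- function(fixture) {
  top <- fixture$topology
  qm_idx <- fixture$qmzone$qm_atoms$index
  cap_local <- length(qm_idx) + 1L
  loc <- function(ix) ifelse(ix == 6, cap_local, match(ix, qm_idx))

  rb <- top$bonds[top$bonds$i %in% qm_idx & top$bonds$j %in% qm_idx, ]
  ra <- top$angles[top$angles$j %in% qm_idx, ]
  rp <- top$propers[top$propers$j %in% qm_idx & top$propers$k %in% qm_idx, ]
  ri <- top$impropers[top$impropers$i %in% qm_idx, ]

  bonds <- data.frame(i = loc(rb$i), j = loc(rb$j), b0 = rb$b0, kb = rb$kb)
  bonds <- rbind(bonds,
                 data.frame(i = match(8, qm_idx), j = cap_local,
                            b0 = fixture$qmzone$cap_length, kb = 350000))
  angles <- data.frame(i = loc(ra$i), j = loc(ra$j), k = loc(ra$k),
                       theta0 = ra$theta0, ktheta = ra$ktheta)
  propers <- data.frame(i = loc(rp$i), j = loc(rp$j), k = loc(rp$k),
                        l = loc(rp$l), m = rp$m, delta = rp$delta,
                        kphi = rp$kphi)
  impropers <- data.frame(i = loc(ri$i), j = loc(ri$j), k = loc(ri$k),
                          l = loc(ri$l), xi0 = ri$xi0, kxi = ri$kxi)
  charges <- c(-0.06, 0.02, 0.02, -0.09, 0.03, 0.03, 0.03, 0.02)
  mock_qm_params(cap_local, bonds = bonds, angles = angles,
                 propers = propers, impropers = impropers, charges = charges)
}

#' Generate the fake external QM executable
#'
#' Writes an executable script that reads a [write_qm_request()] input file,
#' evaluates the given mock potential through [fake_qm_main()], and writes a
#' [read_qm_result()] output file. It exercises the full subprocess/file
#' pathway of a [file_qm_backend()] without any real QM program.
#'
#' @param params a [mock_qm_params()].
#' @param response_mode MM-response representation.
#' @param path where to write the executable.
#' @param units a [unit_table()] the fake program "works in".
#' @return `path`, invisibly.
#' @export
make_fake_qm_executable <- function(params, response_mode = "forces",
                                    path = tempfile("fakeqm_"),
                                    units = unit_table()) {
  lib_paths <- paste(sprintf('"%s"', .libPaths()), collapse = ", ")
  script <- c(
    "#!/usr/bin/env Rscript",
    sprintf(".libPaths(c(%s, .libPaths()))", lib_paths),
    "suppressPackageStartupMessages(library(miniqmmm))",
    "args <- commandArgs(trailingOnly = TRUE)",
    sprintf("params <- %s", paste(deparse(params), collapse = "\n")),
    sprintf("units <- unit_table(length = %.17g, energy = %.17g, force = %.17g, charge = %.17g)",
            units$length, units$energy, units$force, units$charge),
    "status <- tryCatch({",
    sprintf("  fake_qm_main(args[1], args[2], params, response_mode = \"%s\", units = units)",
            response_mode),
    "  0L",
    "}, error = function(e) { message(conditionMessage(e)); 1L })",
    "quit(status = status)")
  writeLines(script, path)
  Sys.chmod(path, "0755")
  invisible(path)
}
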