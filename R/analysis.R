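# Trajectory observables: radial distribution functions, autocorrelation
# power spectra, hydrogen bonds and lifetimes, improper-dihedral series, and
# the vaporization-enthalpy estimator.

#' Radial distribution function
#'
#' Standard normalization: shell counts divided by the ideal-gas expectation
#' at each frame's density, under the minimum-image convention.
#'
#' @param trajectory a `"trajectory"` object from [run_simulation()].
#' @param sel_a,sel_b integer atom selections (may be identical).
#' @param bin_width histogram bin width (nm).
#' @param r_max maximum distance (nm); must not exceed half the smallest box
#'   edge.
#' @return data.frame with bin centers `r` (nm) and `g`.
#' @export
radial_distribution <- function(trajectory, sel_a, sel_b, bin_width = 0.002,
                                r_max = NULL) {
  nframes <- length(trajectory$positions)
  if (nframes == 0) stop("empty trajectory")
  boxes <- trajectory$boxes
  if (is.null(boxes[[1]])) stop("radial distribution requires a periodic box")
  half_min <- min(vapply(boxes, min, 1)) / 2
  r_max <- r_max %||% half_min
  if (r_max > half_min + 1e-9)
    stop(sprintf("r_max %.3f nm exceeds half the smallest box edge (%.3f nm)",
                 r_max, half_min))
  nbin <- ceiling(r_max / bin_width)
  acc <- numeric(nbin)
  for (f in seq_len(nframes)) {
    pos <- trajectory$positions[[f]]
    box <- boxes[[f]]
    hist <- cpp_dist_hist(pos, as.integer(sel_a), as.integer(sel_b), box,
                          bin_width, r_max)
    vol <- prod(box)
    n_b <- length(sel_b) - as.integer(identical(sort(sel_a), sort(sel_b)))
    rho_b <- if (identical(sort(sel_a), sort(sel_b)))
      (length(sel_b) - 1) / vol else length(sel_b) / vol
    edges <- bin_width * (0:nbin)
    shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbin + 1)]^3)
    acc <- acc + hist / (length(sel_a) * rho_b * shell)
  }
  data.frame(r = bin_width * (seq_len(nbin) - 0.5), g = acc / nframes)
}

#' Locate the first maxima of a radial distribution function
#'
#' Applies a short running-mean smoothing (to suppress counting noise in
#' narrow bins), then finds the global first peak, the following minimum
#' within `window` of it, and the second peak (the first maximum beyond the
#' first minimum) within `window` of the minimum.
#'
#' @param rdf data.frame from [radial_distribution()].
#' @param smooth half-width of the running mean, in bins.
#' @param window search range (nm) after the first peak for the minimum, and
#'   after the minimum for the second peak.
#' @return List with `first_max`, `first_min`, `second_max` (abscissae, nm).
#' @export
find_rdf_peaks <- function(rdf, smooth = 5L, window = 0.2) {
  g <- rdf$g
  n <- length(g)
  dr <- rdf$r[2] - rdf$r[1]
  if (smooth > 0) {
    k <- 2 * smooth + 1
    g <- as.numeric(stats::filter(g, rep(1 / k, k), sides = 2))
    g[is.na(g)] <- rdf$g[is.na(g)]
  }
  w <- max(2L, round(window / dr))
  i_max1 <- which.max(g)
  lo <- min(n, i_max1 + 1)
  hi <- min(n, i_max1 + w)
  i_min1 <- lo + which.min(g[lo:hi]) - 1
  lo2 <- min(n, i_min1 + 1)
  hi2 <- min(n, i_min1 + w)
  i_max2 <- lo2 + which.max(g[lo2:hi2]) - 1
  list(first_max = rdf$r[i_max1], first_min = rdf$r[i_min1],
       second_max = if (i_max2 > i_min1 && i_max2 < n) rdf$r[i_max2]
                    else NA_real_)
}

#' Power spectrum of a uniformly sampled series
#'
#' The mean-subtracted series' autocorrelation function is computed (up to
#' half the series length), tapered with a Hann window, and Fourier
#' transformed; the abscissa is converted to wavenumbers (cm^-1) using the
#' sampling interval and the speed of light. Peak positions are the
#' contract; intensities are arbitrary units.
#'
#' @param values numeric series (e.g. a bond length per frame).
#' @param dt_ps sampling interval (ps).
#' @param max_lag autocorrelation length; defaults to half the series.
#' @return data.frame with `wavenumber` (cm^-1) and `intensity`.
#' @export
power_spectrum <- function(values, dt_ps, max_lag = NULL) {
  n <- length(values)
  if (n < 8) stop("series too short for a power spectrum")
  x <- values - mean(values)
  m <- max_lag %||% (n %/% 2)
  # autocorrelation via FFT with zero padding
  pad <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, rep(0, pad - n)))
  ac_full <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[1:(m + 1)]
  ac <- ac_full / (n - 0:m)            # unbiased normalization
  ac <- ac / ac[1]
  hann <- 0.5 * (1 + cos(pi * (0:m) / m))
  acw <- ac * hann
  # one-sided spectrum of the symmetric autocorrelation
  nfft <- 2^ceiling(log2(4 * (m + 1)))
  sp <- Re(stats::fft(c(acw, rep(0, nfft - (m + 1)))))
  nk <- nfft %/% 2
  freq <- (0:(nk - 1)) / (nfft * dt_ps)             # cycles per ps
  wav <- freq / qmmm_constants$c_cm_per_ps          # cm^-1
  data.frame(wavenumber = wav, intensity = abs(sp[1:nk]))
}

#' Geometric hydrogen-bond detection with lifetimes
#'
#' A hydrogen bond is present in a frame when the H...acceptor distance is
#' within `dist_cutoff` and the donor-H...acceptor angle is at least
#' `angle_cutoff`. Lifetimes are the lengths of maximal contiguous
#' present-runs times the frame interval (continuous definition).
#'
#' @param trajectory a `"trajectory"` object.
#' @param donors data.frame with columns `d` (donor heavy atom) and `h`
#'   (its hydrogen).
#' @param acceptors integer vector of acceptor atom indices.
#' @param dist_cutoff H...A distance cutoff (nm).
#' @param angle_cutoff D-H...A angle cutoff (degrees).
#' @return List with `bonds` (data.frame `donor`, `hydrogen`, `acceptor`,
#'   `n_frames`), `presence` (logical matrix, frames x bonds), `lifetimes`
#'   (numeric vector, ps), and `counts` (bonds present per frame).
#' @export
hydrogen_bonds <- function(trajectory, donors, acceptors, dist_cutoff = 0.25,
                           angle_cutoff = 135) {
  if (nrow(donors) == 0 || length(acceptors) == 0)
    stop("empty donor or acceptor selection")
  nframes <- length(trajectory$positions)
  combos <- expand.grid(di = seq_len(nrow(donors)),
                        ai = seq_along(acceptors))
  combos <- combos[donors$d[combos$di] != acceptors[combos$ai], , drop = FALSE]
  nb <- nrow(combos)
  presence <- matrix(FALSE, nframes, nb)
  for (f in seq_len(nframes)) {
    pos <- trajectory$positions[[f]]
    box <- trajectory$boxes[[f]]
    dpos <- pos[donors$d[combos$di], , drop = FALSE]
    hpos <- pos[donors$h[combos$di], , drop = FALSE]
    apos <- pos[acceptors[combos$ai], , drop = FALSE]
    ha <- min_image(apos - hpos, box)
    dha <- sqrt(rowSums(ha^2))
    hd <- min_image(dpos - hpos, box)
    cosang <- rowSums(ha * hd) / (dha * sqrt(rowSums(hd^2)))
    # angle D-H...A >= cutoff <=> cos(angle between H->D and H->A) <= cos(cutoff)
    presence[f, ] <- dha <= dist_cutoff & cosang <= cos(deg2rad(angle_cutoff))
  }
  dt <- if (nframes > 1) trajectory$times[2] - trajectory$times[1] else 1
  lifetimes <- numeric(0)
  for (b in seq_len(nb)) {
    r <- rle(presence[, b])
    lifetimes <- c(lifetimes, r$lengths[r$values] * dt)
  }
  keep <- colSums(presence) > 0
  list(bonds = data.frame(donor = donors$d[combos$di],
                          hydrogen = donors$h[combos$di],
                          acceptor = acceptors[combos$ai],
                          n_frames = colSums(presence))[keep, , drop = FALSE],
       presence = presence, lifetimes = lifetimes,
       counts = rowSums(presence))
}

#' Improper-dihedral series of a hydrogen-bond acceptor
#'
#' Tracks the signed O-C-H...Hb improper dihedral characterizing the
#' geometry of a donated hydrogen bond at a hydroxyl acceptor: `o`, `c`, `h`
#' are fixed atoms (hydroxyl oxygen, adjacent carbon, hydroxyl hydrogen);
#' `hb` is chosen per frame as the closest candidate hydrogen within
#' `dist_cutoff` of the oxygen (nearest-acceptor rule). Frames without a
#' bound hydrogen are skipped.
#'
#' @param trajectory a `"trajectory"` object.
#' @param o,c_adj,h atom indices of the oxygen, adjacent carbon, and
#'   hydroxyl hydrogen.
#' @param hb_candidates candidate donated-hydrogen indices.
#' @param dist_cutoff O...Hb distance cutoff (nm).
#' @return data.frame with `time`, `hb` (chosen hydrogen), `angle` (signed
#'   degrees in (-180, 180]); skipped frames are omitted.
#' @export
improper_dihedral_series <- function(trajectory, o, c_adj, h, hb_candidates,
                                     dist_cutoff = 0.25) {
  out <- list()
  for (f in seq_along(trajectory$positions)) {
    pos <- trajectory$positions[[f]]
    box <- trajectory$boxes[[f]]
    d <- min_image(pos[hb_candidates, , drop = FALSE] -
                     matrix(pos[o, ], length(hb_candidates), 3, byrow = TRUE),
                   box)
    dn <- sqrt(rowSums(d^2))
    sel <- which.min(dn)
    if (!length(sel) || dn[sel] > dist_cutoff) next
    hb <- hb_candidates[sel]
    hb_pos <- pos[o, ] + d[sel, ]       # minimum-image position
    ang <- dihedral_angle(pos[o, ], pos[c_adj, ], pos[h, ], hb_pos)
    out[[length(out) + 1]] <- data.frame(time = trajectory$times[f], hb = hb,
                                         angle = ang)
  }
  if (!length(out))
    return(data.frame(time = numeric(0), hb = integer(0), angle = numeric(0)))
  do.call(rbind, out)
}

#' Solute-solvent interaction energy of a tagged selection
#'
#' Lennard-Jones plus reaction-field Coulomb energy between the atoms of
#' `sel` and the rest of the system, over the pairs of the charge-group
#' cutoff scheme (same force field as the dynamics).
#'
#' @param topology a [topology()].
#' @param state a [system_state()].
#' @param sel integer atom selection (the tagged molecule).
#' @param params an [mm_params()].
#' @return Interaction energy (kJ/mol).
#' @export
interaction_energy <- function(topology, state, sel, params) {
  pairs <- build_pairlist(topology, state, params)
  in_sel <- rep(FALSE, nrow(topology$atoms))
  in_sel[sel] <- TRUE
  lj <- pair_lj_coefs(topology, pairs$i, pairs$j)
  q <- topology$atoms$charge
  qq <- params$coulomb_k * q[pairs$i] * q[pairs$j]
  box <- if (is.null(state$box)) numeric(0) else state$box
  ce <- cpp_cross_energy(state$positions, pairs$i, pairs$j, in_sel, lj$c6,
                         lj$c12, qq, box, params$crf, params$rf_cutoff)
  ce$elj + ce$ecoul
}

#' Vaporization enthalpy from the solute-solvent interaction energy
#'
#' For a homogeneous liquid whose solute is chemically identical to the
#' solvent, \deqn{\Delta H_{vap} = -\langle E_{uv} \rangle / 2 + RT} where
#' \eqn{E_{uv}} is the interaction energy of one molecule with all others:
#' each pair energy is shared between two molecules, and the pV term of the
#' vapor is approximated by RT.
#'
#' @param euv_series per-frame interaction energies (kJ/mol).
#' @param temperature temperature (K).
#' @param se_threshold warn when the blocked standard error of the mean
#'   exceeds this (kJ/mol).
#' @return \eqn{\Delta H_{vap}} in kJ/mol.
#' @export
vaporization_enthalpy <- function(euv_series, temperature,
                                  se_threshold = 2) {
  m <- mean(euv_series)
  n <- length(euv_series)
  if (n >= 20) {
    nb <- 10
    blocks <- split(euv_series, cut(seq_len(n), nb, labels = FALSE))
    bm <- vapply(blocks, mean, 1)
    se <- stats::sd(bm) / sqrt(nb)
    if (se > se_threshold)
      warning(sprintf("interaction-energy series poorly converged (blocked SE %.2f kJ/mol)",
                      se))
  }
  -m / 2 + qmmm_constants$R * temperature
}
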