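# ---- ensemble series -------------------------------------------------

#' Per-frame observable series for one pressure condition
#'
#' A thin validated wrapper around a data frame of per-frame observables:
#' required columns `time` and `volume` (Angstrom^3); optional `temperature`
#' (K), `pressure` (MPa), named energy-term columns (kcal/mol), a
#' precomputed polar-solvation column, and a solvent-accessible area column
#' (Angstrom^2).
#'
#' @param df Data frame of per-frame observables.
#' @return The data frame with class `ensemble_series`.
#' @export
ensemble_series <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("time", "volume") %in% names(df))) {
    stop("series needs at least 'time' and 'volume' columns")
  }
  if (any(df$volume <= 0)) stop("volumes must be positive")
  if ("temperature" %in% names(df) && any(df$temperature <= 0)) {
    stop("temperatures must be positive")
  }
  if (anyNA(df)) stop("missing values in observable series")
  class(df) <- unique(c("ensemble_series", class(df)))
  df
}

#' Read a per-frame observable table
#'
#' Delimited text with a header naming the columns; `#` lines are metadata.
#'
#' @param path File path.
#' @return An [ensemble_series()].
#' @export
read_ensemble_series <- function(path) {
  ensemble_series(utils::read.table(path, header = TRUE, sep = "\t",
                                    comment.char = "#",
                                    stringsAsFactors = FALSE))
}

#' Write a per-frame observable table
#'
#' @param series An [ensemble_series()].
#' @param path Output path.
#' @param meta Character vector of metadata lines (written `#`-prefixed).
#' @export
write_ensemble_series <- function(series, path, meta = character(0)) {
  .write_report(as.data.frame(series), path, meta)
}

# frame indices of the analysis window (tail fraction)
.window_idx <- function(n, constants) {
  start <- n - floor(n * constants$window_fraction) + 1L
  idx <- start:n
  if (length(idx) < 2L) stop("analysis window has fewer than 2 frames")
  idx
}

# split indices into non-overlapping blocks (drop remainder frames)
.blocks <- function(idx, n_blocks) {
  bs <- length(idx) %/% n_blocks
  if (bs < 1) return(list(idx))
  lapply(seq_len(n_blocks), function(b) idx[((b - 1) * bs + 1):(b * bs)])
}

# ---- isothermal compressibility --------------------------------------

#' Isothermal compressibility from volume fluctuations
#'
#' Estimates `kappa_T = (<V^2> - <V>^2) / (kB * T * <V>)` over the analysis
#' window, in GPa^-1. The temperature is the window mean of the series'
#' `temperature` column (or `constants$temperature` when absent).
#' Uncertainty is the SD of the estimator over non-overlapping blocks.
#'
#' @param series An [ensemble_series()].
#' @param constants A [thermo_constants()].
#' @return List of class `kappa_estimate`: `value` (whole-window estimate,
#'   GPa^-1), `block_mean`, `block_sd`, `blocks` (per-block estimates),
#'   `temperature`, `n_frames`.
#' @export
isothermal_compressibility <- function(series,
                                       constants = thermo_constants()) {
  stopifnot(inherits(series, "ensemble_series"))
  idx <- .window_idx(nrow(series), constants)
  temp <- if ("temperature" %in% names(series)) {
    mean(series$temperature[idx])
  } else constants$temperature
  est <- function(v) {
    varv <- mean(v^2) - mean(v)^2               # population variance, A^6
    kBT <- .KB_J * temp / 1e-30                 # Pa A^3
    (varv / (kBT * mean(v))) * 1e9              # Pa^-1 -> GPa^-1
  }
  v <- series$volume[idx]
  blocks <- vapply(.blocks(idx, constants$n_blocks),
                   function(b) est(series$volume[b]), numeric(1))
  structure(list(value = est(v), block_mean = mean(blocks),
                 block_sd = stats::sd(blocks), blocks = blocks,
                 temperature = temp, n_frames = length(v)),
            class = "kappa_estimate")
}

#' Pressure-difference of isothermal compressibility
#'
#' The reported pressure-response statistic: `kappa_T(high) -
#' kappa_T(low)`, with the block SDs combined in quadrature.
#'
#' @param high,low [ensemble_series()] for the high- and low-pressure
#'   conditions.
#' @param constants A [thermo_constants()].
#' @return List: `delta` (GPa^-1), `sd`, `high`, `low` (the two
#'   `kappa_estimate`s).
#' @export
delta_compressibility <- function(high, low,
                                  constants = thermo_constants()) {
  kh <- isothermal_compressibility(high, constants)
  kl <- isothermal_compressibility(low, constants)
  list(delta = kh$value - kl$value,
       sd = sqrt(kh$block_sd^2 + kl$block_sd^2),
       high = kh, low = kl)
}

# ---- trajectories and RMSF -------------------------------------------

#' Coordinate trajectory container
#'
#' @param coords Numeric array `frames x atoms x 3` (Angstrom), finite.
#' @param masses Per-atom masses (amu); default the carbon mass 12.011 for
#'   every atom (a Calpha trace).
#' @param residue Per-atom residue numbers (default 1..natoms).
#' @return List of class `coord_trajectory`.
#' @export
coordinate_trajectory <- function(coords,
                                  masses = rep(12.011, dim(coords)[2]),
                                  residue = seq_len(dim(coords)[2])) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  n <- dim(coords)[2]
  stopifnot(length(masses) == n, length(residue) == n, all(masses > 0))
  structure(list(coords = coords, masses = masses, residue = residue),
            class = "coord_trajectory")
}

.as_trajectory <- function(traj) {
  if (inherits(traj, "coord_trajectory")) return(traj)
  if (is.list(traj) && !is.null(traj$coords)) {
    return(coordinate_trajectory(traj$coords,
                                 traj$masses %||% rep(12.011,
                                                      dim(traj$coords)[2]),
                                 traj$residue %||%
                                   seq_len(dim(traj$coords)[2])))
  }
  stop("cannot interpret object as a coordinate trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Kabsch rotation aligning x (n x 3) onto ref (n x 3), both centred
.kabsch <- function(x, ref) {
  s <- svd(crossprod(x, ref))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# least-squares superposition of every frame onto the iterated mean
# structure; returns the aligned frames x atoms x 3 array
.superpose <- function(coords, n_iter = 2) {
  nf <- dim(coords)[1]
  aligned <- coords
  for (f in seq_len(nf)) {
    x <- aligned[f, , , drop = TRUE]
    aligned[f, , ] <- sweep(x, 2L, colMeans(x))
  }
  ref <- aligned[1, , , drop = TRUE]
  for (it in seq_len(n_iter)) {
    for (f in seq_len(nf)) {
      x <- aligned[f, , , drop = TRUE]
      aligned[f, , ] <- x %*% .kabsch(x, ref)
    }
    ref <- apply(aligned, c(2, 3), mean)
  }
  aligned
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is least-squares superposed onto the (iteratively refined)
#' mean structure, then `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`. The default
#' residue selection is the rhodopsin helix window
#' [rhodopsin_helix_window()] when the trajectory's residue numbering
#' overlaps it, otherwise all residues.
#'
#' @param traj A [coordinate_trajectory()] (or compatible list).
#' @param residues Residue numbers to analyse; `NULL` for the default.
#' @param superpose Superpose frames first (default `TRUE`).
#' @return Data frame `residue`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, residues = NULL, superpose = TRUE) {
  traj <- .as_trajectory(traj)
  if (is.null(residues)) {
    residues <- intersect(traj$residue, rhodopsin_helix_window())
    if (!length(residues)) residues <- traj$residue
  }
  keep <- traj$residue %in% residues
  if (!any(keep)) stop("residue selection is empty")
  coords <- traj$coords[, keep, , drop = FALSE]
  if (superpose && dim(coords)[2] >= 3) coords <- .superpose(coords)
  mu <- apply(coords, c(2, 3), mean)
  dev2 <- sweep(coords, c(2, 3), mu)^2
  msf <- apply(dev2, 2L, mean) * 3   # mean over frames & axes, x3 = |dr|^2
  data.frame(residue = traj$residue[keep], rmsf = sqrt(msf))
}

#' Rhodopsin helix I-VIII residue window
#'
#' The residue range E33(1.28) to C322(8.59) used for flexibility analyses,
#' excluding the poorly modelled termini.
#'
#' @return Integer vector `33:322`.
#' @export
rhodopsin_helix_window <- function() 33:322

#' Pressure-difference of RMSF
#'
#' `delta_RMSF = RMSF(high) - RMSF(low)` per residue and averaged over the
#' selection.
#'
#' @param high,low Trajectories for the two pressure conditions (shared
#'   residue selection).
#' @param residues Residue selection (default as in [rmsf_profile()]).
#' @param superpose Superpose frames first.
#' @return List: `per_residue` (data frame `residue`, `rmsf_high`,
#'   `rmsf_low`, `delta`), `mean_delta`, `sd_delta` (SD over residues).
#' @export
delta_rmsf <- function(high, low, residues = NULL, superpose = TRUE) {
  rh <- rmsf_profile(high, residues, superpose)
  rl <- rmsf_profile(low, residues, superpose)
  if (!identical(rh$residue, rl$residue)) {
    stop("residue selections differ between conditions")
  }
  d <- rh$rmsf - rl$rmsf
  list(per_residue = data.frame(residue = rh$residue,
                                rmsf_high = rh$rmsf, rmsf_low = rl$rmsf,
                                delta = d),
       mean_delta = mean(d), sd_delta = stats::sd(d))
}

# ---- quasiharmonic entropy -------------------------------------------

#' Quasiharmonic vibrational entropy from Calpha fluctuations
#'
#' Superposes the trajectory, forms the mass-weighted covariance matrix of
#' the Cartesian fluctuations, and treats its eigenmodes as harmonic
#' oscillators at `omega_i = sqrt(kB T / lambda_i)`. The per-mode entropy
#' is the quantum harmonic-oscillator expression by default (classical
#' available via `classical = TRUE`). The `drop_modes` smallest-eigenvalue
#' modes (default 6, the rigid-body remnants) and any mode below
#' `eig_floor` are excluded.
#'
#' @param traj A [coordinate_trajectory()].
#' @param constants A [thermo_constants()] (temperature source).
#' @param superpose Remove rigid-body motion by superposition first.
#' @param drop_modes Number of smallest-eigenvalue modes to drop.
#' @param eig_floor Eigenvalue floor (amu Angstrom^2); smaller modes are
#'   dropped with a warning.
#' @param classical Use the classical oscillator entropy instead.
#' @return List of class `entropy_estimate`: `S` (kcal mol^-1 K^-1),
#'   `frequencies` (rad/s, retained modes), `eigenvalues` (amu Angstrom^2),
#'   `n_modes`.
#' @export
quasiharmonic_entropy <- function(traj, constants = thermo_constants(),
                                  superpose = TRUE, drop_modes = 6,
                                  eig_floor = 1e-8, classical = FALSE) {
  traj <- .as_trajectory(traj)
  coords <- traj$coords
  nf <- dim(coords)[1]; n <- dim(coords)[2]
  if (nf < 3 * n) {
    warning("fewer frames (", nf, ") than 3 x atoms (", 3 * n,
            "); covariance will be rank-deficient")
  }
  if (superpose && n >= 3) coords <- .superpose(coords)
  X <- matrix(coords, nf, 3 * n)   # frames x (x1..xn, y1..yn, z1..zn)
  X <- sweep(X, 2L, colMeans(X))
  C <- crossprod(X) / nf           # population covariance, A^2
  sm <- sqrt(rep(traj$masses, 3))
  C <- C * (sm %o% sm)             # mass-weighted, amu A^2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  if (drop_modes > 0) ev <- ev[seq_len(max(length(ev) - drop_modes, 0))]
  low <- ev < eig_floor
  if (any(low)) {
    if (any(ev > eig_floor)) {
      warning(sum(low), " near-singular covariance mode(s) below the ",
              "eigenvalue floor dropped")
    }
    ev <- ev[!low]
  }
  temp <- constants$temperature
  if (!length(ev)) {
    return(structure(list(S = 0, frequencies = numeric(0),
                          eigenvalues = numeric(0), n_modes = 0L),
                     class = "entropy_estimate"))
  }
  lambda_si <- ev * .AMU * 1e-20                  # kg m^2
  omega <- sqrt(.KB_J * temp / lambda_si)         # rad/s
  s_modes <- if (classical) {
    alpha <- .HBAR * omega / (.KB_J * temp)
    .KB_KCAL * (1 - log(alpha))
  } else {
    .qho_entropy(omega, temp)
  }
  structure(list(S = sum(s_modes), frequencies = omega, eigenvalues = ev,
                 n_modes = length(ev)),
            class = "entropy_estimate")
}

#' Entropic free-energy term between two pressure conditions
#'
#' `-T * (S(high) - S(low))` in kcal/mol.
#'
#' @param high,low Trajectories for the two conditions.
#' @param constants A [thermo_constants()].
#' @param ... Passed to [quasiharmonic_entropy()].
#' @return List: `minus_T_delta_S` (kcal/mol), `S_high`, `S_low`
#'   (kcal mol^-1 K^-1).
#' @export
entropy_shift <- function(high, low, constants = thermo_constants(), ...) {
  sh <- quasiharmonic_entropy(high, constants, ...)
  sl <- quasiharmonic_entropy(low, constants, ...)
  list(minus_T_delta_S = -constants$temperature * (sh$S - sl$S),
       S_high = sh$S, S_low = sl$S)
}

# ---- conformational energy -------------------------------------------

#' Default conformational-energy term names
#'
#' The bonded terms (bond stretching, Urey-Bradley, proper/improper
#' dihedral, CMAP dihedral) plus the intramolecular nonbonded terms
#' (short-range and 1-4 Coulomb and Lennard-Jones).
#'
#' @return Character vector of column names.
#' @export
energy_terms_default <- function() {
  c("bond", "urey_bradley", "proper_dihedral", "improper_dihedral",
    "cmap", "lj_sr", "coulomb_sr", "lj_14", "coulomb_14")
}

#' Mean conformational energy of a condition
#'
#' Sums the configured energy-term columns per frame and averages over the
#' analysis window, with a block-SD uncertainty.
#'
#' @param series An [ensemble_series()] carrying the term columns
#'   (kcal/mol).
#' @param terms Term column names (default [energy_terms_default()]).
#' @param constants A [thermo_constants()].
#' @return List: `value` (kcal/mol), `block_sd`, `blocks`.
#' @export
conformational_energy <- function(series, terms = energy_terms_default(),
                                  constants = thermo_constants()) {
  stopifnot(inherits(series, "ensemble_series"))
  missing_terms <- setdiff(terms, names(series))
  if (length(missing_terms)) {
    stop("missing energy term column(s): ",
         paste(missing_terms, collapse = ", "))
  }
  idx <- .window_idx(nrow(series), constants)
  e <- rowSums(as.data.frame(series)[terms])
  blocks <- vapply(.blocks(idx, constants$n_blocks),
                   function(b) mean(e[b]), numeric(1))
  list(value = mean(e[idx]), block_sd = stats::sd(blocks), blocks = blocks)
}

# ---- solvation and free-energy assembly ------------------------------

#' Nonpolar solvation free energy
#'
#' `mu_nonpolar ~ p*V + gamma*A`, with pressure in MPa, volume in
#' Angstrom^3, and area in Angstrom^2, returned in kcal/mol. The van der
#' Waals term is omitted (its contribution is negligible at these
#' pressures).
#'
#' @param pressure_MPa System pressure, MPa (>= 0).
#' @param volume_A3 Solute volume, Angstrom^3 (>= 0).
#' @param area_A2 Solvent-accessible surface area, Angstrom^2 (>= 0).
#' @param constants A [thermo_constants()] (surface tension source).
#' @return Nonpolar solvation free energy, kcal/mol.
#' @export
nonpolar_solvation <- function(pressure_MPa, volume_A3, area_A2,
                               constants = thermo_constants()) {
  stopifnot(all(pressure_MPa >= 0), all(volume_A3 >= 0), all(area_A2 >= 0))
  pv <- pressure_MPa * 1e6 * volume_A3 * .PA_A3_KCALMOL
  pv + constants$surface_tension * area_A2
}

#' Pressure free-energy decomposition
#'
#' Assembles the free-energy cost of pressurisation,
#' `dG_p = dE_conf - T*dS + (mu_high - mu_low)`, from per-condition
#' components. Each component may carry an uncertainty; uncertainties are
#' propagated in quadrature. The assembly identity
#' `dG_p = dE_conf + (-T dS) + ddmu` holds exactly by construction.
#'
#' @param low,high Per-condition component lists with elements `E_conf`,
#'   `S` (entropy, kcal mol^-1 K^-1), `mu` (solvation free energy,
#'   kcal/mol), and optional `E_conf_sd`, `S_sd`, `mu_sd`.
#' @param constants A [thermo_constants()] (temperature for `-T dS`).
#' @return Object of class `free_energy_decomposition`: `delta_E_conf`,
#'   `minus_T_delta_S`, `delta_delta_mu`, `delta_G_p`, and `_sd` fields.
#' @export
free_energy_shift <- function(low, high, constants = thermo_constants()) {
  need <- c("E_conf", "S", "mu")
  for (cond in list(low = low, high = high)) {
    miss <- setdiff(need, names(cond))
    if (length(miss)) {
      stop("missing component(s): ", paste(miss, collapse = ", "))
    }
  }
  g <- function(x, f, d = 0) if (is.null(x[[f]])) d else x[[f]]
  temp <- constants$temperature
  dE <- high$E_conf - low$E_conf
  mTdS <- -temp * (high$S - low$S)
  ddmu <- high$mu - low$mu
  dE_sd <- sqrt(g(high, "E_conf_sd")^2 + g(low, "E_conf_sd")^2)
  mTdS_sd <- temp * sqrt(g(high, "S_sd")^2 + g(low, "S_sd")^2)
  ddmu_sd <- sqrt(g(high, "mu_sd")^2 + g(low, "mu_sd")^2)
  free_energy_decomposition(dE, mTdS, ddmu,
                            sd = c(dE_sd, mTdS_sd, ddmu_sd))
}

#' Assemble a free-energy decomposition from component shifts
#'
#' @param delta_E_conf Conformational energy shift, kcal/mol.
#' @param minus_T_delta_S Entropic term `-T dS`, kcal/mol.
#' @param delta_delta_mu Solvation shift `mu_high - mu_low`, kcal/mol.
#' @param sd Optional numeric length-3 uncertainties of the components.
#' @return Object of class `free_energy_decomposition` with `delta_G_p`
#'   the exact sum of the three components and `delta_G_p_sd` their
#'   quadrature sum.
#' @export
free_energy_decomposition <- function(delta_E_conf, minus_T_delta_S,
                                      delta_delta_mu, sd = c(0, 0, 0)) {
  stopifnot(length(sd) == 3)
  structure(list(delta_E_conf = delta_E_conf,
                 minus_T_delta_S = minus_T_delta_S,
                 delta_delta_mu = delta_delta_mu,
                 delta_G_p = delta_E_conf + minus_T_delta_S + delta_delta_mu,
                 delta_E_conf_sd = sd[1], minus_T_delta_S_sd = sd[2],
                 delta_delta_mu_sd = sd[3],
                 delta_G_p_sd = sqrt(sum(sd^2))),
            class = "free_energy_decomposition")
}

#' @export
print.free_energy_decomposition <- function(x, ...) {
  cat(sprintf(
    "dG_p = %.3f +/- %.3f kcal/mol\n  dE_conf %.3f  -TdS %.3f  ddmu %.3f\n",
    x$delta_G_p, x$delta_G_p_sd, x$delta_E_conf, x$minus_T_delta_S,
    x$delta_delta_mu))
  invisible(x)
}

# ---- solvent-accessible surface area ---------------------------------

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic Shrake-Rupley SASA with a fixed golden-spiral point set.
#' Provided for when no precomputed area column is available.
#'
#' @param coords `natoms x 3` coordinate matrix (Angstrom).
#' @param radii Per-atom radii (Angstrom); default 1.7 (carbon).
#' @param probe Probe radius (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return List: `total` (Angstrom^2), `per_atom`.
#' @export
sasa_shrake_rupley <- function(coords, radii = rep(1.7, nrow(coords)),
                               probe = 1.4, n_points = 960) {
  stopifnot(is.matrix(coords), ncol(coords) == 3,
            length(radii) == nrow(coords))
  n <- nrow(coords)
  # golden-spiral unit sphere points (fixed, no randomness)
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sphere <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  r_eff <- radii + probe
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * r_eff[i], 2L, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- colSums((t(pts) - coords[j, ])^2)
      acc <- acc & d2 > r_eff[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * r_eff[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}
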