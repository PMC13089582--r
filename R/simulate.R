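#' Simulate a codon alignment under the property-partitioned model
#'
#' Evolves codon sites along a tagged tree under the radical/conservative
#' rate matrix. Sites are assigned to classes by the mixture proportions (a
#' single class by default); each branch uses the transition matrix of its
#' tag, so foreground branches can carry their own radical rate. Root states
#' are drawn from the stationary frequencies. The true site classes and all
#' internal-node (ancestral) codon states are returned for recovery tests.
#'
#' @param tree A [tagged_tree()].
#' @param partition A [build_partition()] result.
#' @param nsites Number of codon sites.
#' @param kappa,omega Model parameters (scalars).
#' @param gamma Radical rate: scalar or `c(fg=, bg=)`.
#' @param mixture Optional data frame `omega`, `gamma`, `prop` (site
#'   classes); overrides `omega`/`gamma`.
#' @param freqs Codon frequencies (default uniform over the 61 sense
#'   codons).
#' @param seed Mandatory integer seed.
#' @return List: `alignment` (`codon_alignment`), `site_class` (integer per
#'   site, 1-based row of `mixture`, or all 1), `ancestral` (matrix of codon
#'   strings, internal nodes x sites, rownames the ape node numbers),
#'   `params` (the generating values).
#' @export
simulate_codon_alignment <- function(tree, partition, nsites, kappa = 2,
                                     omega = 0.5, gamma = 0.5,
                                     mixture = NULL,
                                     freqs = uniform_codon_frequencies(),
                                     seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(tree, "tagged_tree"), nsites >= 1)
  pi <- .check_freqs(freqs)
  codons <- names(pi)
  set.seed(seed)

  if (is.null(mixture)) {
    g <- if (length(gamma) == 1L) c(fg = unname(gamma), bg = unname(gamma))
         else gamma
    mixture <- data.frame(omega = omega, gamma = NA, prop = 1)
    gamma_tab <- list(g)
  } else {
    if (abs(sum(mixture$prop) - 1) > 1e-8) {
      stop("mixture proportions must sum to 1")
    }
    gamma_tab <- lapply(mixture$gamma, function(g) c(fg = g, bg = g))
  }
  nclass <- nrow(mixture)
  site_class <- sample.int(nclass, nsites, replace = TRUE,
                           prob = mixture$prop)

  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  # preorder: parents before children
  pre <- ape::reorder.phylo(phy, "cladewise")
  okey <- paste(phy$edge[, 1], phy$edge[, 2])
  perm <- match(paste(pre$edge[, 1], pre$edge[, 2]), okey)
  tags <- tree$tags[perm]

  # transition matrices per (class, tag, edge length): decompose once per
  # class x tag, exponentiate per edge
  decomp <- list()
  for (c in seq_len(nclass)) {
    for (tg in unique(tags)) {
      Q <- build_rate_matrix(kappa, mixture$omega[c], gamma_tab[[c]][[tg]],
                             partition, pi)
      decomp[[paste(c, tg)]] <- .decompose_q(Q, pi)
    }
  }

  states <- matrix(NA_integer_, ntip + nnode, nsites)
  root <- ntip + 1L
  states[root, ] <- sample.int(length(pi), nsites, replace = TRUE, prob = pi)
  for (e in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[e, 1]; child <- pre$edge[e, 2]
    t_e <- pre$edge.length[e]
    for (c in unique(site_class)) {
      sites_c <- which(site_class == c)
      P <- .pmat_from_decomp(decomp[[paste(c, tags[e])]], t_e)
      ps <- states[parent, sites_c]
      for (s in unique(ps)) {
        at <- sites_c[ps == s]
        states[child, at] <- sample.int(length(pi), length(at),
                                        replace = TRUE, prob = P[s, ])
      }
    }
  }

  tip_mat <- matrix(codons[states[seq_len(ntip), , drop = FALSE]],
                    ntip, nsites, dimnames = list(phy$tip.label, NULL))
  anc <- matrix(codons[states[root:(ntip + nnode), , drop = FALSE]],
                nnode, nsites,
                dimnames = list(as.character(root:(ntip + nnode)), NULL))
  aln <- structure(tip_mat, class = "codon_alignment")
  list(alignment = aln, site_class = site_class, ancestral = anc,
       params = list(kappa = kappa, mixture = mixture,
                     gamma = gamma_tab, freqs = pi, seed = seed))
}

#' Simulate a per-frame volume series with known compressibility
#'
#' Draws i.i.d. Gaussian volumes whose variance is set from the target
#' isothermal compressibility, `sigma^2 = kappa_T * kB * T * mu_V`, so the
#' volume-fluctuation estimator recovers `kappa_T` up to sampling error.
#'
#' @param kappa_T Target isothermal compressibility, GPa^-1 (>= 0).
#' @param mean_volume Mean volume, Angstrom^3.
#' @param temperature Kelvin.
#' @param n_frames Number of frames.
#' @param pressure Nominal pressure label, MPa (stored in the series).
#' @param seed Mandatory integer seed.
#' @return Data frame with columns `time`, `volume`, `temperature`,
#'   `pressure` (an `ensemble_series`).
#' @export
simulate_volume_series <- function(kappa_T, mean_volume, temperature = 300,
                                   n_frames = 1e4, pressure = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(kappa_T >= 0, mean_volume > 0, temperature > 0, n_frames >= 1)
  kBT_paa3 <- .KB_J * temperature / 1e-30      # Pa * A^3
  sigma2 <- (kappa_T * 1e-9) * kBT_paa3 * mean_volume   # A^6
  set.seed(seed)
  v <- mean_volume + stats::rnorm(n_frames, 0, sqrt(sigma2))
  structure(data.frame(time = seq_len(n_frames),
                       volume = v,
                       temperature = temperature,
                       pressure = pressure),
            class = c("ensemble_series", "data.frame"))
}

#' Simulate a harmonic Calpha trajectory with known RMSF and entropy
#'
#' Atoms fluctuate independently about fixed centres, Gaussian per axis with
#' variance `kB*T / k_atom` (a 3-D harmonic well per atom). The analytic
#' per-atom RMSF is `sqrt(3 kB T / k_atom)` and the analytic mode spectrum
#' is three modes per atom at angular frequency `sqrt(k/m)`, from which the
#' quantum harmonic-oscillator entropy is returned.
#'
#' @param force_constants Per-atom force constants, kcal mol^-1 A^-2 (> 0).
#' @param masses Per-atom masses, amu (default 12.011, a carbon).
#' @param temperature Kelvin.
#' @param n_frames Number of frames.
#' @param centers Optional natooms x 3 matrix of well centres; default a
#'   stretched helix-like arrangement.
#' @param seed Mandatory integer seed.
#' @return List: `coords` (frames x atoms x 3 array, Angstrom), `masses`,
#'   `residue` (1..natoms), `analytic_rmsf` (per atom, Angstrom),
#'   `analytic_entropy` (kcal mol^-1 K^-1), `omega` (mode angular
#'   frequencies, rad/s).
#' @export
simulate_harmonic_trajectory <- function(force_constants,
                                         masses = rep(12.011,
                                                      length(force_constants)),
                                         temperature = 300, n_frames = 2000,
                                         centers = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(force_constants > 0), all(masses > 0), temperature > 0)
  n <- length(force_constants)
  if (is.null(centers)) {
    th <- seq_len(n)
    centers <- cbind(5 * cos(th), 5 * sin(th), 1.5 * th)
  }
  stopifnot(nrow(centers) == n, ncol(centers) == 3)
  var_axis <- .KB_KCAL * temperature / force_constants   # A^2 per axis
  set.seed(seed)
  coords <- array(stats::rnorm(n_frames * n * 3), c(n_frames, n, 3))
  for (a in seq_len(n)) {
    coords[, a, ] <- coords[, a, ] * sqrt(var_axis[a])
    coords[, a, ] <- sweep(coords[, a, ], 2L, centers[a, ], "+")
  }
  # analytic spectrum: 3 modes per atom, omega = sqrt(k/m) in SI
  k_si <- force_constants * .KCALMOL_J / 1e-20   # J m^-2
  omega <- rep(sqrt(k_si / (masses * .AMU)), each = 3)
  S <- sum(.qho_entropy(omega, temperature))
  list(coords = coords, masses = masses, residue = seq_len(n),
       analytic_rmsf = sqrt(3 * var_axis), analytic_entropy = S,
       omega = omega)
}

# quantum harmonic-oscillator entropy per mode, kcal mol^-1 K^-1
.qho_entropy <- function(omega, temperature) {
  alpha <- .HBAR * omega / (.KB_J * temperature)
  s <- alpha / (exp(alpha) - 1) - log1p(-exp(-alpha))
  s[!is.finite(s) | alpha <= 0] <- 0
  .KB_KCAL * s
}
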