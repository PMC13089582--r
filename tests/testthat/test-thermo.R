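test_that("compressibility estimator: degenerate, oracle, and scaling
           behaviour", {
  const <- thermo_constants(window_fraction = 1)
  flat <- ensemble_series(data.frame(time = 1:100, volume = 5e5,
                                     temperature = 300))
  expect_equal(isothermal_compressibility(flat, const)$value, 0)
  # Gaussian oracle: i.i.d. volumes of known variance
  vs <- simulate_volume_series(kappa_T = 0.45, mean_volume = 5e5,
                               temperature = 300, n_frames = 1e5, seed = 3)
  k <- isothermal_compressibility(vs, const)
  expect_equal(k$value, 0.45, tolerance = 0.03)
  expect_gt(k$block_sd, 0)
  expect_equal(length(k$blocks), const$n_blocks)
  # doubling the volume scale doubles kappa_T (Var x4, <V> x2)
  vs2 <- vs; vs2$volume <- vs$volume * 2
  k2 <- isothermal_compressibility(ensemble_series(vs2), const)
  expect_equal(k2$value, 2 * k$value, tolerance = 1e-10)
  # paired conditions reproduce a planted difference
  hi <- simulate_volume_series(0.55, 5e5, 300, 5e4, pressure = 30, seed = 4)
  lo <- simulate_volume_series(0.45, 5e5, 300, 5e4, pressure = 0.1, seed = 5)
  dk <- delta_compressibility(hi, lo, const)
  expect_lt(abs(dk$delta - 0.10), 0.02)
  expect_error(isothermal_compressibility(
    ensemble_series(data.frame(time = 1, volume = 1)), const), "2 frames")
})

test_that("RMSF: static limit, Gaussian oracle, and rigid-motion
           invariance", {
  static <- coordinate_trajectory(array(rep(1:30, each = 50), c(50, 10, 3)))
  r0 <- rmsf_profile(static, superpose = FALSE)
  expect_equal(r0$rmsf, rep(0, 10), tolerance = 1e-12)
  # sigma * sqrt(3) oracle, no superposition (no rigid motion simulated)
  kT <- 300 * 1.987204259e-3
  kconst <- 2.5
  sim <- simulate_harmonic_trajectory(rep(kconst, 25), n_frames = 6000,
                                      seed = 6)
  traj <- coordinate_trajectory(sim$coords)
  r <- rmsf_profile(traj, superpose = FALSE)
  expect_equal(mean(r$rmsf), sqrt(3 * kT / kconst), tolerance = 0.02)
  expect_equal(mean(r$rmsf), mean(sim$analytic_rmsf), tolerance = 0.02)
  # a uniform rotation + translation of every frame changes nothing
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- sim$coords
  for (f in seq_len(dim(moved)[1])) {
    moved[f, , ] <- sim$coords[f, , ] %*% R + 5
  }
  rm <- rmsf_profile(coordinate_trajectory(moved), superpose = FALSE)
  expect_equal(rm$rmsf, r$rmsf, tolerance = 1e-9)
  # per-frame rigid-body noise is removed by superposition
  jostled <- sim$coords
  set.seed(7)
  for (f in seq_len(dim(jostled)[1])) {
    a <- rnorm(1, 0, 0.3)
    Rf <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    jostled[f, , ] <- sweep(sim$coords[f, , ] %*% Rf, 2, rnorm(3, 0, 2), "+")
  }
  rj <- rmsf_profile(coordinate_trajectory(jostled), superpose = TRUE)
  rs <- rmsf_profile(traj, superpose = TRUE)
  expect_equal(mean(rj$rmsf), mean(rs$rmsf), tolerance = 0.02)
  expect_error(rmsf_profile(traj, residues = 999), "empty")
})

test_that("the default flexibility window is the rhodopsin helix range", {
  expect_identical(rhodopsin_helix_window(), 33:322)
  # a trajectory numbered like rhodopsin is restricted to the window
  sim <- simulate_harmonic_trajectory(rep(2, 340), n_frames = 5, seed = 8)
  traj <- coordinate_trajectory(sim$coords, residue = 1:340)
  r <- rmsf_profile(traj, superpose = FALSE)
  expect_equal(range(r$residue), c(33, 322))
})

test_that("delta RMSF contrasts two conditions over a shared selection", {
  lo <- simulate_harmonic_trajectory(rep(4, 20), n_frames = 3000, seed = 9)
  hi <- simulate_harmonic_trajectory(rep(2, 20), n_frames = 3000, seed = 10)
  d <- delta_rmsf(coordinate_trajectory(hi$coords),
                  coordinate_trajectory(lo$coords), superpose = FALSE)
  kT <- 300 * 1.987204259e-3
  expect_equal(d$mean_delta, sqrt(3 * kT / 2) - sqrt(3 * kT / 4),
               tolerance = 0.03)
  expect_equal(nrow(d$per_residue), 20)
})

test_that("quasiharmonic entropy: frozen limit, analytic oracle,
           monotonicity, and stability", {
  const <- thermo_constants()
  frozen <- coordinate_trajectory(array(rep(1:30, each = 40), c(40, 10, 3)))
  s0 <- quasiharmonic_entropy(frozen, const, superpose = FALSE,
                              drop_modes = 0)
  expect_equal(s0$S, 0)
  # single 3-D oscillator vs the analytic quantum entropy
  sim <- simulate_harmonic_trajectory(5, masses = 12.011,
                                      n_frames = 20000, seed = 11)
  traj <- coordinate_trajectory(sim$coords)
  s <- quasiharmonic_entropy(traj, const, superpose = FALSE, drop_modes = 0)
  expect_equal(s$S, sim$analytic_entropy, tolerance = 0.02)
  # inflating every fluctuation raises the entropy
  bigger <- coordinate_trajectory(sim$coords * 1.5)
  s_big <- quasiharmonic_entropy(bigger, const, superpose = FALSE,
                                 drop_modes = 0)
  expect_gt(s_big$S, s$S)
  # rigid-motion invariance (uniform transform of all frames)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  sim2 <- simulate_harmonic_trajectory(rep(3, 8), n_frames = 8000,
                                       seed = 12)
  moved <- sim2$coords
  for (f in seq_len(dim(moved)[1])) {
    moved[f, , ] <- sim2$coords[f, , ] %*% R - 3
  }
  sa <- quasiharmonic_entropy(coordinate_trajectory(sim2$coords), const)
  sb <- quasiharmonic_entropy(coordinate_trajectory(moved), const)
  expect_equal(sa$S, sb$S, tolerance = 1e-6)
  # two halves of a long trajectory agree
  half1 <- coordinate_trajectory(sim2$coords[1:4000, , ])
  half2 <- coordinate_trajectory(sim2$coords[4001:8000, , ])
  s1 <- quasiharmonic_entropy(half1, const)
  s2 <- quasiharmonic_entropy(half2, const)
  expect_equal(s1$S, s2$S, tolerance = 0.03)
  # severe undersampling is flagged
  w <- capture_warnings(
    quasiharmonic_entropy(coordinate_trajectory(sim2$coords[1:10, , ]),
                          const))
  expect_true(any(grepl("rank-deficient", w)))
})

test_that("entropy shift reports -T dS between conditions with the right
           sign", {
  # softer wells at high pressure -> entropy rises -> -T dS negative
  lo <- simulate_harmonic_trajectory(rep(6, 10), n_frames = 6000, seed = 13)
  hi <- simulate_harmonic_trajectory(rep(2, 10), n_frames = 6000, seed = 14)
  es <- entropy_shift(coordinate_trajectory(hi$coords),
                      coordinate_trajectory(lo$coords),
                      superpose = FALSE, drop_modes = 0)
  expect_gt(es$S_high, es$S_low)
  expect_lt(es$minus_T_delta_S, 0)
  expect_equal(es$minus_T_delta_S, -300 * (es$S_high - es$S_low),
               tolerance = 1e-12)
})

test_that("conformational energy sums the configured term columns over the
           window", {
  const <- thermo_constants(window_fraction = 1, n_blocks = 1)
  terms <- energy_terms_default()
  expect_setequal(terms, c("bond", "urey_bradley", "proper_dihedral",
                           "improper_dihedral", "cmap", "lj_sr",
                           "coulomb_sr", "lj_14", "coulomb_14"))
  df <- data.frame(time = 1:3, volume = 1)
  for (tm in terms) df[[tm]] <- 0
  zero <- conformational_energy(ensemble_series(df), terms, const)
  expect_equal(zero$value, 0)
  # 3-frame hand fixture over two terms
  df2 <- data.frame(time = 1:3, volume = 1,
                    bond = c(10, 12, 14), lj_sr = c(-5, -6, -7))
  e <- conformational_energy(ensemble_series(df2), c("bond", "lj_sr"),
                             const)
  expect_equal(e$value, mean(c(5, 6, 7)))
  expect_error(conformational_energy(ensemble_series(df2),
                                     c("bond", "cmap"), const),
               "cmap")
})

test_that("nonpolar solvation converts pV + gamma A into kcal/mol", {
  const <- thermo_constants()
  expect_equal(nonpolar_solvation(0, 123, 0, const), 0)
  expect_equal(nonpolar_solvation(1, 1, 0, const), 1.439e-4,
               tolerance = 1e-3)
  expect_equal(const$surface_tension, 0.1032)
  expect_equal(nonpolar_solvation(0, 0, 10, const), 1.032,
               tolerance = 1e-12)
  expect_equal(nonpolar_solvation(30, 5e5, 1.5e4,
                                  const),
               30e6 * 5e5 * 1e-30 * 6.02214076e23 / 4184 + 0.1032 * 1.5e4,
               tolerance = 1e-9)
  expect_error(nonpolar_solvation(-1, 1, 1, const))
})

test_that("free-energy assembly identity holds exactly, including the
           reported decompositions", {
  zero <- free_energy_decomposition(0, 0, 0)
  expect_equal(zero$delta_G_p, 0)
  # the four reported component triplets are additive
  cases <- list(c(-56, 14, 285, 243), c(98, -26, 274, 346),
                c(2, -1, 251, 252), c(-66, 17, 257, 208))
  for (cs in cases) {
    fe <- free_energy_decomposition(cs[1], cs[2], cs[3])
    expect_identical(fe$delta_G_p, cs[4])
  }
  # assembly from per-condition components + quadrature errors
  lo <- list(E_conf = 100, S = 0.5, mu = 20, E_conf_sd = 3, S_sd = 0.001,
             mu_sd = 2)
  hi <- list(E_conf = 44, S = 0.5 - 14 / 300, mu = 305, E_conf_sd = 4,
             S_sd = 0.002, mu_sd = 1)
  fe <- free_energy_shift(lo, hi, thermo_constants(temperature = 300))
  expect_equal(fe$delta_E_conf, -56)
  expect_equal(fe$minus_T_delta_S, 14, tolerance = 1e-9)
  expect_equal(fe$delta_delta_mu, 285)
  expect_equal(fe$delta_G_p,
               fe$delta_E_conf + fe$minus_T_delta_S + fe$delta_delta_mu)
  expect_equal(fe$delta_E_conf_sd, 5)
  expect_equal(fe$delta_G_p_sd,
               sqrt(fe$delta_E_conf_sd^2 + fe$minus_T_delta_S_sd^2 +
                      fe$delta_delta_mu_sd^2))
  expect_error(free_energy_shift(list(E_conf = 1, S = 1), hi),
               "missing component")
})

test_that("Shrake-Rupley SASA: single atom, additivity, and burial", {
  one <- sasa_shrake_rupley(matrix(0, 1, 3), radii = 1.7)
  expect_equal(one$total, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  two_far <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(two_far$total, 2 * one$total, tolerance = 1e-9)
  two_close <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_lt(two_close$total, two_far$total)
  # symmetric to within the angular resolution of the fixed point set
  expect_equal(two_close$per_atom[1], two_close$per_atom[2],
               tolerance = 5e-3)
})
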