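# Trajectory-engine conservation laws and adiabatic-structure oracles.

test_that("adiabatic structure matches the dimer closed form and Hellmann-Feynman", {
  m <- dimer(30)
  b <- dimer_bath(m, 10)
  set.seed(3)
  iu <- excitondyn:::.internal_units(m, b)
  q <- matrix(rnorm(20, 0, sqrt(iu$kT) / rep(iu$omega, 2)), 10, 2)
  ad <- adiabatic_structure(m, b, q)
  # analytic 2x2 eigenvalues
  w <- iu$eps + colSums(iu$coupling * q)
  h <- mean(w); d <- (w[1] - w[2]) / 2
  r <- sqrt(d^2 + iu$Jc[1, 2]^2)
  expect_equal(ad$V_el, c(h - r, h + r), tolerance = 1e-12)
  expect_equal(crossprod(ad$U), diag(2), tolerance = 1e-12)
  # Hellmann-Feynman: central-difference gradient of the active surface
  eps_fd <- 1e-6
  for (pick in list(c(3, 1), c(7, 2))) {
    qp <- q; qm <- q
    qp[pick[1], pick[2]] <- qp[pick[1], pick[2]] + eps_fd
    qm[pick[1], pick[2]] <- qm[pick[1], pick[2]] - eps_fd
    Vp <- adiabatic_structure(m, b, qp)$V[1]
    Vm <- adiabatic_structure(m, b, qm)$V[1]
    expect_equal(ad$grad_active[pick[1], pick[2]], (Vp - Vm) / (2 * eps_fd),
                 tolerance = 1e-5)
  }
  # q = 0, J = 0: adiabats are the bare sites
  m0 <- frenkel_model(c(100, 0), matrix(0, 2, 2), m$sd, 300)
  ad0 <- adiabatic_structure(m0, b, matrix(0, 10, 2))
  expect_equal(sort(ad0$V_el), sort(iu$eps), tolerance = 1e-10)
  # ascending order puts site 2 (energy 0) first
  expect_equal(abs(ad0$U), matrix(c(0, 1, 1, 0), 2), tolerance = 1e-12)
})

test_that("hop update conserves energy or reverses only the parallel component", {
  set.seed(4)
  p <- rnorm(50); v <- rnorm(50)
  vhat <- v / sqrt(sum(v^2))
  # downhill: always accepted, kinetic energy increases by |gap| exactly
  h1 <- mash_hop_update(p, v, gap = -12.5)
  expect_true(h1$accepted)
  expect_equal(sum(h1$p^2) / 2 - sum(p^2) / 2, 12.5, tolerance = 1e-10)
  # uphill with enough energy: exact conservation
  gap_ok <- 0.5 * sum(p * vhat)^2 * 0.9
  h2 <- mash_hop_update(p, v, gap_ok)
  expect_true(h2$accepted)
  expect_equal(sum(h2$p^2) / 2 + gap_ok, sum(p^2) / 2, tolerance = 1e-10)
  # frustrated: parallel component negated, perpendicular untouched
  gap_big <- 0.5 * sum(p * vhat)^2 * 1.1
  h3 <- mash_hop_update(p, v, gap_big)
  expect_false(h3$accepted)
  expect_equal(sum(h3$p * vhat), -sum(p * vhat), tolerance = 1e-12)
  expect_equal(h3$p - sum(h3$p * vhat) * vhat, p - sum(p * vhat) * vhat,
               tolerance = 1e-12)
  expect_equal(sum(h3$p^2), sum(p^2), tolerance = 1e-12)
})

test_that("electronic norm is conserved to machine precision over 10^4 steps", {
  m <- dimer(20)
  b <- dimer_bath(m, 100)
  iu <- excitondyn:::.internal_units(m, b)
  set.seed(6)
  q0 <- rnorm(200, 0, sqrt(iu$kT) / rep(iu$omega, 2))
  p0 <- rnorm(200, 0, sqrt(iu$kT))
  r <- step_trajectory(m, b, q0, p0, c(0.8, 0.6i), n_steps = 10000, dt = 5e-4)
  expect_lt(r$max_norm_err, 1e-10)
  expect_equal(sum(Mod(r$c)^2), 1, tolerance = 1e-10)
})

test_that("phases-only limit keeps populations frozen", {
  # J = 0 and a zero spectral density: site populations are constants
  sdz <- tabulated_spectral_density(c(1, 10, 100), c(0, 0, 0))
  m0 <- frenkel_model(c(100, 0), matrix(0, 2, 2), sdz, 300)
  b <- discretize_bath(debye_spectral_density(20, 53), 50)
  b$coupling <- b$coupling * 0
  set.seed(8)
  q0 <- rnorm(100); p0 <- rnorm(100)
  c0 <- c(sqrt(0.7), sqrt(0.3) * 1i)
  r <- step_trajectory(m0, b, q0, p0, c0, n_steps = 2000, dt = 5e-4)
  expect_equal(as.numeric(Mod(r$c)^2), c(0.7, 0.3), tolerance = 1e-12)
  expect_equal(r$n_hops, 0)
})

test_that("energy drift between hops is small and hops conserve exactly", {
  m <- dimer(20)
  b <- dimer_bath(m, 100)
  iu <- excitondyn:::.internal_units(m, b)
  set.seed(10)
  q0 <- rnorm(200, 0, sqrt(iu$kT) / rep(iu$omega, 2))
  p0 <- rnorm(200, 0, sqrt(iu$kT))
  # hop-free control: J = 0 and a site-energy gap far beyond the bath
  # fluctuations, so the trajectory is a displaced harmonic oscillator on a
  # single surface (diabatic crossings cannot occur)
  m0 <- frenkel_model(c(1e5, 0), matrix(0, 2, 2), m$sd, 300)
  r0 <- step_trajectory(m0, b, q0, p0, c(1, 0), n_steps = 200000, dt = 5e-5)
  expect_equal(r0$n_hops + r0$n_frustrated, 0)
  expect_lt(abs(r0$energy - r0$energy0) / iu$kT / 10, 1e-4)   # per ps over 10 ps
  # full dynamics: accepted hops conserve energy to machine precision
  r <- step_trajectory(m, b, q0, p0, c(0.8, 0.6), n_steps = 20000, dt = 2.5e-4)
  expect_gt(r$n_hops, 0)
  expect_lt(r$max_hop_err, 1e-8)
})

test_that("ensemble estimator means are exactly normalized and reproducible", {
  m <- dimer(20)
  b <- dimer_bath(m, 50)
  tr <- run_ensemble(m, b, n_traj = 200, t_max = 0.5, dt = 5e-4, seed = 3)
  expect_equal(rowSums(tr$pop_site), rep(1, length(tr$time)), tolerance = 1e-10)
  expect_equal(rowSums(tr$pop_exc), rep(1, length(tr$time)), tolerance = 1e-10)
  tr2 <- run_ensemble(m, b, n_traj = 200, t_max = 0.5, dt = 5e-4, seed = 3)
  expect_identical(tr$pop_site, tr2$pop_site)    # byte-identical under one seed
  tr3 <- run_ensemble(m, b, n_traj = 200, t_max = 0.5, dt = 5e-4, seed = 4)
  expect_false(identical(tr$pop_site, tr3$pop_site))
})

test_that("frozen electronic world: lambda = 0 and J = 0 freezes every scheme", {
  sdz <- tabulated_spectral_density(c(1, 10, 100), c(0, 0, 0))
  m0 <- frenkel_model(c(100, 0), matrix(0, 2, 2), sdz, 300)
  b <- discretize_bath(debye_spectral_density(20, 53), 20)
  b$coupling <- b$coupling * 0
  for (sch in c("cap", "focused", "equivariant", "original")) {
    tr <- run_ensemble(m0, b, scheme = sch, n_traj = 100, t_max = 0.2,
                       dt = 5e-4, seed = 5)
    expect_equal(tr$pop_site[nrow(tr$pop_site), ], tr$pop_site[1, ],
                 tolerance = 1e-8, label = sch)
  }
})

test_that("equilibrium oracle reduces to the Boltzmann limit at lambda -> 0", {
  m <- dimer(1e-4)
  b <- dimer_bath(m, 50)
  eq <- equilibrium_populations(m, b, n_samples = 50000, seed = 2)
  w <- exciton_states(system_hamiltonian(m))
  boltz <- exp(-m$beta * w$energies); boltz <- boltz / sum(boltz)
  # N = 2: site estimator reduces to |U_{n,occ}|^2, so the oracle must equal
  # the Boltzmann-weighted exciton composition
  expected <- as.numeric(w$U^2 %*% boltz)
  expect_equal(eq$populations, expected, tolerance = 5e-3)
  expect_equal(sum(eq$populations), 1, tolerance = 1e-10)
})
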