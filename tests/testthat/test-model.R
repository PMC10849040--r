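test_that("unit constants agree with CODATA", {
  # kB/(h c) with CODATA values, in cm^-1/K; c in cm/ps
  kB_codata <- 1.380649e-23 / (6.62607015e-34 * 2.99792458e10)
  expect_equal(exciton_units$kB_cm1, kB_codata, tolerance = 1e-8)
  expect_equal(exciton_units$cm1_to_radps, 2 * pi * 0.0299792458, tolerance = 1e-12)
})

test_that("Debye spectral density has the closed form and Eq-6 normalization", {
  sd <- debye_spectral_density(100, 53)
  expect_equal(sd_eval(sd, 53), 100)                      # J(omega_c) = lambda
  expect_equal(sd_eval(sd, -10), 0)                       # J(omega < 0) = 0
  expect_equal(sd_eval(sd, 0), 0)
  lam_quad <- stats::integrate(function(w) sd_eval(sd, w) / w, 0, Inf,
                               rel.tol = 1e-10)$value / pi
  expect_equal(lam_quad, 100, tolerance = 1e-6)
  expect_equal(reorganization_energy(sd), 100)            # exact, omega_c-independent
  expect_equal(reorganization_energy(debye_spectral_density(45, 999)), 45)
  expect_error(debye_spectral_density(-1, 53), "positive")
  expect_error(debye_spectral_density(100, 0), "positive")
})

test_that("tabulated spectral density recomputes lambda from the grid", {
  w <- seq(1e-3, 2000, length.out = 2000)
  sd0 <- debye_spectral_density(100, 53)
  tab <- tabulated_spectral_density(w, sd_eval(sd0, w))
  expect_equal(reorganization_energy(tab), 100, tolerance = 0.02)
  zero <- tabulated_spectral_density(c(1, 10, 100), c(0, 0, 0))
  expect_equal(reorganization_energy(zero), 0)
  expect_equal(sd_eval(tab, 3000), 0)                     # outside grid
  expect_error(tabulated_spectral_density(1, 1), "2 points")
})

test_that("spectral density file round-trips", {
  w <- seq(1, 500, by = 1)
  sd0 <- debye_spectral_density(45, 106)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test density", paste(w, sd_eval(sd0, w))), f)
  sd <- read_spectral_density(f)
  expect_equal(sd_eval(sd, 250), sd_eval(sd0, 250), tolerance = 1e-6)
})

test_that("debye_tan discretization carries lambda exactly for any M", {
  for (M in c(1, 7, 100)) {
    b <- discretize_bath(debye_spectral_density(50, 53), M)
    expect_equal(bath_lambda(b), 50, tolerance = 1e-12)
  }
  b1 <- discretize_bath(debye_spectral_density(50, 53), 1)
  expect_equal(b1$omega, 53 * tan(pi / 4))                # = 53
  expect_true(all(discretize_bath(debye_spectral_density(10, 53), 200)$omega > 0))
})

test_that("equal_grid discretization matches its trapezoid oracle and renormalizes", {
  sd <- debye_spectral_density(45, 106)
  raw <- discretize_bath(sd, 100, "equal_grid", omega_max = 500, renormalize = FALSE)
  # independent oracle: trapezoid of J/w/pi over the truncated window
  wg <- seq(0.01, 500, length.out = 20000)
  lam_trunc <- sum(diff(wg) * (sd_eval(sd, wg) / wg)[-1]) / pi
  expect_equal(bath_lambda(raw), lam_trunc, tolerance = 0.02)
  # analytic truncation factor (2/pi) atan(omega_max/omega_c)
  expect_equal(bath_lambda(raw), 45 * 2 / pi * atan(500 / 106), tolerance = 0.01)
  ren <- suppressMessages(discretize_bath(sd, 100, "equal_grid", omega_max = 500))
  expect_equal(bath_lambda(ren), 45, tolerance = 1e-10)
  expect_error(discretize_bath(sd, 100, "equal_grid"), "omega_max")
  expect_error(discretize_bath(sd, 100, "equal_grid", omega_max = -5), "positive")
})

test_that("dimer builder reproduces the benchmark model", {
  d <- build_dimer_model(100)
  expect_equal(d$J_coupling[1, 2], 20)
  expect_equal(d$epsilon, c(100, 0))
  expect_equal(d$sd$omega_c, 53)
  H <- system_hamiltonian(d)
  expect_equal(H, t(H))
  ev <- eigen(H, symmetric = TRUE)
  expect_equal(ev$vectors %*% diag(ev$values) %*% t(ev$vectors), H, tolerance = 1e-12)
  expect_equal(diff(sort(ev$values)), sqrt(100^2 + 4 * 20^2))  # 107.70
  d0 <- build_dimer_model(100, delta_eps = 0)
  expect_equal(sort(eigen(system_hamiltonian(d0))$values), c(-20, 20))
})

test_that("spin-boson mapping doubles the reorganization energy", {
  d <- build_dimer_model(50)
  sb <- dimer_to_spin_boson(d)
  expect_equal(sb$bias, 100)
  expect_equal(sb$tunneling, 20)
  expect_equal(reorganization_energy(sb$sd), 100)
  lam_quad <- stats::integrate(function(w) sd_eval(sb$sd, w) / w, 0, Inf,
                               rel.tol = 1e-9)$value / pi
  expect_equal(lam_quad, 100, tolerance = 1e-5)
  expect_error(dimer_to_spin_boson(toy3()), "2-site")
})

test_that("model constructor validates inputs", {
  sd <- debye_spectral_density(10, 53)
  expect_error(frenkel_model(c(1, 2), matrix(c(0, 1, 2, 0), 2), sd, 300), "symmetric")
  expect_error(frenkel_model(c(1, 2), matrix(c(1, 3, 3, 0), 2), sd, 300), "diagonal")
})

test_that("model config file round-trips", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# dimer config", "sites: 2", "epsilon: 100 0",
               "coupling1: 0 20", "coupling2: 20 0",
               "bath: debye", "lambda: 35", "omega_c: 53",
               "temperature: 300"), f)
  m <- read_model_config(f)
  expect_equal(m$epsilon, c(100, 0))
  expect_equal(m$J_coupling[1, 2], 20)
  expect_equal(m$sd$lambda, 35)
  expect_equal(m$temperature, 300)
  expect_error(read_model_config(file.path(tempdir(), "nope.cfg")), "not found")
})
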