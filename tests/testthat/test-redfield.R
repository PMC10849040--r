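test_that("exciton basis is ascending, sign-fixed and round-trips", {
  m <- toy3()
  H <- system_hamiltonian(m)
  eb <- exciton_states(H)
  expect_true(all(diff(eb$energies) > 0))
  expect_equal(crossprod(eb$U), diag(3), tolerance = 1e-12)
  expect_equal(t(eb$U) %*% H %*% eb$U, diag(eb$energies), tolerance = 1e-10)
  for (k in 1:3) expect_gt(eb$U[which.max(abs(eb$U[, k])), k], 0)
  # zero couplings: excitons are sites sorted by energy
  m0 <- frenkel_model(c(30, 10, 20), matrix(0, 3, 3), m$sd, 300)
  eb0 <- exciton_states(system_hamiltonian(m0))
  expect_equal(eb0$energies, c(10, 20, 30))
  # exciton k is the unit vector of the site with the k-th smallest energy
  perm <- matrix(0, 3, 3)
  perm[cbind(order(c(30, 10, 20)), 1:3)] <- 1
  expect_equal(abs(eb0$U), perm, tolerance = 1e-12)
})

test_that("secular rates obey detailed balance and limits", {
  for (m in list(dimer(20), toy3(45))) {
    K <- secular_rates(m)
    w <- K$exciton_basis$energies
    N <- m$n_sites
    expect_equal(colSums(K$K), rep(0, N), tolerance = 1e-14)
    for (mu in seq_len(N)) for (nu in seq_len(N)) {
      if (mu >= nu) next
      expect_equal(K$K[mu, nu] / K$K[nu, mu],
                   exp(-m$beta * (w[mu] - w[nu])), tolerance = 1e-10)
    }
    # stationary state is the exciton Boltzmann distribution
    st <- excitondyn:::.stationary_populations(K$K)
    boltz <- exp(-m$beta * w) / sum(exp(-m$beta * w))
    expect_equal(st, boltz, tolerance = 1e-8)
  }
  # J = 0: no inter-exciton bath matrix elements -> all rates vanish
  m0 <- frenkel_model(c(100, 0), matrix(0, 2, 2), debye_spectral_density(30, 53), 300)
  expect_equal(secular_rates(m0)$K, matrix(0, 2, 2))
  # degeneracy is rejected
  mdeg <- frenkel_model(c(0, 0), matrix(0, 2, 2), debye_spectral_density(30, 53), 300)
  expect_error(secular_rates(mdeg), "degenerate|Degenerate")
})

test_that("full generator preserves trace and Hermiticity and reduces correctly", {
  m <- dimer(2)
  gen <- build_redfield_generator(m)
  N <- 2
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(complex(real = rnorm(N * N), imaginary = rnorm(N * N)), N)
    rho <- (A + Conj(t(A))) / 2
    dr <- matrix(gen$L %*% as.vector(rho), N, N)
    expect_lt(Mod(sum(diag(dr))), 1e-12)
    expect_lt(max(Mod(dr - Conj(t(dr)))), 1e-12)
  }
  # population block equals the secular rates
  Ks <- secular_rates(m)$K
  pp <- matrix(NA_real_, N, N)
  for (mu in 1:N) for (nu in 1:N)
    pp[mu, nu] <- Re(gen$L[mu + N * (mu - 1), nu + N * (nu - 1)])
  expect_equal(pp, Ks, tolerance = 1e-12)
  # lambda -> 0 (zero tabulated density): pure coherent part
  m0 <- frenkel_model(c(100, 0), matrix(c(0, 20, 20, 0), 2),
                      tabulated_spectral_density(c(1, 10, 100), c(0, 0, 0)), 300)
  gen0 <- build_redfield_generator(m0)
  w <- gen0$basis$energies
  Lcoh <- -1i * kap * (kronecker(diag(2), diag(w)) - kronecker(diag(w), diag(2)))
  expect_equal(gen0$L, Lcoh, tolerance = 1e-12)
})

test_that("propagation conserves trace and matches an independent expm oracle", {
  m <- dimer(2)
  gen <- build_redfield_generator(m)
  times <- seq(0, 5, length.out = 26)
  tr <- propagate_redfield(gen, diag(c(1, 0)), times)
  expect_equal(rowSums(tr$pop_site), rep(1, 26), tolerance = 1e-10)
  expect_equal(rowSums(tr$pop_exc), rep(1, 26), tolerance = 1e-10)
  # independent scaling-and-squaring matrix exponential at t = 2 ps
  t2 <- 2
  A <- gen$L * t2 / 2^9
  E <- diag(4) + 0i
  term <- diag(4) + 0i
  for (k in 1:20) { term <- term %*% A / k; E <- E + term }
  for (s in 1:9) E <- E %*% E
  U <- gen$basis$U
  rho_e <- t(U) %*% diag(c(1, 0)) %*% U
  rho_t <- matrix(E %*% as.vector(rho_e), 2, 2)
  oracle <- Re(diag(U %*% rho_t %*% t(U)))
  i2 <- which.min(abs(times - t2))
  expect_equal(tr$pop_site[i2, ], oracle, tolerance = 1e-8)
  # stationary state stays put
  st <- eigen(gen$L)
  v <- matrix(st$vectors[, which.min(Mod(st$values))], 2, 2)
  v <- (v + Conj(t(v))) / 2; v <- v / Re(sum(diag(v)))
  rho0 <- U %*% v %*% t(U)   # back to site basis
  trs <- propagate_redfield(gen, rho0, c(0, 5, 10))
  expect_equal(trs$pop_site[3, ], trs$pop_site[1, ], tolerance = 1e-9)
  expect_error(propagate_redfield(gen, matrix(c(1, 1i, 1i, 0), 2), c(0, 1)), "Hermitian")
})

test_that("weak-coupling eigenvalue structure behaves as benchmarked", {
  # Without the Lamb shift the slow eigenvalue reduces to the secular rate at
  # weak coupling; with it (the default, validated against hierarchical
  # benchmark dynamics) the pure-dephasing sector renormalizes it upward.
  m <- dimer(2)
  K <- secular_rates(m)$K
  k_sec <- K[1, 2] + K[2, 1]
  slow_of <- function(gen) {
    ev <- eigen(gen$L)$values
    real_evs <- Re(ev[abs(Im(ev)) < 1e-6])
    -max(real_evs[real_evs < -1e-9])
  }
  expect_equal(slow_of(build_redfield_generator(m, lamb_shift = FALSE)), k_sec,
               tolerance = 0.07)
  expect_gt(slow_of(build_redfield_generator(m)), k_sec)
})
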