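# Estimator algebra and the three initial-condition schemes, checked against
# sphere-moment oracles (Monte Carlo under a fixed seed).

test_that("estimator constants satisfy the printed relations and exact values", {
  for (N in c(2, 3, 5, 8)) {
    k <- estimator_constants(N)
    expect_equal(N * k$beta_N, 1 - k$alpha_N, tolerance = 1e-14)
    expect_equal(N * k$b_N, 1 - k$a_N, tolerance = 1e-14)
  }
  k2 <- estimator_constants(2)
  expect_equal(k2$alpha_N, 2)
  expect_equal(k2$beta_N, -1 / 2)
  k3 <- estimator_constants(3)
  expect_equal(k3$alpha_N, 12 / 5)       # (N-1)/(H_N-1), H_3 = 11/6
  expect_equal(k3$beta_N, -7 / 15)
  expect_equal(k3$a_N, 5 / 3)
  expect_equal(k3$b_N, -2 / 9)
  expect_error(estimator_constants(1), ">= 2")
})

test_that("population estimator normalizes and hits the exact corner values", {
  set.seed(1)
  for (N in c(2, 3, 8)) {
    s <- sample_uniform_sphere(N)
    expect_equal(sum(population_estimator(s$c)), 1, tolerance = 1e-12)
  }
  expect_equal(population_estimator(c(1, 0) + 0i), c(3 / 2, -1 / 2))
  expect_equal(population_estimator(c(1, 0, 0) + 0i), c(29 / 15, -7 / 15, -7 / 15))
  # the simplex center maps to itself
  expect_equal(population_estimator(rep(sqrt(1 / 4), 4) + 0i), rep(1 / 4, 4))
})

test_that("uniform sphere sampling has the exact moments", {
  set.seed(7)
  n <- 1e5
  N <- 8
  p <- t(vapply(seq_len(n), function(i) Mod(sample_uniform_sphere(N)$c)^2, numeric(N)))
  se <- apply(p, 2, sd) / sqrt(n)
  expect_true(all(abs(colMeans(p) - 1 / N) < 3 * se))
  expect_equal(rowSums(p)[1:5], rep(1, 5), tolerance = 1e-12)
  # fourth moment E|c_i|^4 = 2/(N(N+1)) at N = 3
  set.seed(8)
  p3 <- vapply(seq_len(n), function(i) Mod(sample_uniform_sphere(3)$c[1])^2, numeric(1))
  m4 <- mean(p3^2)
  expect_lt(abs(m4 - 2 / (3 * 4)), 3 * sd(p3^2) / sqrt(n))
  # cross moment E|c_i|^2|c_j|^2 = 1/(N(N+1))
  set.seed(9)
  pc <- t(vapply(seq_len(n), function(i) Mod(sample_uniform_sphere(3)$c[1:2])^2,
                 numeric(2)))
  cr <- pc[, 1] * pc[, 2]
  expect_lt(abs(mean(cr) - 1 / 12), 3 * sd(cr) / sqrt(n))
})

test_that("cap sampling satisfies its defining constraint and moments", {
  set.seed(11)
  n <- 2e4
  caps <- t(vapply(seq_len(n), function(i) Mod(init_cap(2, 2)$c)^2, numeric(2)))
  expect_true(all(caps[, 2] >= 0.5 - 1e-12))             # Theta_i = 1 always
  se <- sd(caps[, 2]) / sqrt(n)
  expect_lt(abs(mean(caps[, 2]) - 3 / 4), 3 * se)        # |c_i|^2 uniform on [1/2, 1]
})

test_that("all three schemes satisfy the t = 0 contract (weighted mean = delta)", {
  # moderate n here; the 1e5-sample vectorized version runs in the
  # acceptance suite
  n <- 2e4
  for (N in c(2, 3)) {
    k <- estimator_constants(N)
    i <- if (N > 2) 2L else 1L
    for (scheme in c("cap", "focused", "equivariant")) {
      set.seed(100 + N)
      est <- matrix(0, n, N); wts <- numeric(n)
      for (s in seq_len(n)) {
        smp <- switch(scheme, cap = init_cap(i, N), focused = init_focused(i, N),
                      equivariant = init_equivariant(i, N))
        est[s, ] <- smp$weight * population_estimator(smp$c, k)
        wts[s] <- smp$weight
      }
      se <- apply(est, 2, sd) / sqrt(n)
      target <- as.numeric(seq_len(N) == i)
      expect_true(all(abs(colMeans(est) - target) < 3 * pmax(se, 1e-14)),
                  label = sprintf("scheme %s N %d", scheme, N))
      if (scheme == "equivariant")
        expect_lt(abs(mean(wts) - 1), 3 * sd(wts) / sqrt(n))
    }
  }
})

test_that("focused scheme is exact per sample", {
  set.seed(5)
  for (N in c(2, 3)) {
    k <- estimator_constants(N)
    s <- init_focused(1, N)
    expect_equal(Mod(s$c[1])^2, (1 - k$beta_N) / k$alpha_N, tolerance = 1e-14)
    if (N == 2) expect_equal(Mod(s$c[2])^2, 1 / 4, tolerance = 1e-14)
    if (N == 3) expect_equal(Mod(s$c[2])^2, 7 / 36, tolerance = 1e-14)
    expect_equal(population_estimator(s$c, k),
                 as.numeric(seq_len(N) == 1), tolerance = 1e-12)
  }
})

test_that("equivariant weights transform correctly under a basis rotation", {
  set.seed(21)
  N <- 3
  k <- estimator_constants(N)
  U <- qr.Q(qr(matrix(rnorm(N * N), N)))         # random orthogonal rotation
  target <- U[, 2]                               # rotated target state
  for (rep in 1:20) {
    s <- sample_uniform_sphere(N)
    # weight for the rotated target computed directly in the original basis
    w_direct <- N * (k$a_N * Mod(sum(target * s$c))^2 + k$b_N)
    # same weight computed from the amplitudes expressed in the rotated basis
    c_rot <- as.vector(crossprod(U, s$c))
    w_rot <- N * (k$a_N * Mod(c_rot[2])^2 + k$b_N)
    expect_equal(w_rot, w_direct, tolerance = 1e-12)
  }
})
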