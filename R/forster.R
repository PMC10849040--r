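# Foerster theory: golden-rule hopping rates between sites built from the
# cumulant lineshape exponent g(t), and kinetic propagation of populations
# under a constant rate matrix.

#' Foerster rate between two sites
#'
#' For identical independent site baths the donor fluorescence and acceptor
#' absorption lineshapes combine into
#' \deqn{k_{n\to m} = 2 J_{nm}^2\, \mathrm{Re} \int_0^\infty
#'   e^{\,i(\epsilon_n - \epsilon_m - 2\lambda) t - 2 g(t)}\, dt,}
#' with the Stokes shift \eqn{2\lambda} on the fluorescence function.  The
#' integral runs on a uniform grid with Simpson weights and is truncated
#' when \eqn{e^{-2\,\mathrm{Re}\,g(t)}} falls below `tail_tol` (or at
#' `t_cap`, whichever comes first).
#'
#' @param model A `frenkel_model`.
#' @param n Donor site index.
#' @param m Acceptor site index (different from `n`).
#' @param dt Integration step in ps (default 1e-4 ps = 0.1 fs).
#' @param tail_tol Truncation threshold on the decay envelope.
#' @param t_cap Hard cap on the upper integration limit in ps.
#' @return Non-negative rate in ps^-1.
#' @export
forster_rate <- function(model, n, m, dt = 1e-4, tail_tol = 1e-10, t_cap = 200) {
  stopifnot(inherits(model, "frenkel_model"))
  N <- model$n_sites
  if (n == m || n < 1 || m < 1 || n > N || m > N) stop("need two distinct site indices")
  J <- model$J_coupling[n, m]
  if (J == 0) return(0)
  prof <- .forster_profile(model$sd, model$temperature, dt, tail_tol, t_cap)
  x <- model$epsilon[n] - model$epsilon[m] - 2 * reorganization_energy(model$sd)
  max(2 * (.kappa * J)^2 * .forster_overlap(prof, x), 0)
}

# time grid, Simpson weights and decay envelope exp(-2 g(t)) of the
# lineshape overlap integral; shared by all site pairs of one bath
.forster_profile <- function(sd, temperature, dt = 1e-4, tail_tol = 1e-10,
                             t_cap = 200) {
  bc <- bath_correlation(sd, temperature)
  tmax <- .forster_tmax(bc, tail_tol, t_cap)
  nt <- ceiling(tmax / dt)
  if (nt %% 2 == 1) nt <- nt + 1          # Simpson needs an even interval count
  tg <- seq(0, by = dt, length.out = nt + 1)
  g <- lineshape_g(bc, tg)
  list(tg = tg, w = .simpson_weights(nt + 1) * dt, env = exp(-2 * g))
}

# Re int_0^inf exp(i kappa x t) exp(-2 g(t)) dt for a detuning x in cm^-1
.forster_overlap <- function(prof, x) {
  Re(sum(prof$w * prof$env * exp(1i * .kappa * x * prof$tg)))
}

# spline table of the overlap integral over a detuning range (cm^-1); used
# to evaluate many disorder realizations cheaply
.forster_kernel <- function(sd, temperature, x_range, dx = 1, ...) {
  prof <- .forster_profile(sd, temperature, ...)
  xs <- seq(x_range[1] - 2 * dx, x_range[2] + 2 * dx, by = dx)
  ph <- exp(1i * .kappa * outer(prof$tg, xs))
  vals <- as.numeric(Re(t(prof$w * prof$env) %*% ph))
  stats::splinefun(xs, vals)
}

# upper time limit where exp(-2 Re g) < tol, by doubling search
.forster_tmax <- function(bc, tol, t_cap) {
  t <- 0.5
  while (t < t_cap) {
    if (Re(lineshape_g(bc, t)) > -log(tol) / 2) break
    t <- t * 2
  }
  if (t >= t_cap)
    warning(sprintf("Foerster integral truncated at t = %g ps before envelope < %g", t_cap, tol))
  min(t, t_cap)
}

.simpson_weights <- function(n) {  # n odd number of points
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w / 3
}

#' Full Foerster rate matrix of a model
#'
#' Fills every ordered pair with non-zero coupling by [forster_rate()];
#' convention `[m, n] = rate n -> m`, diagonal = minus column sums.
#'
#' @inheritParams forster_rate
#' @return A `rate_matrix` in the site basis.
#' @export
forster_rate_matrix <- function(model, dt = 1e-4, tail_tol = 1e-10, t_cap = 200) {
  stopifnot(inherits(model, "frenkel_model"))
  prof <- .forster_profile(model$sd, model$temperature, dt, tail_tol, t_cap)
  .forster_matrix_from(model, function(x) .forster_overlap(prof, x))
}

# assemble the rate matrix given an overlap evaluator I(x)
.forster_matrix_from <- function(model, overlap) {
  N <- model$n_sites
  lam2 <- 2 * reorganization_energy(model$sd)
  K <- matrix(0, N, N)
  for (n in seq_len(N)) for (m in seq_len(N)) {
    J <- model$J_coupling[n, m]
    if (n != m && J != 0)
      K[m, n] <- max(2 * (.kappa * J)^2 *
                       overlap(model$epsilon[n] - model$epsilon[m] - lam2), 0)
  }
  diag(K) <- -colSums(K)
  structure(list(K = K, basis = "site", model = model), class = "rate_matrix")
}

#' Propagate populations under a constant rate matrix
#'
#' Solves dp/dt = K p by matrix exponential (spectral decomposition of K,
#' with a scaling-and-squaring fallback for defective matrices).
#'
#' @param rates A `rate_matrix` or a plain N x N matrix with zero column
#'   sums and non-negative off-diagonals.
#' @param p0 Initial probability vector (non-negative, sums to 1).
#' @param times Output times in ps.
#' @return A `population_trace` in the basis of the rate matrix.
#' @export
propagate_kinetic <- function(rates, p0, times) {
  K <- if (inherits(rates, "rate_matrix")) rates$K else as.matrix(rates)
  N <- nrow(K)
  if (max(abs(colSums(K))) > 1e-8 * max(1, max(abs(K))))
    stop("malformed rate matrix: column sums must be zero")
  if (any(K - diag(diag(K)) < -1e-12)) stop("off-diagonal rates must be non-negative")
  stopifnot(length(p0) == N, all(p0 >= 0))
  if (abs(sum(p0) - 1) > 1e-8) stop("p0 must sum to 1")
  ed <- eigen(K)
  p <- matrix(NA_real_, length(times), N)
  ok <- rcond(ed$vectors) > 1e-10
  if (ok) {
    a0 <- solve(ed$vectors, p0)
    for (k in seq_along(times))
      p[k, ] <- Re(ed$vectors %*% (exp(ed$values * times[k]) * a0))
  } else {
    for (k in seq_along(times)) p[k, ] <- .expm_mult(K * times[k], p0)
  }
  bas <- if (inherits(rates, "rate_matrix")) rates$basis else "site"
  if (identical(bas, "exciton"))
    new_population_trace(times, pop_site = NULL, pop_exc = p, method = "kinetic")
  else
    new_population_trace(times, pop_site = p, pop_exc = NULL, method = "kinetic")
}

# scaling-and-squaring expm action on a vector (fallback path)
.expm_mult <- function(A, v) {
  s <- max(0, ceiling(log2(max(1, norm(A, "1")))))
  B <- A / 2^s
  E <- diag(1, nrow(A))
  term <- diag(1, nrow(A))
  for (k in 1:16) {
    term <- term %*% B / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  as.numeric(E %*% v)
}
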