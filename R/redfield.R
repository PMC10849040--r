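# Redfield theory in the exciton basis: the eigenbasis of H_S, the full
# (non-secular) master-equation generator, its propagation, and the secular
# population-transfer rates.  Rate-matrix convention throughout the package:
# entry [mu, nu] is the rate nu -> mu, so populations obey dp/dt = K p with
# column sums of K equal to zero.

#' Exciton basis of a system Hamiltonian
#'
#' Eigendecomposition of a (real symmetric) site-basis Hamiltonian with
#' eigenvalues sorted ascending; the largest-magnitude component of each
#' eigenvector is made positive.  Exciton `mu` is column `mu` of `U`, and
#' `U^T H U` is diagonal.
#'
#' @param H Symmetric N x N matrix in cm^-1.
#' @return An object of class `exciton_basis` with fields `energies`
#'   (ascending, cm^-1) and `U` (N x N orthogonal, columns = excitons).
#' @export
exciton_states <- function(H) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  if (max(abs(H - t(H))) > 1e-8) stop("Hamiltonian must be symmetric")
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  for (k in seq_along(vals)) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) U[, k] <- -U[, k]
  }
  structure(list(energies = vals, U = U), class = "exciton_basis")
}

#' Assemble the (non-secular) Redfield generator
#'
#' Second-order Born-Markov generator for identical independent site baths,
#' expressed in the exciton basis.  With site projectors
#' \eqn{A_n = |n\rangle\langle n|} and the half-Fourier bath spectrum
#' \eqn{\tilde C(\omega)}, the one-sided operators
#' \eqn{(\Lambda_n)_{\mu\nu} = (A_n)_{\mu\nu} \tilde C(\omega_\nu -
#' \omega_\mu)} enter
#' \deqn{\dot\rho = -i[H_S, \rho] + \sum_n \left( \Lambda_n \rho A_n -
#'  A_n \Lambda_n \rho + A_n \rho \Lambda_n^\dagger -
#'  \rho \Lambda_n^\dagger A_n \right),}
#' which preserves trace and Hermiticity.  The imaginary (Lamb-shift-like)
#' part of \eqn{\tilde C} never affects the secular population rates, but in
#' the non-secular generator it couples populations to coherences through
#' the pure-dephasing fluctuations (whose scale \eqn{\propto \lambda k_B
#' T/\omega_c} is large even when \eqn{\lambda} is small) and thereby
#' renormalizes the slow relaxation eigenvalue substantially; hierarchical
#' benchmark dynamics confirm the renormalized value, so the term is
#' included by default (see the methods vignette).
#'
#' @param model A `frenkel_model`.
#' @param lamb_shift Logical; include Im C~ in the one-sided operators
#'   (default `TRUE`).
#' @return An object of class `redfield_generator` with the N^2 x N^2
#'   complex superoperator `L` (units ps^-1, acting on vec of the
#'   exciton-basis density matrix), the `exciton_basis`, and the model.
#' @export
build_redfield_generator <- function(model, lamb_shift = TRUE) {
  stopifnot(inherits(model, "frenkel_model"))
  N <- model$n_sites
  eb <- exciton_states(system_hamiltonian(model))
  if (N > 1 && min(diff(eb$energies)) < 1e-6)
    warning("near-degenerate exciton energies; secular rates are ill-defined")
  bc <- bath_correlation(model$sd, model$temperature)
  # C~ at all N^2 energy gaps omega_nu - omega_mu
  gaps <- outer(eb$energies, eb$energies, function(a, b) b - a)  # [mu,nu] = w_nu - w_mu
  Ct <- matrix(corr_spectrum(bc, as.numeric(gaps), imaginary = lamb_shift), N, N)
  Id <- diag(1, N)
  D <- diag(eb$energies, N)
  L <- matrix(0 + 0i, N * N, N * N)
  L <- L - 1i * .kappa * (kronecker(Id, D) - kronecker(D, Id))
  for (n in seq_len(N)) {
    An <- tcrossprod(eb$U[n, ])            # (A_n)_{mu nu} in exciton basis
    Ln <- An * Ct                          # Lambda_n
    L <- L + .kappa * (kronecker(An, Ln) - kronecker(Id, An %*% Ln) +
                       kronecker(Conj(Ln), An) - kronecker(An %*% Conj(Ln), Id))
  }
  structure(list(L = L, basis = eb, model = model, lamb_shift = lamb_shift),
            class = "redfield_generator")
}

#' Propagate a density matrix under the Redfield generator
#'
#' Spectral decomposition of the superoperator is used, so arbitrary output
#' times cost one 64 x 64 (for N = 8) eigensolve.  The input density matrix
#' is given in the site basis; populations are returned in both the site and
#' exciton bases.  Positivity is not enforced (Redfield may violate it); the
#' most negative transient population is recorded in the result.
#'
#' @param gen A `redfield_generator`.
#' @param rho0 Hermitian, unit-trace N x N density matrix in the site basis.
#' @param times Output times in ps.
#' @return A `population_trace` with site- and exciton-basis populations.
#' @export
propagate_redfield <- function(gen, rho0, times) {
  stopifnot(inherits(gen, "redfield_generator"))
  N <- gen$model$n_sites
  rho0 <- as.matrix(rho0)
  if (max(Mod(rho0 - Conj(t(rho0)))) > 1e-10) stop("rho0 must be Hermitian")
  if (abs(sum(diag(rho0)) - 1) > 1e-10) stop("rho0 must have unit trace")
  U <- gen$basis$U
  rho_e <- t(U) %*% rho0 %*% U            # to exciton basis
  ed <- eigen(gen$L)
  a0 <- solve(ed$vectors, as.vector(rho_e))
  pop_site <- matrix(NA_real_, length(times), N)
  pop_exc <- matrix(NA_real_, length(times), N)
  min_eig <- 0
  for (k in seq_along(times)) {
    v <- ed$vectors %*% (exp(ed$values * times[k]) * a0)
    rho_t <- matrix(v, N, N)
    rho_t <- (rho_t + Conj(t(rho_t))) / 2
    tr <- Re(sum(diag(rho_t)))
    if (abs(tr - 1) > 1e-8)
      warning(sprintf("trace deviates by %.2e at t = %g ps", tr - 1, times[k]))
    pop_exc[k, ] <- Re(diag(rho_t))
    rho_s <- U %*% rho_t %*% t(U)
    pop_site[k, ] <- Re(diag(rho_s))
    min_eig <- min(min_eig, min(Re(eigen(rho_t, only.values = TRUE,
                                         symmetric = FALSE)$values)))
  }
  new_population_trace(times, pop_site, pop_exc,
                       method = "redfield", extra = list(min_eigenvalue = min_eig))
}

#' Secular Redfield population-transfer rates
#'
#' \deqn{k_{\nu\to\mu} = 2\,\mathrm{Re}\,\tilde C(\omega_\nu - \omega_\mu)
#'   \sum_n |\langle\mu|n\rangle|^2 |\langle\nu|n\rangle|^2}
#' for identical independent site baths.  The returned matrix follows the
#' package convention `[mu, nu] = rate nu -> mu` with diagonal entries equal
#' to minus the column sums; detailed balance
#' \eqn{k_{\nu\to\mu}/k_{\mu\to\nu} = e^{-\beta(\omega_\mu-\omega_\nu)}} is
#' inherited from the bath spectrum.
#'
#' @param model A `frenkel_model`.
#' @return A list of class `rate_matrix` with the N x N matrix `K`
#'   (ps^-1), `basis` (`"exciton"`), the `exciton_basis`, and the model.
#' @export
secular_rates <- function(model) {
  stopifnot(inherits(model, "frenkel_model"))
  N <- model$n_sites
  eb <- exciton_states(system_hamiltonian(model))
  if (N > 1 && min(diff(eb$energies)) < 1e-6)
    stop("degenerate exciton energies: secular rates undefined")
  bc <- bath_correlation(model$sd, model$temperature)
  overlap <- crossprod(eb$U^2)             # [mu,nu] = sum_n U_{n mu}^2 U_{n nu}^2
  gaps <- outer(eb$energies, eb$energies, function(a, b) b - a)  # w_nu - w_mu
  K <- 2 * .kappa * Re(matrix(corr_spectrum(bc, as.numeric(gaps), imaginary = FALSE),
                              N, N)) * overlap
  diag(K) <- 0
  diag(K) <- -colSums(K)
  structure(list(K = K, basis = "exciton", exciton_basis = eb, model = model),
            class = "rate_matrix")
}
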