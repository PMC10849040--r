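# Multi-state MASH: equivariant population estimators, the four initial
# electronic sampling schemes, the quantum-classical equilibrium oracle, and
# R wrappers around the compiled trajectory engine.

#' Estimator and initial-condition constants for N states
#'
#' The equivariant population estimator is \eqn{O_n(c) = \alpha_N |c_n|^2 +
#' \beta_N} with \eqn{\alpha_N = (N-1)/(H_N - 1)} (harmonic number
#' \eqn{H_N}) and \eqn{N\beta_N = 1 - \alpha_N}.  The equivariant initial
#' quasiprobability uses \eqn{a_N = (N+1)/\alpha_N} and
#' \eqn{N b_N = 1 - a_N}, fixed by the sphere moments
#' \eqn{E|c_i|^4 = 2/(N(N+1))} and \eqn{E|c_i|^2|c_j|^2 = 1/(N(N+1))}.
#'
#' @param N Number of electronic states (>= 2).
#' @return List with `N`, `H_N`, `alpha_N`, `beta_N`, `a_N`, `b_N`.
#' @examples
#' estimator_constants(2)  # alpha = 2, beta = -1/2
#' @export
estimator_constants <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("'N' must be an integer >= 2")
  H_N <- sum(1 / seq_len(N))
  alpha_N <- (N - 1) / (H_N - 1)
  beta_N <- (1 - alpha_N) / N
  a_N <- (N + 1) / alpha_N
  b_N <- (1 - a_N) / N
  list(N = as.integer(N), H_N = H_N, alpha_N = alpha_N, beta_N = beta_N,
       a_N = a_N, b_N = b_N)
}

#' Equivariant population estimator
#'
#' @param c Complex amplitude vector, normalized to 1.
#' @param consts Output of [estimator_constants()] (defaults to
#'   `estimator_constants(length(c))`).
#' @return Population vector summing to 1 (entries may be negative).
#' @export
population_estimator <- function(c, consts = estimator_constants(length(c))) {
  stopifnot(abs(sum(Mod(c)^2) - 1) < 1e-10)
  consts$alpha_N * Mod(c)^2 + consts$beta_N
}

#' Sample a wavefunction uniformly on the unit sphere
#'
#' Draws 2N standard normal deviates and normalizes, giving the uniform
#' measure on normalized complex N-vectors.  Uses R's RNG.
#'
#' @param N Number of states.
#' @return List with complex vector `c` and `weight` (1).
#' @export
sample_uniform_sphere <- function(N) {
  z <- complex(real = stats::rnorm(N), imaginary = stats::rnorm(N))
  list(c = z / sqrt(sum(Mod(z)^2)), weight = 1)
}

#' Cap initial condition
#'
#' Rejection-samples the uniform sphere until state `i` carries the largest
#' population, i.e. a uniform sample from the cap of state `i`.
#'
#' @param i Target state index.
#' @param N Number of states.
#' @return List with `c` and `weight` (1).
#' @export
init_cap <- function(i, N) {
  stopifnot(i >= 1, i <= N)
  repeat {
    s <- sample_uniform_sphere(N)
    if (which.max(Mod(s$c)^2) == i) return(s)
  }
}

#' Focused initial condition
#'
#' Fixes the moduli to \eqn{|c_i|^2 = (1-\beta_N)/\alpha_N} and
#' \eqn{|c_{j\ne i}|^2 = -\beta_N/\alpha_N} so that the estimator of every
#' sample is exactly the Kronecker delta at `i`; phases are uniform.
#'
#' @inheritParams init_cap
#' @return List with `c` and `weight` (1).
#' @export
init_focused <- function(i, N) {
  stopifnot(i >= 1, i <= N)
  k <- estimator_constants(N)
  mod <- rep(sqrt(-k$beta_N / k$alpha_N), N)
  mod[i] <- sqrt((1 - k$beta_N) / k$alpha_N)
  ph <- stats::runif(N, 0, 2 * pi)
  list(c = mod * exp(1i * ph), weight = 1)
}

#' Equivariant initial condition
#'
#' Uniform-sphere sample carrying the signed quasiprobability weight
#' \eqn{N (a_N |c_i|^2 + b_N)}; the weighted mean of the estimator at t = 0
#' is the Kronecker delta at `i`, and the construction transforms correctly
#' under unitary basis changes.
#'
#' @inheritParams init_cap
#' @return List with `c` and signed `weight`.
#' @export
init_equivariant <- function(i, N) {
  stopifnot(i >= 1, i <= N)
  k <- estimator_constants(N)
  s <- sample_uniform_sphere(N)
  list(c = s$c, weight = N * (k$a_N * Mod(s$c[i])^2 + k$b_N))
}

# ---- adiabatic electronic structure --------------------------------------

# Convert model + discretized bath to the engine's internal units (rad/ps).
.internal_units <- function(model, bath) {
  list(eps = .kappa * model$epsilon,
       Jc = .kappa * model$J_coupling,
       omega = .kappa * bath$omega,
       coupling = .kappa^1.5 * bath$coupling,
       kT = .kappa * .kB * model$temperature)
}

#' Adiabatic electronic structure at a nuclear configuration
#'
#' Diagonalizes the diabatic potential matrix \eqn{V_{nn}(q) = \epsilon_n +
#' \sum_j c_j q_{j,n}}, \eqn{V_{nm} = J_{nm}} and returns adiabatic energies
#' (including the common harmonic term), the transform, the analytic
#' gradient of the active surface, and all nonadiabatic coupling vectors
#' \eqn{d^j_{ab} = \langle a|\nabla_j V|b\rangle/(V_b - V_a)}.
#'
#' All quantities are in the engine's internal units (energies in rad/ps;
#' `q` mass-scaled with unit masses); use the `internal` element of the
#' return value of [run_ensemble()] diagnostics or `excitondyn:::.internal_units`
#' to convert a model/bath pair.
#'
#' @param model A `frenkel_model`.
#' @param bath A `discretized_bath`.
#' @param q Nuclear coordinates, an M x N matrix (mode, site) in internal
#'   units.
#' @param active Active adiabat index for the gradient (default 1).
#' @return List with `V` (adiabatic energies incl. harmonic part, rad/ps),
#'   `V_el` (electronic eigenvalues), `U` (N x N transform, columns =
#'   adiabats), `grad_active` (M x N), and `d` (array M x N x N x N of
#'   couplings `d[j, n, a, b]`).
#' @export
adiabatic_structure <- function(model, bath, q, active = 1) {
  stopifnot(inherits(model, "frenkel_model"), inherits(bath, "discretized_bath"))
  iu <- .internal_units(model, bath)
  N <- model$n_sites; M <- bath$n_modes
  q <- matrix(q, M, N)
  W <- iu$Jc
  diag(W) <- iu$eps + colSums(iu$coupling * q)
  e <- eigen(W, symmetric = TRUE)
  ord <- order(e$values)
  V_el <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  harm <- 0.5 * sum(iu$omega^2 * q^2)
  grad <- -(-iu$omega^2 * q - outer(iu$coupling, U[, active]^2))
  d <- array(0, c(M, N, N, N))
  for (a in seq_len(N)) for (b in seq_len(N)) {
    if (a == b) next
    gap <- V_el[b] - V_el[a]
    if (abs(gap) < 1e-8) gap <- sign(gap + (gap == 0)) * 1e-8
    d[, , a, b] <- outer(iu$coupling, U[, a] * U[, b]) / gap
  }
  list(V = V_el + harm, V_el = V_el, U = U, grad_active = grad, d = d)
}

#' Momentum rescaling/reversal at a surface hop
#'
#' Decomposes the momentum along the (normalized) rescaling direction `v`.
#' If the kinetic energy in that component covers the potential step `gap`,
#' the parallel component is rescaled to conserve total energy and the hop
#' is accepted; otherwise the parallel component is reversed and the hop is
#' frustrated.  The perpendicular component is never touched.
#'
#' @param p Momentum vector.
#' @param v Rescaling direction (need not be normalized).
#' @param gap Potential step `V_b - V_a` (same units as `p^2/2`).
#' @return List with `p` (updated momentum) and `accepted` (logical).
#' @export
mash_hop_update <- function(p, v, gap) {
  vn <- sqrt(sum(v^2))
  if (vn == 0) stop("rescaling direction must be non-zero")
  vhat <- v / vn
  pv <- sum(p * vhat)
  if (0.5 * pv^2 >= gap) {
    pvnew <- sign(pv) * sqrt(pv^2 - 2 * gap)
    list(p = p + (pvnew - pv) * vhat, accepted = TRUE)
  } else {
    list(p = p - 2 * pv * vhat, accepted = FALSE)
  }
}

# ---- ensemble driver -----------------------------------------------------

#' Run a MASH trajectory ensemble
#'
#' Propagates `n_traj` MASH trajectories of a Frenkel-exciton model with a
#' discretized bath.  Nuclei start from the classical Boltzmann distribution
#' of the uncoupled bath; the electronic state starts from the chosen
#' sampling scheme in the requested basis.  Observables are (weighted)
#' ensemble means of the equivariant population estimator in the site and
#' exciton bases, with standard errors from batch means.
#'
#' @param model A `frenkel_model`.
#' @param bath A `discretized_bath` (per site; all sites identical).
#' @param init_state Initially excited state index (site or exciton).
#' @param scheme One of `"cap"`, `"focused"`, `"equivariant"`,
#'   `"original"` (the two-state prescription; requires 2 sites).
#' @param basis Basis of the initial excitation, `"site"` or `"exciton"`.
#' @param n_traj Number of trajectories.
#' @param t_max Propagation time in ps.
#' @param dt Time step in ps (default 5e-4 ps = 0.5 fs).
#' @param seed Integer seed (mandatory; the compiled engine uses its own
#'   deterministic per-trajectory streams derived from it).
#' @param record_every Record observables every this many steps.
#' @param n_batch Number of batches for standard errors and bootstrap.
#' @param disorder_sigma Optional per-site Gaussian static-disorder standard
#'   deviations in cm^-1, resampled per trajectory.
#' @return A `population_trace` with populations, standard errors, batch
#'   means and engine diagnostics in `$extra`.
#' @export
run_ensemble <- function(model, bath, init_state = 1,
                         scheme = c("cap", "focused", "equivariant", "original"),
                         basis = c("site", "exciton"),
                         n_traj = 10000, t_max = 1, dt = 5e-4, seed = 1,
                         record_every = max(1L, round(t_max / dt / 400)),
                         n_batch = 50, disorder_sigma = NULL) {
  stopifnot(inherits(model, "frenkel_model"), inherits(bath, "discretized_bath"),
            n_traj >= 1)
  scheme <- match.arg(scheme)
  basis <- match.arg(basis)
  N <- model$n_sites
  if (scheme == "original" && N != 2) stop("original MASH requires a 2-site model")
  if (init_state < 1 || init_state > N) stop("invalid 'init_state'")
  k <- estimator_constants(N)
  iu <- .internal_units(model, bath)
  n_steps <- ceiling(t_max / dt)
  record_every <- max(1L, as.integer(record_every))
  n_steps <- as.integer(ceiling(n_steps / record_every) * record_every)
  sig <- if (is.null(disorder_sigma)) rep(0, N) else .kappa * disorder_sigma
  stopifnot(length(sig) == N)
  n_batch <- min(n_batch, n_traj)

  res <- .mash_ensemble_cpp(iu$eps, sig, iu$Jc, iu$omega, iu$coupling, iu$kT,
                            dt, n_steps, record_every, as.integer(n_traj),
                            as.integer(n_batch), as.integer(init_state) - 1L,
                            if (basis == "exciton") 1L else 0L,
                            match(scheme, c("cap", "focused", "equivariant", "original")) - 1L,
                            k$alpha_N, k$beta_N, k$a_N, k$b_N, as.integer(seed))
  if (res$n_dropped > 0.001 * n_traj)
    stop(sprintf("%d of %d trajectories diverged", res$n_dropped, n_traj))

  times <- seq(0, by = record_every * dt, length.out = dim(res$acc_site)[1])
  tot <- sum(res$batch_n)
  mk <- function(acc) {
    m <- apply(acc, c(1, 2), sum) / tot
    # batch means and their spread
    bm <- sweep(acc, 3, pmax(res$batch_n, 1), "/")
    nb <- sum(res$batch_n > 0)
    se <- sqrt(apply(bm, c(1, 2), stats::var) / nb)
    list(mean = m, se = se, batches = bm)
  }
  s <- mk(res$acc_site); e <- mk(res$acc_exc)
  new_population_trace(times, pop_site = s$mean, pop_exc = e$mean,
                       se_site = s$se, se_exc = e$se,
                       n_traj = as.integer(tot), method = "mash",
                       scheme = scheme, seed = seed,
                       batch_site = s$batches, batch_exc = e$batches,
                       extra = res[c("n_hops", "n_frustrated", "n_event_overflow",
                                     "n_dropped", "max_norm_err",
                                     "max_seg_drift_rate", "max_hop_err")])
}

#' Original two-state MASH ensemble
#'
#' Runs the original two-state surface-hopping prescription: identical
#' nuclear dynamics, but diabatic observables are decomposed in the
#' adiabatic basis, where populations are measured by the state indicator
#' and coherences by coefficient bilinears carrying the weight
#' \eqn{W_a(c) = 4|c_a|^2 - 2} (zero at equal adiabatic populations).
#'
#' @inheritParams run_ensemble
#' @return A `population_trace`.
#' @export
original_mash_two_state <- function(model, bath, init_state = 1, n_traj = 10000,
                                    t_max = 1, dt = 5e-4, seed = 1,
                                    record_every = max(1L, round(t_max / dt / 400)),
                                    n_batch = 50) {
  run_ensemble(model, bath, init_state = init_state, scheme = "original",
               basis = "site", n_traj = n_traj, t_max = t_max, dt = dt,
               seed = seed, record_every = record_every, n_batch = n_batch)
}

#' Single-trajectory propagation (debugging/validation interface)
#'
#' Integrates one deterministic MASH trajectory from an explicit phase-space
#' point with the compiled engine and returns the final state together with
#' norm/energy-conservation diagnostics.
#'
#' @param model A `frenkel_model`.
#' @param bath A `discretized_bath`.
#' @param q,p Nuclear coordinates/momenta (length `n_sites * n_modes`,
#'   internal units).
#' @param c Complex electronic amplitudes in the site basis.
#' @param n_steps Number of steps.
#' @param dt Time step in ps.
#' @param active Initial active adiabat (default: largest population).
#' @return List with final `q`, `p`, `c`, `active`, initial/final total
#'   energy, hop counts and conservation diagnostics.
#' @export
step_trajectory <- function(model, bath, q, p, c, n_steps = 1, dt = 5e-4,
                            active = NULL) {
  stopifnot(inherits(model, "frenkel_model"), inherits(bath, "discretized_bath"))
  if (dt <= 0) stop("'dt' must be positive")
  iu <- .internal_units(model, bath)
  .mash_trajectory_cpp(iu$eps, iu$Jc, iu$omega, iu$coupling, iu$kT, dt,
                       as.integer(n_steps), as.numeric(q), as.numeric(p),
                       as.complex(c), if (is.null(active)) -1L else as.integer(active) - 1L)
}

# ---- equilibrium oracle --------------------------------------------------

#' Quantum-classical equilibrium populations of MASH
#'
#' Monte-Carlo estimate of the long-time MASH distribution: nuclear
#' configurations are importance-sampled from the uncoupled-bath Boltzmann
#' distribution and reweighted by \eqn{e^{-\beta W_a(q)}} on each adiabat
#' `a`; the electronic wavefunction is uniform on the cap of the occupied
#' adiabat, for which the conditional moments are
#' \eqn{E[|c_b|^2 | \mathrm{cap}_a] = H_N/N} for `b = a` and
#' \eqn{(1 - H_N/N)/(N-1)} otherwise.  The equivariant estimator (or the
#' original two-state indicator) is then averaged in the requested basis.
#'
#' @param model A `frenkel_model`.
#' @param bath A `discretized_bath`.
#' @param basis `"site"` or `"exciton"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed Integer seed.
#' @param estimator `"equivariant"` (multi-state) or `"original"`
#'   (two-state adiabatic indicator).
#' @return List with `populations`, `se` (delta-method standard errors) and
#'   `sigma_z` (P_1 - P_2, two-state models only).
#' @export
equilibrium_populations <- function(model, bath, basis = c("site", "exciton"),
                                    n_samples = 200000, seed = 1,
                                    estimator = c("equivariant", "original")) {
  stopifnot(inherits(model, "frenkel_model"), inherits(bath, "discretized_bath"))
  basis <- match.arg(basis)
  estimator <- match.arg(estimator)
  N <- model$n_sites; M <- bath$n_modes
  if (estimator == "original" && N != 2) stop("original estimator requires 2 states")
  k <- estimator_constants(N)
  iu <- .internal_units(model, bath)
  beta_t <- model$beta / .kappa
  m_same <- k$H_N / N
  m_other <- (1 - m_same) / (N - 1)
  Uexc <- if (basis == "exciton") exciton_states(system_hamiltonian(model))$U else diag(1, N)

  # local RNG scope: restore the caller's stream afterwards
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  num <- matrix(0, 0, N); den <- numeric(0)
  withr_seed({
    chunk <- 5000L
    done <- 0L
    num <- matrix(0, n_samples, N); den <- numeric(n_samples)
    while (done < n_samples) {
      nc <- min(chunk, n_samples - done)
      # site-energy shifts sum_j c_j q_jn for all samples/sites at once
      z <- matrix(stats::rnorm(nc * M * N), M)          # M x (nc N)
      shifts <- matrix(colSums(sqrt(iu$kT) / iu$omega * iu$coupling * z), nc, N)
      for (s in seq_len(nc)) {
        W <- iu$Jc
        diag(W) <- iu$eps + shifts[s, ]
        e <- eigen(W, symmetric = TRUE)
        ord <- order(e$values)
        Vel <- e$values[ord]; U <- e$vectors[, ord, drop = FALSE]
        # global (sample-independent) energy reference: per-sample shifts
        # would bias the ratio estimator
        w_a <- exp(-beta_t * (Vel - min(iu$eps)))
        P <- crossprod(Uexc, U)^2                        # [obs, adiabat]
        mom <- matrix(m_other, N, N); diag(mom) <- m_same # [adiabat(occ), adiabat]
        est <- if (estimator == "equivariant") {
          k$alpha_N * P %*% t(mom) + k$beta_N            # [obs, occupied adiabat]
        } else {
          P                                              # indicator: O_aa
        }
        num[done + s, ] <- as.numeric(est %*% w_a)
        den[done + s] <- sum(w_a)
      }
      done <- done + nc
    }
  })
  pop <- colMeans(num) / mean(den)
  # delta-method SE of the ratio estimator
  se <- vapply(seq_len(N), function(n) {
    r <- pop[n]
    stats::sd(num[, n] - r * den) / mean(den) / sqrt(n_samples)
  }, numeric(1))
  out <- list(populations = pop, se = se)
  if (N == 2) {
    out$sigma_z <- pop[1] - pop[2]
    out$sigma_z_se <- stats::sd((num[, 1] - num[, 2]) -
                                  out$sigma_z * den) / mean(den) / sqrt(n_samples)
  }
  out
}
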