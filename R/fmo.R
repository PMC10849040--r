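# Eight-site Fenna-Matthews-Olson (FMO) model of Prosthecochloris
# aestuarii: average site energies and couplings from electrostatic
# calculations, Gaussian static disorder of the site energies, and drivers
# for the site-basis and exciton-basis transfer experiments.

.fmo_fwhm_to_sigma <- 1 / (2 * sqrt(2 * log(2)))

#' Build the eight-site FMO model
#'
#' Loads the packaged average site energies and couplings (cm^-1, site 3 is
#' the energy reference) and the Gaussian disorder widths (FWHM, cm^-1).
#' The experimentally derived structured spectral density of this complex is
#' not distributed with the package; the default bath is a Debye substitute
#' carrying the same reorganization energy, `debye_spectral_density(45, 106)`,
#' and a tabulated density can be supplied instead.
#'
#' @param sd Optional `spectral_density` (default Debye, lambda = 45 cm^-1,
#'   omega_c = 106 cm^-1).
#' @param temperature Temperature in kelvin (default 300).
#' @return An object of class `fmo_model` with fields `mean_epsilon`,
#'   `coupling`, `fwhm`, `sd`, `temperature`.
#' @examples
#' fmo <- build_fmo_model()
#' fmo$coupling[1, 2]   # -94.8 cm^-1
#' @export
build_fmo_model <- function(sd = NULL, temperature = 300) {
  H <- as.matrix(utils::read.table(
    system.file("extdata", "fmo_site_hamiltonian.txt", package = "excitondyn"),
    comment.char = "#"))
  dimnames(H) <- NULL
  fwhm <- as.numeric(utils::read.table(
    system.file("extdata", "fmo_disorder_fwhm.txt", package = "excitondyn"),
    comment.char = "#"))
  eps <- diag(H)
  Jc <- H - diag(eps)
  Jc <- (Jc + t(Jc)) / 2
  if (is.null(sd)) sd <- debye_spectral_density(45, 106)
  stopifnot(inherits(sd, "spectral_density"), all(fwhm >= 0), length(fwhm) == 8)
  structure(list(mean_epsilon = eps, coupling = Jc, fwhm = fwhm, sd = sd,
                 temperature = temperature),
            class = "fmo_model")
}

#' Sample one static-disorder realization of the FMO model
#'
#' Site energies are drawn as Gaussians around the published means with
#' standard deviations `fwhm / (2 sqrt(2 ln 2))`; couplings are unchanged.
#' Uses R's RNG.
#'
#' @param fmo An `fmo_model`.
#' @return A `frenkel_model` realization.
#' @export
sample_disorder <- function(fmo) {
  stopifnot(inherits(fmo, "fmo_model"))
  sigma <- fmo$fwhm * .fmo_fwhm_to_sigma
  eps <- stats::rnorm(length(fmo$mean_epsilon), fmo$mean_epsilon, sigma)
  frenkel_model(eps, fmo$coupling, fmo$sd, fmo$temperature)
}

#' Mean-energy FMO realization (no disorder)
#'
#' @param fmo An `fmo_model`.
#' @return The `frenkel_model` at the published mean site energies.
#' @export
fmo_mean_model <- function(fmo) {
  stopifnot(inherits(fmo, "fmo_model"))
  frenkel_model(fmo$mean_epsilon, fmo$coupling, fmo$sd, fmo$temperature)
}

#' Run an FMO transfer experiment
#'
#' Reproduces the two benchmark setups: population dynamics in the site
#' basis after excitation of a single site (MASH or Foerster hopping), and
#' in the exciton basis after excitation of a single exciton (MASH or
#' secular Redfield).  Static disorder is resampled per trajectory (MASH)
#' or averaged over `n_realizations` independent rate-matrix propagations
#' (rate theories); exciton observables use each realization's own
#' eigenbasis, labelled in order of increasing energy.
#'
#' @param fmo An `fmo_model`.
#' @param init_state Index of the initially excited site or exciton.
#' @param basis `"site"` or `"exciton"`.
#' @param method `"mash"`, `"forster"` (site init only) or
#'   `"redfield_secular"` (exciton init only).
#' @param scheme MASH initial-condition scheme (`"cap"`, `"focused"`,
#'   `"equivariant"`).
#' @param n_traj MASH trajectory count.
#' @param n_realizations Disorder realizations for the rate theories.
#' @param t_max Propagation time in ps.
#' @param dt MASH time step in ps (default 2.5e-4 ps = 0.25 fs).
#' @param seed Integer seed.
#' @param n_modes,omega_max Bath discretization for MASH (equally spaced
#'   grid, renormalized to the spectral density's reorganization energy).
#' @param disorder Logical; include static disorder.
#' @return A `population_trace`.
#' @export
run_fmo <- function(fmo, init_state = 1, basis = c("site", "exciton"),
                    method = c("mash", "forster", "redfield_secular"),
                    scheme = "cap", n_traj = 10000, n_realizations = 1000,
                    t_max = 1, dt = 2.5e-4, seed = 1,
                    n_modes = 100, omega_max = 500, disorder = TRUE) {
  stopifnot(inherits(fmo, "fmo_model"))
  basis <- match.arg(basis)
  method <- match.arg(method)
  if (method == "forster" && basis != "site")
    stop("Foerster propagation starts from a site excitation")
  if (method == "redfield_secular" && basis != "exciton")
    stop("secular Redfield propagation starts from an exciton excitation")
  N <- 8
  sigma <- if (disorder) fmo$fwhm * .fmo_fwhm_to_sigma else rep(0, N)

  if (method == "mash") {
    bath <- discretize_bath(fmo$sd, n_modes, "equal_grid", omega_max = omega_max,
                            renormalize = TRUE)
    return(run_ensemble(fmo_mean_model(fmo), bath, init_state = init_state,
                        scheme = scheme, basis = basis, n_traj = n_traj,
                        t_max = t_max, dt = dt, seed = seed,
                        disorder_sigma = if (disorder) sigma else NULL))
  }

  times <- seq(0, t_max, length.out = 201)
  nr <- if (disorder) n_realizations else 1L
  set.seed(seed)
  pop_site <- matrix(0, length(times), N)
  pop_exc <- matrix(0, length(times), N)
  kernel <- if (method == "forster") {
    # detuning range covering mean gaps +/- disorder tails and Stokes shift
    span <- max(abs(outer(fmo$mean_epsilon, fmo$mean_epsilon, "-"))) +
      8 * max(fmo$fwhm) * .fmo_fwhm_to_sigma + 2 * reorganization_energy(fmo$sd)
    .forster_kernel(fmo$sd, fmo$temperature, c(-span, span))
  }
  for (r in seq_len(nr)) {
    m <- if (disorder) sample_disorder(fmo) else fmo_mean_model(fmo)
    eb <- exciton_states(system_hamiltonian(m))
    if (method == "forster") {
      K <- .forster_matrix_from(m, kernel)
      p0 <- numeric(N); p0[init_state] <- 1
      tr <- propagate_kinetic(K, p0, times)
      ps <- tr$pop_site
      pop_site <- pop_site + ps
      pop_exc <- pop_exc + ps %*% eb$U^2          # p_mu = sum_n U_{n mu}^2 p_n
    } else {
      K <- secular_rates(m)
      p0 <- numeric(N); p0[init_state] <- 1
      tr <- propagate_kinetic(K, p0, times)
      pe <- tr$pop_exc
      pop_exc <- pop_exc + pe
      pop_site <- pop_site + pe %*% t(eb$U^2)     # p_n = sum_mu U_{n mu}^2 p_mu
    }
  }
  new_population_trace(times, pop_site / nr, pop_exc / nr,
                       n_traj = nr, method = method, seed = seed,
                       extra = list(n_realizations = nr))
}

#' @export
print.fmo_model <- function(x, ...) {
  cat(sprintf("FMO model: 8 sites, T = %g K, disorder FWHM %s cm^-1\n",
              x$temperature, paste(x$fwhm, collapse = "/")))
  print(x$sd)
  invisible(x)
}
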