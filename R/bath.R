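# Discretization of a continuous spectral density into M harmonic modes with
# unit masses, frequencies omega_j and linear couplings c_j, such that the
# discrete reorganization energy sum_j c_j^2/(2 omega_j^2) reproduces lambda.

#' Discretize a spectral density into harmonic bath modes
#'
#' Two schemes are provided.  `debye_tan` (Debye form only) places the nodes
#' at \eqn{\omega_j = \omega_c \tan(\pi (j - 1/2)/(2M))} with couplings
#' \eqn{c_j = \omega_j \sqrt{2\lambda/M}}, so each mode carries exactly
#' \eqn{\lambda/M} of reorganization energy for any M.  `equal_grid` uses a
#' uniform grid \eqn{\omega_j = (j - 1/2)\Delta\omega} up to `omega_max` with
#' \eqn{c_j = \sqrt{(2/\pi) J(\omega_j)\, \omega_j\, \Delta\omega}}; the grid
#' truncation loses part of the reorganization energy, which is restored by
#' rescaling the couplings when `renormalize = TRUE` (the default, so that
#' the discrete bath carries the reorganization energy of its parent).
#'
#' @param sd A `spectral_density`.
#' @param n_modes Number of modes M (>= 1).
#' @param scheme One of `"debye_tan"`, `"equal_grid"`.
#' @param omega_max Upper frequency cutoff in cm^-1 (required for
#'   `equal_grid`).
#' @param renormalize Logical; rescale `equal_grid` couplings so that the
#'   discrete reorganization energy equals `reorganization_energy(sd)`.
#' @return An object of class `discretized_bath` with fields `omega`,
#'   `coupling` (both cm^-1, unit masses), `lambda_raw` (before any
#'   rescaling) and `sd`.
#' @examples
#' b <- discretize_bath(debye_spectral_density(50, 53), 100)
#' sum(b$coupling^2 / (2 * b$omega^2))  # = 50
#' @export
discretize_bath <- function(sd, n_modes, scheme = c("debye_tan", "equal_grid"),
                            omega_max = NULL, renormalize = TRUE) {
  stopifnot(inherits(sd, "spectral_density"), n_modes >= 1)
  scheme <- match.arg(scheme)
  M <- as.integer(n_modes)
  if (scheme == "debye_tan") {
    if (sd$form != "debye") stop("'debye_tan' discretization requires a Debye spectral density")
    j <- seq_len(M)
    omega <- sd$omega_c * tan(pi * (j - 0.5) / (2 * M))
    coupling <- omega * sqrt(2 * sd$lambda / M)
    lambda_raw <- sd$lambda
  } else {
    if (is.null(omega_max)) stop("'equal_grid' requires 'omega_max'")
    if (omega_max <= 0) stop("'omega_max' must be positive")
    if (sd$form == "tabulated" && omega_max > max(sd$grid_omega))
      message("equal_grid extends beyond the tabulated support; J treated as 0 there")
    dw <- omega_max / M
    omega <- (seq_len(M) - 0.5) * dw
    coupling <- sqrt((2 / pi) * sd_eval(sd, omega) * omega * dw)
    lambda_raw <- sum(coupling^2 / (2 * omega^2))
    if (renormalize) {
      if (lambda_raw <= 0) stop("discretized bath carries no reorganization energy")
      coupling <- coupling * sqrt(sd$lambda / lambda_raw)
      frac <- 1 - lambda_raw / sd$lambda
      if (abs(frac) > 0.02)
        message(sprintf("equal_grid truncation lost %.1f%% of lambda; couplings rescaled", 100 * frac))
    }
  }
  structure(list(omega = omega, coupling = coupling, n_modes = M,
                 scheme = scheme, lambda_raw = lambda_raw, sd = sd),
            class = "discretized_bath")
}

#' Reorganization energy carried by a discretized bath
#'
#' @param bath A `discretized_bath`.
#' @return sum_j c_j^2 / (2 omega_j^2) in cm^-1.
#' @export
bath_lambda <- function(bath) {
  stopifnot(inherits(bath, "discretized_bath"))
  sum(bath$coupling^2 / (2 * bath$omega^2))
}

#' @export
print.discretized_bath <- function(x, ...) {
  cat(sprintf("Discretized bath: %d modes (%s), lambda = %g cm^-1, omega in [%.3g, %.3g] cm^-1\n",
              x$n_modes, x$scheme, bath_lambda(x), min(x$omega), max(x$omega)))
  invisible(x)
}
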