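# Spectral densities J(omega) of the harmonic environment.  Two forms are
# supported: the analytic Debye (overdamped Brownian) form and a tabulated
# curve read from a two-column text file.  By convention J(omega <= 0) = 0.

#' Debye spectral density
#'
#' Constructs the overdamped Debye spectral density
#' \deqn{J(\omega) = 2 \lambda \omega_c \omega / (\omega^2 + \omega_c^2)}
#' for \eqn{\omega > 0} and zero otherwise.  The reorganization energy
#' \eqn{\lambda = (1/\pi)\int_0^\infty J(\omega)/\omega \, d\omega} is exactly
#' the `lambda` parameter for this form.
#'
#' @param lambda Reorganization energy in cm^-1 (> 0).
#' @param omega_c Debye cutoff frequency in cm^-1 (> 0).
#' @return An object of class `spectral_density`.
#' @examples
#' sd <- debye_spectral_density(100, 53)
#' sd_eval(sd, 53)  # equals lambda at omega = omega_c
#' @export
debye_spectral_density <- function(lambda, omega_c) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(omega_c), length(omega_c) == 1L, is.finite(omega_c))
  if (lambda <= 0) stop("'lambda' must be positive")
  if (omega_c <= 0) stop("'omega_c' must be positive")
  structure(list(form = "debye", lambda = lambda, omega_c = omega_c),
            class = "spectral_density")
}

#' Tabulated spectral density
#'
#' Builds a spectral density from a grid of frequencies and values.  The
#' curve is linearly interpolated inside its grid and is zero outside and for
#' non-positive frequencies.  The reorganization energy is recomputed from
#' the grid by the trapezoid rule (it is not user-set).
#'
#' @param omega Ascending frequencies in cm^-1.
#' @param value Spectral density values in cm^-1, non-negative.
#' @return An object of class `spectral_density`.
#' @export
tabulated_spectral_density <- function(omega, value) {
  stopifnot(is.numeric(omega), is.numeric(value), length(omega) == length(value))
  if (length(omega) < 2L) stop("tabulated grid needs at least 2 points")
  if (is.unsorted(omega, strictly = TRUE)) stop("'omega' must be strictly ascending")
  if (any(value < 0)) stop("spectral density values must be non-negative")
  keep <- omega > 0
  if (sum(keep) < 2L) stop("tabulated grid needs at least 2 points with omega > 0")
  omega <- omega[keep]; value <- value[keep]
  sd <- structure(list(form = "tabulated", grid_omega = omega, grid_value = value),
                  class = "spectral_density")
  sd$lambda <- .trapz(omega, value / omega) / pi
  sd
}

#' Read a tabulated spectral density from a text file
#'
#' Expects two whitespace-separated columns (frequency in cm^-1, J in cm^-1)
#' with ascending frequency; lines starting with `#` are comments.
#'
#' @param path Path to the file.
#' @return An object of class `spectral_density`.
#' @export
read_spectral_density <- function(path) {
  tab <- utils::read.table(path, comment.char = "#", col.names = c("omega", "value"))
  tabulated_spectral_density(tab$omega, tab$value)
}

.trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Evaluate a spectral density
#'
#' @param sd A `spectral_density`.
#' @param omega Frequencies in cm^-1 (any sign; J is zero for omega <= 0).
#' @return J(omega) in cm^-1.
#' @export
sd_eval <- function(sd, omega) {
  stopifnot(inherits(sd, "spectral_density"))
  out <- numeric(length(omega))
  pos <- omega > 0
  if (sd$form == "debye") {
    w <- omega[pos]
    out[pos] <- 2 * sd$lambda * sd$omega_c * w / (w^2 + sd$omega_c^2)
  } else {
    out[pos] <- stats::approx(sd$grid_omega, sd$grid_value, xout = omega[pos],
                              yleft = 0, yright = 0, rule = 1)$y
    out[is.na(out)] <- 0
  }
  out
}

#' Reorganization energy of a spectral density
#'
#' Computes \eqn{\lambda = (1/\pi)\int_0^\infty J(\omega)/\omega\, d\omega}.
#' For the Debye form this returns the defining parameter exactly; for a
#' tabulated form the grid is integrated by the trapezoid rule.
#'
#' @param sd A `spectral_density`.
#' @return Reorganization energy in cm^-1.
#' @export
reorganization_energy <- function(sd) {
  stopifnot(inherits(sd, "spectral_density"))
  sd$lambda
}

# Upper integration limit capturing all but ~1e-8 of integrals weighted by
# J(w)/w (Debye tail ~ 2*lambda*omega_c/w^2).
.sd_support <- function(sd) {
  if (sd$form == "debye") 2000 * sd$omega_c else max(sd$grid_omega)
}

#' @export
print.spectral_density <- function(x, ...) {
  if (x$form == "debye") {
    cat(sprintf("Debye spectral density: lambda = %g cm^-1, omega_c = %g cm^-1\n",
                x$lambda, x$omega_c))
  } else {
    cat(sprintf("Tabulated spectral density: %d points on [%g, %g] cm^-1, lambda = %g cm^-1\n",
                length(x$grid_omega), min(x$grid_omega), max(x$grid_omega), x$lambda))
  }
  invisible(x)
}
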