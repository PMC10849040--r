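# Bath correlation function C(t), its half-Fourier transform C~(omega), and
# the cumulant lineshape exponent g(t).  C(t) is in cm^-2, C~(omega) in
# cm^-1, g(t) dimensionless; every time-dependent phase carries the cm^-1 to
# rad/ps conversion factor.

#' Bath correlation object
#'
#' Bundles a spectral density with an inverse temperature so that the
#' correlation function \eqn{C(t)}, its half-Fourier transform
#' \eqn{\tilde C(\omega)} and the lineshape exponent \eqn{g(t)} can be
#' evaluated.
#'
#' @param sd A `spectral_density`.
#' @param temperature Temperature in kelvin.
#' @return An object of class `bath_correlation`.
#' @export
bath_correlation <- function(sd, temperature) {
  stopifnot(inherits(sd, "spectral_density"))
  structure(list(sd = sd, beta = beta_cm1(temperature), temperature = temperature),
            class = "bath_correlation")
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch on the Jacobi
# matrix); the [-1, 1] base rule is cached per order since the eigensolve is
# the expensive part.
.gl_cache <- new.env(parent = emptyenv())

.gauss_legendre <- function(n, a = -1, b = 1) {
  key <- as.character(n)
  base <- .gl_cache[[key]]
  if (is.null(base)) {
    i <- seq_len(n - 1)
    off <- i / sqrt(4 * i^2 - 1)
    Jm <- matrix(0, n, n)
    Jm[cbind(i, i + 1)] <- off
    Jm[cbind(i + 1, i)] <- off
    e <- eigen(Jm, symmetric = TRUE)
    base <- list(x = e$values, w = 2 * e$vectors[1, ]^2)
    .gl_cache[[key]] <- base
  }
  list(x = (b - a) / 2 * base$x + (a + b) / 2, w = (b - a) / 2 * base$w)
}

# composite Gauss-Legendre rule: n_panel panels of order n_nodes each
.gl_composite <- function(a, b, n_panels = 40, n_nodes = 100) {
  edges <- seq(a, b, length.out = n_panels + 1)
  xs <- ws <- NULL
  for (k in seq_len(n_panels)) {
    g <- .gauss_legendre(n_nodes, edges[k], edges[k + 1])
    xs <- c(xs, g$x); ws <- c(ws, g$w)
  }
  list(x = xs, w = ws)
}

# Fixed composite quadrature rule over the support of J, denser near 0 where
# coth(beta w/2) peaks. Returns nodes and weights.
.bc_rule <- function(sd, n_per_panel = 160) {
  hi <- .sd_support(sd)
  scale <- if (sd$form == "debye") sd$omega_c else max(sd$grid_omega) / 20
  edges <- unique(sort(c(0, scale * c(0.1, 1, 4, 20, 100), hi)))
  edges <- edges[edges <= hi]
  if (edges[length(edges)] < hi) edges <- c(edges, hi)
  xs <- ws <- NULL
  for (k in seq_len(length(edges) - 1)) {
    g <- .gauss_legendre(n_per_panel, edges[k], edges[k + 1])
    xs <- c(xs, g$x); ws <- c(ws, g$w)
  }
  list(x = xs, w = ws)
}

.coth <- function(x) 1 / tanh(x)

#' Bath correlation function C(t)
#'
#' \deqn{C(t) = \frac{1}{\pi}\int_0^\infty d\omega\, J(\omega)
#'   [\coth(\beta\omega/2)\cos\omega t - i \sin\omega t]}
#' evaluated by quadrature.  Stationarity gives `C(-t) = Conj(C(t))`.
#'
#' @param bc A `bath_correlation`.
#' @param t Times in ps (vectorized, any sign).
#' @return Complex vector in cm^-2.
#' @export
corr_time <- function(bc, t) {
  stopifnot(inherits(bc, "bath_correlation"))
  r <- .bc_rule(bc$sd)
  J <- sd_eval(bc$sd, r$x)
  cothv <- .coth(bc$beta * r$x / 2)
  phases <- outer(r$x, .kappa * abs(t))          # |omega| x |t|
  re <- as.numeric(crossprod(J * cothv * r$w, cos(phases))) / pi
  im <- -as.numeric(crossprod(J * r$w, sin(phases))) / pi
  out <- complex(real = re, imaginary = im)
  ifelse(t < 0, Conj(out), out)
}

#' Half-Fourier transform of the bath correlation function
#'
#' Returns \eqn{\tilde C(\omega) = \int_0^\infty C(t) e^{i\omega t} dt}
#' expressed in cm^-1 (divide through by the rad/ps conversion).  The real
#' part uses the closed form
#' \eqn{\mathrm{Re}\,\tilde C(\omega) = J(\omega)(1 + n(\omega)) +
#' J(-\omega) n(-\omega)} with the Bose-Einstein distribution
#' \eqn{n(\omega)}; the imaginary (Lamb-shift-like) part is computed by a
#' principal-value integral over the real part and can be skipped with
#' `imaginary = FALSE`.
#'
#' @param bc A `bath_correlation`.
#' @param omega Frequencies in cm^-1 (vectorized, any sign including 0).
#' @param imaginary Logical; compute the principal-value imaginary part.
#' @return Complex vector in cm^-1.
#' @export
corr_spectrum <- function(bc, omega, imaginary = TRUE) {
  stopifnot(inherits(bc, "bath_correlation"))
  re <- .corr_spectrum_re(bc, omega)
  if (!imaginary) return(complex(real = re, imaginary = 0))
  complex(real = re, imaginary = .corr_spectrum_im(bc, omega))
}

# Re C~(omega); the omega -> 0 limit J(omega) n(omega) -> J'(0)/beta is taken
# by evaluating at a tiny positive frequency.
.corr_spectrum_re <- function(bc, omega) {
  scale <- .sd_scale(bc$sd)
  w <- ifelse(abs(omega) < 1e-9 * scale, 1e-9 * scale, omega)
  nb <- function(x) 1 / expm1(bc$beta * x)   # x > 0
  vapply(w, function(wi) {
    if (wi > 0) sd_eval(bc$sd, wi) * (1 + nb(wi))
    else sd_eval(bc$sd, -wi) * nb(-wi)
  }, numeric(1))
}

.sd_scale <- function(sd) if (sd$form == "debye") sd$omega_c else max(sd$grid_omega)

# Im C~(omega) = (1/pi) P int Re C~(w') / (omega - w') dw', regularized by
# subtracting the singular value on a finite symmetric window.  The panel
# edges are geometrically graded around zero (where J peaks) and refined
# near the singular point.
.corr_spectrum_im <- function(bc, omega) {
  scale <- .sd_scale(bc$sd)
  hi <- .sd_support(bc$sd)
  vapply(omega, function(w0) {
    W <- max(hi, 4 * abs(w0) + scale)
    grade <- scale * 2^seq(-2, ceiling(log2(W / scale)))
    edges <- sort(unique(pmin(pmax(c(-W, -rev(grade), 0, grade, W,
                                     w0 + scale * c(-1, -0.1, 0.1, 1)),
                                   -W), W)))
    xs <- ws <- NULL
    for (k in seq_len(length(edges) - 1)) {
      if (edges[k + 1] - edges[k] < 1e-12) next
      g <- .gauss_legendre(60, edges[k], edges[k + 1])
      xs <- c(xs, g$x); ws <- c(ws, g$w)
    }
    f <- .corr_spectrum_re(bc, xs)
    f0 <- .corr_spectrum_re(bc, w0)
    d <- w0 - xs
    reg <- ifelse(abs(d) < 1e-12, 0, (f - f0) / d)
    (sum(reg * ws) + f0 * log(abs((W + w0) / (W - w0)))) / pi
  }, numeric(1))
}

#' Cumulant lineshape exponent g(t)
#'
#' The double time integral of the bath correlation function, evaluated in
#' its frequency form
#' \deqn{g(t) = \frac{1}{\pi}\int_0^\infty \frac{J(\omega)}{\omega^2}
#'  \left[\coth(\beta\omega/2)(1-\cos\omega t) + i(\sin\omega t - \omega t)
#'  \right] d\omega.}
#' `g(0) = 0`, the real part is non-decreasing, and the imaginary part
#' approaches the Stokes-shift asymptote `Im g(t) -> -lambda * (kappa t)`
#' where kappa converts cm^-1 to rad/ps.
#'
#' @param bc A `bath_correlation`.
#' @param t Times in ps (vectorized, >= 0).
#' @return Complex dimensionless vector.
#' @export
lineshape_g <- function(bc, t) {
  stopifnot(inherits(bc, "bath_correlation"), all(t >= 0))
  r <- .bc_rule(bc$sd)
  J <- sd_eval(bc$sd, r$x)
  cothv <- .coth(bc$beta * r$x / 2)
  base <- J / r$x^2 * r$w
  ph <- outer(r$x, .kappa * t)
  re <- as.numeric(crossprod(base * cothv, 1 - cos(ph))) / pi
  im <- as.numeric(crossprod(base, sin(ph) - ph)) / pi
  complex(real = re, imaginary = im)
}
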