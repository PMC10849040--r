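# Rate extraction: fit the population difference sigma_z(t) = P_1 - P_2 to a
# single exponential with the equilibrium value supplied externally, then
# split the total rate into forward/backward parts by detailed balance.

#' Fit the total transfer rate of a two-state trace
#'
#' Fits \deqn{\sigma_z(t) = (\sigma_z(0) - \sigma_z^{eq}) e^{-k_{tot} t} +
#' \sigma_z^{eq}} by nonlinear least squares in the single parameter
#' \eqn{k_{tot}}.  The equilibrium value is supplied externally (the MASH
#' equilibrium oracle, or the stationary state of a rate matrix), which is
#' more stable than a two-parameter fit.  The fit window starts at `t0`
#' (default 50 fs, excluding the initial coherent transient) and
#' \eqn{\sigma_z(0)} is pinned to the first trace point.  When the trace
#' carries batch means, `k_tot_stderr` is estimated by bootstrap over
#' batches.
#'
#' @param trace A `population_trace` (two states, or use `states`).
#' @param sigma_z_eq Equilibrium value of P_1 - P_2.
#' @param states Pair of state indices forming sigma_z (default 1, 2).
#' @param basis `"site"` or `"exciton"`.
#' @param t0 Fit-window start in ps.
#' @param n_boot Bootstrap resamples for the stderr (when batches exist).
#' @return An object of class `rate_result` with `k_tot`, `k_forward`,
#'   `k_backward`, `sigma_z_eq`, `fit_rms_residual`, `k_tot_stderr`.
#' @export
fit_k_tot <- function(trace, sigma_z_eq, states = c(1, 2),
                      basis = c("site", "exciton"), t0 = 0.05, n_boot = 100) {
  stopifnot(inherits(trace, "population_trace"))
  basis <- match.arg(basis)
  sz <- trace_sigma_z(trace, states, basis)
  k_hat <- .fit_single_k(trace$time, sz, sigma_z_eq, t0)
  win <- trace$time >= t0
  resid <- sz[win] - ((sz[1] - sigma_z_eq) * exp(-k_hat * trace$time[win]) + sigma_z_eq)
  k_se <- NA_real_
  batches <- if (basis == "site") trace$batch_site else trace$batch_exc
  if (!is.null(batches)) {
    nb <- dim(batches)[3]
    ks <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nb, nb, replace = TRUE)
      m <- apply(batches[, , idx, drop = FALSE], c(1, 2), mean)
      .fit_single_k(trace$time, m[, states[1]] - m[, states[2]], sigma_z_eq, t0)
    }, numeric(1))
    k_se <- stats::sd(ks)
  }
  structure(list(k_tot = k_hat,
                 k_forward = split_rates(k_hat, (1 - sigma_z_eq) / 2)$k_forward,
                 k_backward = split_rates(k_hat, (1 - sigma_z_eq) / 2)$k_backward,
                 sigma_z_eq = sigma_z_eq,
                 fit_rms_residual = sqrt(mean(resid^2)),
                 k_tot_stderr = k_se),
            class = "rate_result")
}

.fit_single_k <- function(time, sz, sigma_z_eq, t0) {
  amp <- sz[1] - sigma_z_eq
  win <- time >= t0
  if (sum(win) < 3) stop("fit window contains fewer than 3 points")
  tt <- time[win]; yy <- sz[win]
  if (abs(amp) < 1e-12) stop("trace starts at equilibrium; rate undefined")
  # non-decaying guard: the tail must have moved toward equilibrium
  tail_dev <- mean(abs(yy[tt >= stats::quantile(tt, 0.8)] - sigma_z_eq))
  if (tail_dev >= abs(amp)) stop("non-decaying trace: fitted rate would be <= 0")
  obj <- function(logk) {
    k <- exp(logk)
    sum((yy - (amp * exp(-k * tt) + sigma_z_eq))^2)
  }
  opt <- stats::optimize(obj, c(log(1e-5), log(1e4)), tol = 1e-12)
  k <- exp(opt$minimum)
  if (k <= 1.05e-5) stop("non-decaying trace: fitted rate at lower bound")
  k
}

#' Split a total rate into forward and backward parts
#'
#' By detailed balance the forward/backward rates of a two-state kinetic
#' scheme satisfy \eqn{k_{1\to2}/k_{2\to1} = P_2^{eq}/P_1^{eq}}, hence
#' \eqn{k_{1\to2} = k_{tot} P_2^{eq}} and \eqn{k_{2\to1} = k_{tot}
#' (1 - P_2^{eq})}.
#'
#' @param k_tot Total rate (sum of forward and backward), ps^-1.
#' @param p2_eq Equilibrium population of the acceptor state, in (0, 1).
#' @return List with `k_forward` and `k_backward`.
#' @export
split_rates <- function(k_tot, p2_eq) {
  if (!is.numeric(p2_eq) || p2_eq <= 0 || p2_eq >= 1)
    stop("'p2_eq' must lie strictly inside (0, 1)")
  list(k_forward = k_tot * p2_eq, k_backward = k_tot * (1 - p2_eq))
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("k_tot = %.5g ps^-1 (stderr %.2g), k_forward = %.5g, k_backward = %.5g\n",
              x$k_tot, x$k_tot_stderr, x$k_forward, x$k_backward))
  cat(sprintf("sigma_z_eq = %.5g, fit rms residual = %.3g\n",
              x$sigma_z_eq, x$fit_rms_residual))
  invisible(x)
}

#' Serialize a rate result as JSON
#'
#' @param x A `rate_result`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @export
rate_result_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "rate_result"))
  j <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(path)
}
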