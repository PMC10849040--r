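# PopulationTrace container: ensemble- or realization-averaged populations
# versus time, optionally with standard errors and per-batch means for
# bootstrap resampling.

new_population_trace <- function(time, pop_site = NULL, pop_exc = NULL,
                                 se_site = NULL, se_exc = NULL,
                                 n_traj = NA_integer_, method = NA_character_,
                                 scheme = NA_character_, seed = NA_integer_,
                                 batch_site = NULL, batch_exc = NULL,
                                 extra = list()) {
  structure(list(time = time, pop_site = pop_site, pop_exc = pop_exc,
                 se_site = se_site, se_exc = se_exc, n_traj = n_traj,
                 method = method, scheme = scheme, seed = seed,
                 batch_site = batch_site, batch_exc = batch_exc,
                 extra = extra),
            class = "population_trace")
}

#' Extract populations from a trace
#'
#' @param trace A `population_trace`.
#' @param basis `"site"` or `"exciton"`.
#' @return Matrix (times x states) of populations.
#' @export
trace_populations <- function(trace, basis = c("site", "exciton")) {
  stopifnot(inherits(trace, "population_trace"))
  basis <- match.arg(basis)
  p <- if (basis == "site") trace$pop_site else trace$pop_exc
  if (is.null(p)) stop("trace has no ", basis, "-basis populations")
  p
}

#' Population difference P_a(t) - P_b(t)
#'
#' @param trace A `population_trace`.
#' @param states Pair of state indices (default 1, 2).
#' @param basis `"site"` or `"exciton"`.
#' @return Numeric vector over the trace times.
#' @export
trace_sigma_z <- function(trace, states = c(1, 2), basis = c("site", "exciton")) {
  p <- trace_populations(trace, match.arg(basis))
  p[, states[1]] - p[, states[2]]
}

#' @export
print.population_trace <- function(x, ...) {
  n <- if (!is.null(x$pop_site)) ncol(x$pop_site) else ncol(x$pop_exc)
  cat(sprintf("Population trace: %d states, %d times on [%g, %g] ps (%s%s)\n",
              n, length(x$time), min(x$time), max(x$time), x$method,
              if (!is.na(x$scheme)) paste0(", ", x$scheme) else ""))
  if (!is.na(x$n_traj)) cat(sprintf("  averaged over %d trajectories\n", x$n_traj))
  invisible(x)
}

#' @export
as.data.frame.population_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- data.frame(time = x$time)
  if (!is.null(x$pop_site)) {
    colnames_site <- paste0("site", seq_len(ncol(x$pop_site)))
    out <- cbind(out, stats::setNames(as.data.frame(x$pop_site), colnames_site))
    if (!is.null(x$se_site))
      out <- cbind(out, stats::setNames(as.data.frame(x$se_site), paste0("se_", colnames_site)))
  }
  if (!is.null(x$pop_exc)) {
    cn <- paste0("exciton", seq_len(ncol(x$pop_exc)))
    out <- cbind(out, stats::setNames(as.data.frame(x$pop_exc), cn))
    if (!is.null(x$se_exc))
      out <- cbind(out, stats::setNames(as.data.frame(x$se_exc), paste0("se_", cn)))
  }
  out
}

#' Write a population trace as CSV
#'
#' Columns: time, per-state means, per-state standard errors (when
#' available), plus `n_traj`, `scheme` and `seed` metadata columns.
#'
#' @param trace A `population_trace`.
#' @param path Output file path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$n_traj <- trace$n_traj
  df$scheme <- trace$scheme
  df$seed <- trace$seed
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
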