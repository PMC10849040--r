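# Frenkel-exciton models: N localized pigment excitations (sites) with
# energies eps_n and couplings J_nm, each site coupled linearly to an
# identical, independent harmonic bath specified by one spectral density.

#' Construct a Frenkel-exciton model
#'
#' @param epsilon Site energies in cm^-1 (length N).
#' @param J_coupling Symmetric N x N coupling matrix in cm^-1 with zero
#'   diagonal.
#' @param sd A `spectral_density` shared by all sites.
#' @param temperature Temperature in kelvin.
#' @return An object of class `frenkel_model` with fields `n_sites`,
#'   `epsilon`, `J_coupling`, `sd`, `temperature` and `beta` (1/cm^-1).
#' @examples
#' m <- frenkel_model(c(100, 0), matrix(c(0, 20, 20, 0), 2),
#'                    debye_spectral_density(50, 53), 300)
#' system_hamiltonian(m)
#' @export
frenkel_model <- function(epsilon, J_coupling, sd, temperature) {
  stopifnot(is.numeric(epsilon), length(epsilon) >= 1L,
            is.matrix(J_coupling), inherits(sd, "spectral_density"),
            is.numeric(temperature), temperature > 0)
  n <- length(epsilon)
  if (!all(dim(J_coupling) == c(n, n)))
    stop("'J_coupling' must be an N x N matrix matching length(epsilon)")
  if (max(abs(J_coupling - t(J_coupling))) > 1e-10)
    stop("'J_coupling' must be symmetric")
  if (any(diag(J_coupling) != 0))
    stop("'J_coupling' must have zero diagonal")
  structure(list(n_sites = n, epsilon = as.numeric(epsilon),
                 J_coupling = unname(J_coupling), sd = sd,
                 temperature = temperature, beta = beta_cm1(temperature)),
            class = "frenkel_model")
}

#' System Hamiltonian in the site basis
#'
#' @param model A `frenkel_model`.
#' @return Symmetric N x N matrix in cm^-1.
#' @export
system_hamiltonian <- function(model) {
  stopifnot(inherits(model, "frenkel_model"))
  diag(model$epsilon, model$n_sites) + model$J_coupling
}

#' Two-site exciton dimer with a Debye bath
#'
#' Builds the standard dimer benchmark: site energies `(delta_eps, 0)`,
#' symmetric coupling `J12`, each site coupled to an identical independent
#' Debye bath.  Defaults reproduce the well-studied two-site model
#' (site-energy gap 100 cm^-1, J12 = 20 cm^-1, omega_c = 53 cm^-1, 300 K);
#' the bath reorganization energy `lambda` is the scan parameter.
#'
#' @param lambda Bath reorganization energy in cm^-1.
#' @param delta_eps Site-energy gap eps_1 - eps_2 in cm^-1 (any sign).
#' @param J12 Inter-site coupling in cm^-1.
#' @param omega_c Debye cutoff in cm^-1.
#' @param temperature Temperature in kelvin.
#' @return A `frenkel_model` with 2 sites.
#' @examples
#' d <- build_dimer_model(lambda = 100)
#' eigen(system_hamiltonian(d))$values
#' @export
build_dimer_model <- function(lambda, delta_eps = 100, J12 = 20, omega_c = 53,
                              temperature = 300) {
  frenkel_model(c(delta_eps, 0),
                matrix(c(0, J12, J12, 0), 2, 2),
                debye_spectral_density(lambda, omega_c),
                temperature)
}

#' Map a dimer onto spin-boson parameters
#'
#' Two identical independent site baths combine into a single collective
#' bath coupled to the relative (sigma_z/2) coordinate, with twice the
#' per-site reorganization energy.
#'
#' @param model A 2-site `frenkel_model`.
#' @return A list with `bias` (eps_1 - eps_2, cm^-1), `tunneling` (J12,
#'   cm^-1), and `sd` (the effective collective-bath `spectral_density`,
#'   reorganization energy 2 lambda).
#' @export
dimer_to_spin_boson <- function(model) {
  stopifnot(inherits(model, "frenkel_model"))
  if (model$n_sites != 2) stop("spin-boson mapping requires a 2-site model")
  sd <- model$sd
  sd2 <- if (sd$form == "debye") {
    debye_spectral_density(2 * sd$lambda, sd$omega_c)
  } else {
    tabulated_spectral_density(sd$grid_omega, 2 * sd$grid_value)
  }
  list(bias = model$epsilon[1] - model$epsilon[2],
       tunneling = model$J_coupling[1, 2],
       sd = sd2)
}

#' Read a Frenkel-exciton model from a plain-text config file
#'
#' Key-value format, one key per line (`key: value`), `#` comments allowed.
#' Keys: `sites` (N), `epsilon` (N numbers), `coupling` (N rows of N numbers,
#' given as `coupling1` ... `couplingN` or a single `coupling` line for N=2
#' off-diagonal value), `bath` (`debye` or path of a tabulated file),
#' `lambda`, `omega_c` (debye only), `temperature`.
#'
#' @param path Path to the config file.
#' @return A `frenkel_model`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    kv[[m[2]]] <- m[3]
  }
  need <- function(key) {
    if (is.null(kv[[key]])) stop("config is missing key '", key, "'")
    kv[[key]]
  }
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  n <- as.integer(need("sites"))
  eps <- nums(need("epsilon"))
  if (length(eps) != n) stop("'epsilon' must list ", n, " energies")
  Jc <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- kv[[paste0("coupling", i)]]
    if (is.null(row)) stop("config is missing key 'coupling", i, "'")
    v <- nums(row)
    if (length(v) != n) stop("'coupling", i, "' must list ", n, " values")
    Jc[i, ] <- v
  }
  diag(Jc) <- 0
  Jc <- (Jc + t(Jc)) / 2
  bath <- need("bath")
  sd <- if (identical(bath, "debye")) {
    debye_spectral_density(as.numeric(need("lambda")), as.numeric(need("omega_c")))
  } else {
    bp <- if (file.exists(bath)) bath else file.path(dirname(path), bath)
    read_spectral_density(bp)
  }
  frenkel_model(eps, Jc, sd, as.numeric(need("temperature")))
}

#' @export
print.frenkel_model <- function(x, ...) {
  cat(sprintf("Frenkel-exciton model: %d sites, T = %g K\n", x$n_sites, x$temperature))
  cat("Site energies (cm^-1): ", paste(signif(x$epsilon, 6), collapse = " "), "\n")
  print(x$sd)
  invisible(x)
}
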