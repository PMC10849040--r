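# Shared fixtures: all built in code, nothing read from disk.

kap <- excitondyn::exciton_units$cm1_to_radps
kB <- excitondyn::exciton_units$kB_cm1

dimer <- function(lambda = 20, ...) build_dimer_model(lambda, ...)

dimer_bath <- function(model, n_modes = 100) discretize_bath(model$sd, n_modes)

# 3-site toy Frenkel model for multi-state checks
toy3 <- function(lambda = 30, temperature = 300) {
  Jc <- matrix(0, 3, 3)
  Jc[1, 2] <- Jc[2, 1] <- 50
  Jc[2, 3] <- Jc[3, 2] <- 30
  Jc[1, 3] <- Jc[3, 1] <- 5
  frenkel_model(c(200, 100, 0), Jc, debye_spectral_density(lambda, 53), temperature)
}

# classical Marcus golden-rule rate in ps^-1 (energies cm^-1)
marcus_rate <- function(J, delta_eps, lambda_tot, temperature) {
  beta <- 1 / (kB * temperature)
  kap * J^2 * sqrt(pi * beta / lambda_tot) *
    exp(-beta * (delta_eps - lambda_tot)^2 / (4 * lambda_tot))
}
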