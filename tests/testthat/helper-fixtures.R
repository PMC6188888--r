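# Fixtures are generated in code; nothing is read from disk.

# small random symmetric positive-definite matrix
random_spd <- function(n, scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(stats::rnorm(n * n), n, n)
  scale * (G %*% t(G) + n * diag(n) / 2)
}

# small two-area von Mises population
two_area_pop <- function(n_per_area = 24, seed = 11) {
  params <- tuning_params(2 * n_per_area)
  build_population(params, seed = seed,
                   area = rep(c("M", "V"), each = n_per_area))
}

# stack a population with itself (neuron duplication)
duplicate_pop <- function(pop, times = 2L) {
  out <- pop
  for (f in c("area", "b", "h", "kappa", "pref", "f0", "deriv", "sigma2"))
    out[[f]] <- rep(pop[[f]], times)
  out$n <- pop$n * times
  out
}

# forward-generate a noiseless inactivation design from known (a, E)
forward_design <- function(a, E, rho) {
  th <- apply(rho, 1, function(r) coarse_threshold(a, E, r))
  beta <- t(apply(rho, 1, function(r) coarse_cc_slopes(a, E, r)))
  colnames(beta) <- colnames(rho)
  inactivation_design(rho, th, beta)
}

rho_grid_2 <- function() {
  m <- rbind(c(1, 1), c(1, 0), c(0, 1), c(1, 0.5), c(0.5, 1))
  colnames(m) <- c("x", "y")
  m
}
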