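test_that("coarse thresholds follow the quadratic form with renormalisation", {
  E <- matrix(c(15, 0, 0, 45), 2, 2)
  expect_equal(coarse_threshold(c(1, 0), E), sqrt(15))
  expect_equal(coarse_threshold(c(0.5, 0.5), E), sqrt(15), tolerance = 1e-12)
  # full inactivation of one area leaves the other's noise magnitude
  expect_equal(coarse_threshold(c(0.7, 0.3), E, rho = c(0, 1)), sqrt(45))
  expect_equal(coarse_threshold(c(0.7, 0.3), E, rho = c(1, 0)), sqrt(15))
  # intact retention changes nothing
  a <- c(0.6, 0.4)
  Ec <- matrix(c(5, 2, 2, 8), 2, 2)
  expect_equal(coarse_threshold(a, Ec, rho = 1), coarse_threshold(a, Ec))
  expect_error(coarse_threshold(c(1, -1), Ec, rho = c(1, 1)),
               "inactivated")
})

test_that("coarse slopes equal one at the optimal scaling", {
  for (seed in 1:10) {
    E <- random_spd(3, seed = seed)
    a <- optimal_scalings(E)
    expect_equal(unname(coarse_cc_slopes(a, E)), rep(1, 3),
                 tolerance = 1e-10)
  }
  # single population: slope is identically one
  expect_equal(unname(coarse_cc_slopes(1, matrix(4))), 1)
})

test_that("two-population ratio reproduces the printed-parameter arithmetic", {
  # optimal case: squared threshold ratio alone
  expect_equal(two_population_ratio(1, 1, theta_minus_x = 2,
                                    theta_minus_y = 1), 4)
  # exact variant on the extensive-model noise magnitudes
  expect_equal(two_population_ratio(1, 1, eps_xx = 15, eps_yy = 45), 3)
  # correlated-area form on the limited-model parameters
  r <- two_population_ratio(1.1, 2.4, eps_xx = 5, eps_yy = 38,
                            gamma = 10 / 5)
  expect_equal(r, ((1.1 / 2.4) * 38 / 5 - 2) / (1 - (1.1 / 2.4) * 2),
               tolerance = 1e-12)
  expect_gt(r, 14 - 7); expect_lt(r, 14 + 7)
  # exact variant takes precedence over thresholds when both given
  expect_equal(two_population_ratio(1, 1, theta_minus_x = 100,
                                    theta_minus_y = 1,
                                    eps_xx = 15, eps_yy = 45), 3)
  expect_error(two_population_ratio(1, 2, eps_xx = 1, eps_yy = 1,
                                    gamma = 2), "singular")
})

test_that("solver round-trips a two-population ground truth", {
  a <- c(x = 0.7, y = 0.3)
  E <- matrix(c(5, 10, 10, 38), 2, 2)
  des <- forward_design(a, E, rho_grid_2())
  fit <- fit_decoder_scaling(des, n_starts = 8, seed = 3)
  expect_equal(unname(fit$a), unname(a), tolerance = 1e-4)
  expect_equal(unname(fit$E$E), E, tolerance = 1e-4)
  expect_lt(fit$residual_norm, 1e-6)
})

test_that("solver round-trips six correlated populations", {
  rec <- cmd_recover(n_areas = 6, n_experiments = 14, seed = 5,
                     n_starts = 8)
  expect_lt(rec$rel_err_a, 1e-3)
  expect_lt(rec$rel_err_E, 1e-3)
})

test_that("single area solves in closed form and shortages error out", {
  des1 <- inactivation_design(matrix(1, 2, 1,
                                     dimnames = list(NULL, "only")),
                              threshold = c(2, 2))
  fit1 <- fit_decoder_scaling(des1)
  expect_equal(unname(fit1$a), 1)
  expect_equal(drop(fit1$E$E), 4)
  des2 <- inactivation_design(rbind(c(1, 1), c(1, 0)), c(2, 3))
  expect_error(fit_decoder_scaling(des2), "under-determined")
})

test_that("recovery degrades gracefully under observation noise", {
  a <- c(x = 0.7, y = 0.3)
  E <- matrix(c(5, 10, 10, 38), 2, 2)
  rho <- rho_grid_2()
  errs <- vapply(1:50, function(rep) {
    set.seed(1000 + rep)
    th <- apply(rho, 1, function(r) coarse_threshold(a, E, r)) *
      (1 + stats::rnorm(nrow(rho), sd = 0.05))
    beta <- t(apply(rho, 1, function(r) coarse_cc_slopes(a, E, r))) *
      (1 + stats::rnorm(2 * nrow(rho), sd = 0.05))
    colnames(beta) <- colnames(rho)
    des <- inactivation_design(rho, th, beta)
    fit <- fit_decoder_scaling(des, n_starts = 4, seed = rep)
    max(abs(fit$a - a)) / max(abs(a))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)
})

test_that("threshold along the scaling simplex is U-shaped", {
  E <- matrix(c(15, 0, 0, 45), 2, 2)  # extensive-model magnitudes
  a_grid <- seq(0.02, 0.98, length.out = 97)
  th <- vapply(a_grid, function(t) coarse_threshold(c(t, 1 - t), E),
               numeric(1))
  d2 <- diff(diff(th))
  expect_true(all(d2 > -1e-10))              # convex
  a_opt <- optimal_scalings(E)[1]
  expect_equal(unname(a_opt), 45 / 60, tolerance = 1e-12)
  i_min <- which.min(th)
  expect_lt(abs(a_grid[i_min] - a_opt), 0.02)
  # inferred scaling (|a_M/a_V| = 0.8) and the VIP-inactivation endpoint
  # (a_M = 1) straddle the optimum
  a_inf <- 0.8 / 1.8
  expect_lt(a_inf, a_opt)
  expect_gt(1, a_opt)
})

test_that("CC rescaling under inactivation matches recomputed correlations", {
  # coarse level: the post-inactivation CC of area x (slope times the new
  # threshold ratio) is zeta_x times the intact CC, exactly
  for (seed in 1:10) {
    E <- random_spd(2, seed = 30 + seed)
    set.seed(seed)
    a <- stats::runif(2, 0.2, 1); a <- a / sum(a)
    th <- coarse_threshold(a, E)
    beta <- coarse_cc_slopes(a, E)
    th_after <- coarse_threshold(a, E, rho = c(1, 0))
    beta_after <- coarse_cc_slopes(a, E, rho = c(1, 0))[1]
    zeta_x <- predict_cc_scaling(beta[1], th, th_after)
    # per-unit-sensitivity CC: beta * theta; ratio after/before = zeta
    expect_equal(beta_after * th_after, zeta_x * beta[1] * th,
                 tolerance = 1e-10)
  }
  # fine level: silencing one area of a block-correlated population
  # rescales every remaining neuron's CC by the same zeta
  pop <- two_area_pop(12, seed = 41)
  cv <- extensive_covariance(pop, c(M = 0.3, V = 0.5), k = 0)
  cg <- coarse_grain_extensive(cv, pop)
  a <- c(M = 0.6, V = 0.4)
  cc_before <- choice_correlations(mode_decoder(cg, pop, a), cv)
  cc_after <- choice_correlations(mode_decoder(cg, pop, c(M = 1, V = 0)),
                                  cv)
  th <- coarse_threshold(a, cg$E)
  th_minus_V <- coarse_threshold(a, cg$E, rho = c(1, 0))
  beta <- coarse_cc_slopes(a, cg$E)
  zeta_M <- predict_cc_scaling(beta[1], th, th_minus_V)
  iM <- pop$area == "M"
  expect_equal(cc_after[iM], zeta_M * cc_before[iM], tolerance = 1e-8)
  # inactivating an irrelevant optimally-read area changes nothing
  expect_equal(predict_cc_scaling(1, 2, 2), 1)
  expect_equal(predict_cc_scaling(1, 2, 4), 2)
})

test_that("decoding efficiency is the squared threshold ratio", {
  expect_equal(decoding_efficiency(2, 2), 1)
  expect_equal(decoding_efficiency(1.98, 2.2), 1.98^2 / 2.2^2)
  expect_warning(decoding_efficiency(3, 2), "exceeds")
})

test_that("efficiency of subspace decoding falls off inversely with N", {
  sizes <- c(128, 256, 512, 1024)
  eta <- vapply(sizes, function(n) {
    pop <- build_population(tuning_params(n), seed = 2)
    cv <- extensive_covariance(pop, 0.2)
    th_opt <- estimator_threshold(optimal_weights(cv, pop$deriv), cv)
    th_sub <- estimator_threshold(subspace_weights(cv, pop$deriv, 2), cv)
    decoding_efficiency(th_opt, th_sub)
  }, numeric(1))
  # power-law exponent of eta(N) close to -1
  expo <- stats::coef(stats::lm(log(eta) ~ log(sizes)))[2]
  expect_lt(expo, -0.7)
  expect_gt(expo, -1.3)
})

test_that("fit object methods expose coefficients and predictions", {
  a <- c(M = 0.6, V = 0.4)
  E <- matrix(c(6, 3, 3, 20), 2, 2)
  rho <- rho_grid_2(); colnames(rho) <- c("M", "V")
  fit <- fit_decoder_scaling(forward_design(a, E, rho),
                             n_starts = 6, seed = 2)
  co <- coef(fit)
  expect_equal(unname(co["a_M"]), 0.6, tolerance = 1e-4)
  expect_equal(unname(co["eps_M.V"]), 3, tolerance = 1e-3)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  pr <- predict(fit, rho = rbind(c(1, 1), c(1, 0), c(0, 1)))
  expect_equal(pr$threshold,
               c(coarse_threshold(a, E), sqrt(E[1, 1]), sqrt(E[2, 2])),
               tolerance = 1e-4)
  expect_equal(unname(pr$beta_M[1]),
               unname(coarse_cc_slopes(a, E)[1]), tolerance = 1e-4)
  expect_true(all(c("zeta_M", "zeta_V") %in% names(pr)))
  expect_output(print(fit), "scaling factors")
  expect_output(summary(fit), "optimal scalings")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
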