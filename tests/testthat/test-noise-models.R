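test_that("signal correlations handle identical, opposite and flat tuning", {
  pop <- build_population(tuning_params(3), seed = 1)
  # neuron 2 identical to neuron 1; neuron 3 = -f1 + const
  for (f in c("b", "h", "kappa", "pref"))
    pop[[f]][2] <- pop[[f]][1]
  R <- signal_correlation_matrix(pop)
  expect_equal(R[1, 2], 1, tolerance = 1e-12)
  grid <- seq(-pi, pi, length.out = 361)[-1]
  f <- tuning_curve(pop, grid)
  f[, 3] <- -f[, 1] + 100
  expect_equal(stats::cor(f[, 1], f[, 3]), -1, tolerance = 1e-12)
  # flat neuron: flagged, zero off-diagonal
  popf <- build_population(tuning_params(3), seed = 2)
  popf$h[2] <- 0
  expect_warning(Rf <- signal_correlation_matrix(popf), "zero tuning")
  expect_equal(Rf[2, c(1, 3)], c(0, 0))
  expect_equal(diag(Rf), rep(1, 3))
})

test_that("signal correlations match a brute-force grid oracle", {
  pop <- build_population(tuning_params(20), seed = 3)
  R <- signal_correlation_matrix(pop, n_grid = 180)
  grid <- seq(-pi, pi, length.out = 181)[-1]
  expect_equal(R, stats::cor(tuning_curve(pop, grid)), tolerance = 1e-12)
})

test_that("m = 0 gives independent Poisson-like neurons", {
  pop <- build_population(tuning_params(10), seed = 4)
  cv <- extensive_covariance(pop, m = 0)
  expect_equal(cv$Sigma, diag(pop$f0), tolerance = 1e-12)
})

test_that("sampled correlation matrices are centred on the mean model", {
  pop <- build_population(tuning_params(12), seed = 5)
  Rbar <- popdecode:::mean_correlation_matrix(pop, 0.19)
  acc <- matrix(0, 12, 12)
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    cv <- extensive_covariance(pop, 0.19, wishart_dof = 60, seed = i)
    acc <- acc + stats::cov2cor(cv$Sigma)
  }
  avg <- acc / n_rep
  # entrywise within 3 standard errors (sd of a correlation entry is
  # bounded by ~sqrt(2/dof) for a rescaled Wishart draw)
  tol <- 3 * sqrt(2 / 60) / sqrt(n_rep)
  off <- upper.tri(avg)
  expect_lt(max(abs(avg[off] - Rbar[off])), 5 * tol)
})

test_that("refitting the slope to sampled matrices recovers it", {
  pop <- build_population(tuning_params(24), seed = 6)
  m_hat <- vapply(1:40, function(i) {
    cv <- extensive_covariance(pop, 0.19, wishart_dof = 120, seed = i)
    refit_correlation_slope(cv, pop)
  }, numeric(1))
  expect_lt(abs(mean(m_hat) - 0.19), 3 * stats::sd(m_hat) / sqrt(40))
})

test_that("interareal slope is k times the geometric mean", {
  expect_equal(interareal_slope(0.3, 0.5, 0), 0)
  expect_equal(interareal_slope(0.19, 0.70, 0.999999),
               sqrt(0.19 * 0.70), tolerance = 1e-5)
  expect_equal(interareal_slope(0.4, 0.4, 0.5), 0.2)
  expect_error(interareal_slope(0.3, 0.5, 1), "k")
  expect_error(interareal_slope(1, 0.5, 0.2), "slopes")
})

test_that("zero information-limiting noise leaves the covariance unchanged", {
  pop <- two_area_pop(8)
  base <- extensive_covariance(pop, 0.2)
  out <- limited_covariance(base, pop, matrix(0, 2, 2))
  expect_equal(out$Sigma, base$Sigma)
  expect_identical(out$model, "limited")
})

test_that("information additivity holds exactly (Sherman-Morrison)", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 15
    Sigma <- random_spd(n)
    fp <- stats::rnorm(n)
    eps <- stats::runif(1, 0.01, 2)
    Sil <- Sigma + eps * tcrossprod(fp)
    v_base <- 1 / drop(crossprod(fp, solve(Sigma, fp)))
    v_lim <- 1 / drop(crossprod(fp, solve(Sil, fp)))
    expect_equal(v_lim, v_base + eps, tolerance = 1e-10)
  }
})

test_that("limited covariance caps information under neuron duplication", {
  pop <- build_population(tuning_params(16), seed = 7)
  eps <- 0.05
  v_prev <- Inf
  for (times in c(1, 2, 4, 8)) {
    big <- duplicate_pop(pop, times)
    base <- covariance_model(diag(big$sigma2), big$area, check = FALSE)
    lim <- limited_covariance(base, big, eps)
    v <- 1 / linear_fisher_information(lim, big$deriv)
    expect_gt(v, eps)      # never below the information-limiting floor
    expect_lt(v, v_prev)   # monotone decrease towards it
    v_prev <- v
  }
  expect_lt(v_prev - eps, 0.2 * eps)
})

test_that("extensive information grows with N, limited information saturates", {
  pop <- build_population(tuning_params(128), seed = 8)
  sizes <- c(16, 32, 64, 128)
  j_ext <- j_lim <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    sub <- duplicate_pop(pop, 1)  # copy then truncate to nested subsample
    keep <- seq_len(sizes[i])
    for (f in c("area", "b", "h", "kappa", "pref", "f0", "deriv", "sigma2"))
      sub[[f]] <- sub[[f]][keep]
    sub$n <- sizes[i]
    cv <- extensive_covariance(sub, 0.2)
    j_ext[i] <- linear_fisher_information(cv, sub$deriv)
    lim <- limited_covariance(cv, sub, 0.5)
    j_lim[i] <- linear_fisher_information(lim, sub$deriv)
  }
  expect_true(all(diff(j_ext) > 0))
  expect_true(all(j_lim < 1 / 0.5))
  # saturation: relative growth of limited info shrinks
  expect_lt(j_lim[4] / j_lim[3], j_ext[4] / j_ext[3])
})

test_that("coarse graining recovers pure differential noise exactly", {
  pop <- build_population(tuning_params(12), seed = 9)
  eps <- 0.7
  Sigma <- eps * tcrossprod(pop$deriv)
  cv <- covariance_model(Sigma, pop$area, check = FALSE)
  cg <- coarse_grain_extensive(cv, pop)
  expect_equal(drop(cg$E), eps, tolerance = 1e-10)
  # sign convention u'f' >= 0 makes u equal the unit signal direction
  expect_equal(cg$U[, 1], pop$deriv / sqrt(sum(pop$deriv^2)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("block-diagonal covariances coarse-grain to uncorrelated areas", {
  pop <- two_area_pop(10)
  cv <- extensive_covariance(pop, c(M = 0.2, V = 0.4), k = 0)
  cg <- coarse_grain_extensive(cv, pop)
  expect_equal(cg$E["M", "V"], 0, tolerance = 1e-10)
  expect_true(all(diag(cg$E) > 0))
})

test_that("coarse graining matches the brute-force mode definitions", {
  pop <- two_area_pop(9, seed = 13)
  cv <- extensive_covariance(pop, c(M = 0.3, V = 0.5), k = 0.6)
  cg <- coarse_grain_extensive(cv, pop)
  iM <- which(pop$area == "M"); iV <- which(pop$area == "V")
  eM <- eigen(cv$Sigma[iM, iM], symmetric = TRUE)
  eV <- eigen(cv$Sigma[iV, iV], symmetric = TRUE)
  uM <- eM$vectors[, 1]; if (sum(uM * pop$deriv[iM]) < 0) uM <- -uM
  uV <- eV$vectors[, 1]; if (sum(uV * pop$deriv[iV]) < 0) uV <- -uV
  ufM <- sum(uM * pop$deriv[iM]); ufV <- sum(uV * pop$deriv[iV])
  expect_equal(cg$E["M", "M"], eM$values[1] / ufM^2, tolerance = 1e-10)
  expect_equal(cg$E["V", "V"], eV$values[1] / ufV^2, tolerance = 1e-10)
  lam_mv <- drop(uM %*% cv$Sigma[iM, iV] %*% uV)
  expect_equal(cg$E["M", "V"], lam_mv / (ufM * ufV), tolerance = 1e-10)
  # invariance to the eigenvector sign convention
  cg2 <- coarse_grain_extensive(cv, pop)
  expect_equal(cg$E, cg2$E)
})

test_that("produced covariances are symmetric and PSD", {
  pop <- two_area_pop(8, seed = 17)
  for (dof in list(NULL, 200L)) {
    cv <- extensive_covariance(pop, c(M = 0.19, V = 0.7), k = 0.3,
                               wishart_dof = dof, seed = 21)
    expect_lt(max(abs(cv$Sigma - t(cv$Sigma))), 1e-10 * max(abs(cv$Sigma)))
    ev <- eigen(cv$Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    lim <- limited_covariance(cv, pop, matrix(c(2, 1, 1, 3), 2))
    evl <- eigen(lim$Sigma, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(evl), -1e-8 * max(evl))
  }
})

test_that("covariance files round-trip with their sidecar", {
  pop <- build_population(tuning_params(5), seed = 10)
  cv <- extensive_covariance(pop, 0.2)
  path <- tempfile(fileext = ".csv")
  write_covariance(cv, path)
  back <- read_covariance(path)
  expect_equal(back$Sigma, cv$Sigma)
  expect_identical(back$area, cv$area)
  expect_identical(back$model, "extensive")
})
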