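#' Covariance model container
#'
#' A stimulus-independent N x N noise covariance carrying its population
#' partition and a provenance tag.
#'
#' @param Sigma symmetric positive semi-definite matrix, (spikes/s)^2.
#' @param area per-neuron area labels (length N).
#' @param model provenance tag: "extensive", "limited" or "custom".
#' @param check validate symmetry/PSD (small tolerance) on construction.
#' @return Object of class \code{"covariance_model"}.
#' @export
covariance_model <- function(Sigma, area, model = "custom", check = TRUE) {
  Sigma <- as.matrix(Sigma)
  n <- nrow(Sigma)
  if (length(area) == 1L) area <- rep(as.character(area), n)
  if (ncol(Sigma) != n || length(area) != n)
    stop("dimension mismatch between 'Sigma' and 'area'")
  if (check) {
    if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma))))
      stop("'Sigma' is not symmetric")
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("'Sigma' is not positive semi-definite")
    if (any(diag(Sigma) <= 0))
      stop("'Sigma' must have a positive diagonal")
  }
  structure(list(Sigma = Sigma, area = as.character(area), model = model),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat(sprintf("Noise covariance (%s model): %d x %d, %d area(s)\n",
              x$model, nrow(x$Sigma), ncol(x$Sigma),
              length(unique(x$area))))
  invisible(x)
}

#' Coarse population-level noise container
#'
#' Holds the Z x Z matrix E of population-level noise magnitudes
#' \eqn{\epsilon_{xy}} (stimulus units squared) and, optionally, the
#' eigenmode scaffolding it was derived from: the block mode matrix U
#' (N x Z) and the mode covariance L (Z x Z).
#'
#' @param E symmetric Z x Z matrix with positive diagonal and
#'   \eqn{|\epsilon_{xy}| \le \sqrt{\epsilon_{xx}\epsilon_{yy}}}.
#' @param areas area labels naming the rows/columns of E.
#' @param U,L optional mode matrix and mode covariance.
#' @return Object of class \code{"coarse_noise"}.
#' @export
coarse_noise <- function(E, areas = NULL, U = NULL, L = NULL) {
  E <- as.matrix(E)
  if (nrow(E) != ncol(E)) stop("'E' must be square")
  if (max(abs(E - t(E))) > 1e-8 * max(1, max(abs(E))))
    stop("'E' must be symmetric")
  if (any(diag(E) <= 0)) stop("diag(E) must be positive")
  bound <- sqrt(outer(diag(E), diag(E)))
  if (any(abs(E) > bound * (1 + 1e-8)))
    stop("E violates |eps_xy| <= sqrt(eps_xx eps_yy)")
  if (is.null(areas)) areas <- rownames(E)
  if (is.null(areas)) areas <- paste0("pop", seq_len(nrow(E)))
  dimnames(E) <- list(areas, areas)
  structure(list(E = E, areas = areas, U = U, L = L),
            class = "coarse_noise")
}

#' @export
print.coarse_noise <- function(x, ...) {
  cat("Coarse population-level noise E (stimulus units^2):\n")
  print(round(x$E, 4))
  invisible(x)
}

#' Signal correlation matrix of a population
#'
#' Correlation between mean tuning curves \eqn{f_i} and \eqn{f_j} evaluated
#' over a uniform grid of stimuli on the population's domain. A neuron with
#' zero tuning variance (flat tuning) gets zeros off-diagonal and one on the
#' diagonal, with a warning.
#'
#' @param pop a \code{"neural_population"}.
#' @param n_grid number of uniform grid points on the stimulus domain.
#' @return N x N correlation matrix.
#' @export
signal_correlation_matrix <- function(pop, n_grid = 360) {
  stopifnot(inherits(pop, "neural_population"))
  grid <- seq(pop$domain[1], pop$domain[2], length.out = n_grid + 1L)[-1L]
  f <- tuning_curve(pop, grid)
  v <- apply(f, 2, stats::var)
  flat <- v <= .Machine$double.eps * max(v, 1)
  R <- matrix(0, pop$n, pop$n)
  if (any(!flat)) R[!flat, !flat] <- stats::cor(f[, !flat, drop = FALSE])
  if (any(flat)) {
    warning(sum(flat), " neuron(s) with zero tuning variance: ",
            "signal correlation set to 0 off-diagonal")
  }
  diag(R) <- 1
  R
}

#' Project a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping at zero; used to repair marginal PSD violations after
#' rescaling sampled correlation matrices.
#'
#' @param M symmetric matrix.
#' @return PSD matrix closest to M in Frobenius norm.
#' @export
nearest_psd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

#' Interareal signal-to-noise correlation slope
#'
#' The proportionality between signal and noise correlations for pairs of
#' neurons in different areas, \eqn{m_{xy} = k \sqrt{m_x m_y}}: a fraction
#' \eqn{k} of the geometric mean of the two within-area slopes.
#'
#' @param m_x,m_y within-area slopes, each in [0, 1).
#' @param k fraction in [0, 1).
#' @return The cross-area slope.
#' @export
interareal_slope <- function(m_x, m_y, k) {
  if (any(c(m_x, m_y) < 0) || any(c(m_x, m_y) >= 1))
    stop("within-area slopes must lie in [0, 1)")
  if (k < 0 || k >= 1) stop("'k' must lie in [0, 1)")
  k * sqrt(m_x * m_y)
}

# Mean correlation matrix of the limited-range model:
# within area x: (1 - m_x) * I + m_x * Rsig; across x, y: m_xy * Rsig.
mean_correlation_matrix <- function(pop, m, k = 0, n_grid = 360) {
  areas <- area_levels(pop)
  if (length(m) == 1L) m <- stats::setNames(rep(m, length(areas)), areas)
  if (is.null(names(m))) names(m) <- areas
  if (!all(areas %in% names(m))) stop("'m' must name every area")
  if (any(m < 0) || any(m >= 1)) stop("slopes 'm' must lie in [0, 1)")
  Rsig <- signal_correlation_matrix(pop, n_grid)
  mvec <- m[pop$area]
  # per-pair slope: within-area m_x, across areas k * sqrt(m_x m_y)
  M <- sqrt(outer(mvec, mvec))
  same <- outer(pop$area, pop$area, "==")
  M[!same] <- k * M[!same]
  Rbar <- M * Rsig
  diag(Rbar) <- 1
  Rbar
}

#' Limited-range ("extensive information") noise covariance
#'
#' Builds the covariance in which noise correlations are proportional to
#' signal correlations, \eqn{\bar R_{ij} = (1 - m)\delta_{ij} + m
#' R^{sig}_{ij}} within each area, with per-area slopes and an interareal
#' slope \eqn{k\sqrt{m_x m_y}} across areas. Variances are Poisson-like:
#' \eqn{\Sigma_{ij} = R_{ij}\sqrt{f_i f_j}} with \eqn{f_i = f_i(s_0)}.
#' Optionally a single correlation matrix is sampled from a Wishart
#' distribution centred on \eqn{\bar R} (then rescaled to unit diagonal and
#' PSD-repaired) to emulate the diversity of measured pairwise correlations.
#'
#' @param pop a \code{"neural_population"}.
#' @param m within-area slope(s): scalar or named per-area vector, in [0, 1).
#' @param k interareal fraction in [0, 1); see \code{\link{interareal_slope}}.
#' @param wishart_dof degrees of freedom for Wishart sampling (>= N), or
#'   \code{NULL} for the deterministic mean-correlation model.
#' @param seed integer seed used when sampling.
#' @param n_grid grid resolution for signal correlations.
#' @return A \code{"covariance_model"} with tag "extensive".
#' @export
extensive_covariance <- function(pop, m, k = 0, wishart_dof = NULL,
                                 seed = 1L, n_grid = 360) {
  stopifnot(inherits(pop, "neural_population"))
  Rbar <- mean_correlation_matrix(pop, m, k, n_grid)
  if (is.null(wishart_dof)) {
    R <- nearest_psd(Rbar)
    d <- sqrt(diag(R)); R <- R / outer(d, d)  # keep unit diagonal
  } else {
    wishart_dof <- as.integer(wishart_dof)
    if (wishart_dof < pop$n)
      stop("'wishart_dof' must be at least the number of neurons")
    set.seed(as.integer(seed))
    Rbar_psd <- nearest_psd(Rbar)
    # small jitter keeps the scale matrix full-rank for the sampler
    W <- stats::rWishart(1, wishart_dof,
                         (Rbar_psd + 1e-10 * diag(pop$n)) / wishart_dof)[, , 1]
    R <- stats::cov2cor(W)
    R <- nearest_psd(R)
    d <- sqrt(diag(R)); R <- R / outer(d, d)
  }
  Sigma <- R * sqrt(outer(pop$f0, pop$f0))
  covariance_model(Sigma, pop$area, model = "extensive", check = FALSE)
}

#' Calibrate Wishart degrees of freedom to a target slope uncertainty
#'
#' Bisection search for the Wishart dof at which refitting the
#' signal-to-noise correlation slope to sampled matrices has a target
#' Monte-Carlo standard deviation (larger dof gives tighter matrices).
#'
#' @param pop single-area \code{"neural_population"}.
#' @param m generating within-area slope.
#' @param target_sd desired standard deviation of the refitted slope.
#' @param n_rep Monte-Carlo replicates per candidate dof.
#' @param dof_range integer search interval (lower bound at least N).
#' @param seed integer seed.
#' @return The calibrated degrees of freedom (integer).
#' @export
calibrate_wishart_dof <- function(pop, m, target_sd, n_rep = 50,
                                  dof_range = c(pop$n, 64L * pop$n),
                                  seed = 1L) {
  slope_sd <- function(dof) {
    s <- vapply(seq_len(n_rep), function(i) {
      cv <- extensive_covariance(pop, m, wishart_dof = dof,
                                 seed = seed * 1000L + i)
      refit_correlation_slope(cv, pop)
    }, numeric(1))
    stats::sd(s)
  }
  lo <- max(as.integer(dof_range[1]), pop$n)
  hi <- as.integer(dof_range[2])
  if (slope_sd(lo) < target_sd) return(lo)
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) / 2)
    if (slope_sd(mid) > target_sd) lo <- mid else hi <- mid
  }
  hi
}

#' Refit the signal-to-noise correlation slope of a covariance
#'
#' Least-squares slope of off-diagonal noise correlations against signal
#' correlations (through the origin), the procedure used to summarise
#' pairwise recordings. Restricted to within-area pairs of one area.
#'
#' @param cov a \code{"covariance_model"}.
#' @param pop the matching population.
#' @param area which area to refit (default: first).
#' @param n_grid grid resolution for signal correlations.
#' @return Fitted slope m.
#' @export
refit_correlation_slope <- function(cov, pop, area = area_levels(pop)[1],
                                    n_grid = 360) {
  idx <- which(pop$area == area)
  R <- stats::cov2cor(cov$Sigma[idx, idx])
  sub <- pop
  for (f in c("area", "b", "h", "kappa", "pref", "f0", "deriv", "sigma2"))
    sub[[f]] <- sub[[f]][idx]
  sub$n <- length(idx)
  Rsig <- signal_correlation_matrix(sub, n_grid)
  off <- upper.tri(R)
  sum(R[off] * Rsig[off]) / sum(Rsig[off]^2)
}

#' Add information-limiting (differential) correlations
#'
#' Augments a base covariance with the low-rank information-limiting
#' component \eqn{F E F^T}, where F is the N x Z block matrix of per-area
#' tuning derivative vectors and E the Z x Z covariance of
#' information-limiting noise. With a single population and scalar
#' \eqn{\epsilon} this is \eqn{\Sigma + \epsilon f' f'^T}, which caps the
#' linear Fisher information at \eqn{1/\epsilon}.
#'
#' @param base a \code{"covariance_model"} (the general noise).
#' @param pop the matching population (provides derivatives and partition).
#' @param E_IL a \code{"coarse_noise"}, a Z x Z matrix, or a scalar
#'   \eqn{\epsilon} for a single population.
#' @return A \code{"covariance_model"} with tag "limited".
#' @export
limited_covariance <- function(base, pop, E_IL) {
  stopifnot(inherits(base, "covariance_model"),
            inherits(pop, "neural_population"))
  if (!identical(base$area, pop$area)) stop("partition mismatch")
  E <- if (inherits(E_IL, "coarse_noise")) E_IL$E else as.matrix(E_IL)
  areas <- area_levels(pop)
  if (nrow(E) != length(areas))
    stop("E dimension does not match the number of areas")
  if (max(abs(E - t(E))) > 1e-8 * max(1, max(abs(E))))
    stop("'E_IL' must be symmetric")
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("'E_IL' must be PSD")
  F_ <- derivative_blocks(pop)
  Sigma <- base$Sigma + F_ %*% E %*% t(F_)
  covariance_model(Sigma, pop$area, model = "limited", check = FALSE)
}

# N x Z block-diagonal matrix of per-area derivative vectors f'_z
derivative_blocks <- function(pop) {
  areas <- area_levels(pop)
  F_ <- matrix(0, pop$n, length(areas),
               dimnames = list(NULL, areas))
  for (z in seq_along(areas))
    F_[pop$area == areas[z], z] <- pop$deriv[pop$area == areas[z]]
  F_
}

#' Coarse-grain an extensive-model covariance to population level
#'
#' For each area x, takes the leading eigenvector \eqn{u_x} of that area's
#' own covariance block \eqn{\Sigma_{xx}} (not of the full matrix) with
#' eigenvalue \eqn{\lambda_x}, cross-mode noise
#' \eqn{\lambda_{xy} = u_x^T \Sigma_{xy} u_y}, and maps to stimulus units:
#' \eqn{\epsilon_{xx} = \lambda_x / (u_x^T f'_x)^2},
#' \eqn{\epsilon_{xy} = \lambda_{xy} / ((u_x^T f'_x)(u_y^T f'_y))}.
#' Eigenvector signs are fixed so \eqn{u_x^T f'_x \ge 0}.
#'
#' @param cov a \code{"covariance_model"}.
#' @param pop the matching population.
#' @param tie_tol relative gap between the two leading eigenvalues below
#'   which a degeneracy warning is issued.
#' @return A \code{"coarse_noise"} with U and L attached.
#' @export
coarse_grain_extensive <- function(cov, pop, tie_tol = 1e-6) {
  stopifnot(inherits(cov, "covariance_model"),
            inherits(pop, "neural_population"))
  if (!identical(cov$area, pop$area)) stop("partition mismatch")
  areas <- area_levels(pop)
  Z <- length(areas)
  U <- matrix(0, pop$n, Z, dimnames = list(NULL, areas))
  lam <- numeric(Z)
  uf <- numeric(Z)
  for (z in seq_len(Z)) {
    idx <- which(pop$area == areas[z])
    e <- eigen(cov$Sigma[idx, idx], symmetric = TRUE)
    if (length(idx) > 1L) {
      gap <- (e$values[1] - e$values[2]) / max(e$values[1], .Machine$double.eps)
      if (gap < tie_tol)
        warning("near-degenerate leading eigenvalues in area '", areas[z],
                "'; taking the first by index order")
    }
    u <- e$vectors[, 1]
    fz <- pop$deriv[idx]
    if (sum(u * fz) < 0) u <- -u  # sign convention: u.f' >= 0
    uf[z] <- sum(u * fz)
    if (abs(uf[z]) < 1e-12 * sqrt(sum(fz^2)))
      stop("leading mode of area '", areas[z],
           "' carries no signal (u'f' = 0); epsilon undefined")
    U[idx, z] <- u
    lam[z] <- e$values[1]
  }
  L <- diag(lam, Z)
  for (x in seq_len(Z)) for (y in seq_len(Z)) {
    if (x < y) {
      ix <- which(pop$area == areas[x]); iy <- which(pop$area == areas[y])
      L[x, y] <- L[y, x] <-
        drop(U[ix, x] %*% cov$Sigma[ix, iy] %*% U[iy, y])
    }
  }
  E <- L / outer(uf, uf)
  # clip marginal Cauchy-Schwarz violations from finite precision
  bound <- sqrt(outer(diag(E), diag(E)))
  E <- pmin(pmax(E, -bound), bound)
  diag(E) <- lam / uf^2
  coarse_noise(E, areas = areas, U = U, L = L)
}

#' Linear Fisher information of a population
#'
#' \eqn{J = f'^T \Sigma^{-1} f'}; its inverse is the variance of the locally
#' optimal unbiased linear estimator.
#'
#' @param cov a \code{"covariance_model"} (or plain matrix).
#' @param deriv tuning derivative vector f'.
#' @return Scalar linear Fisher information (stimulus units^-2).
#' @export
linear_fisher_information <- function(cov, deriv) {
  Sigma <- if (inherits(cov, "covariance_model")) cov$Sigma else as.matrix(cov)
  drop(crossprod(deriv, solve_or_ginv(Sigma, deriv)))
}

# Solve Sigma x = b, falling back to the pseudo-inverse for singular Sigma.
solve_or_ginv <- function(Sigma, b) {
  out <- tryCatch(solve(Sigma, b), error = function(e) NULL)
  if (is.null(out)) {
    warning("singular covariance: using the Moore-Penrose pseudo-inverse")
    out <- MASS::ginv(Sigma) %*% b
  }
  out
}
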