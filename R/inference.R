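#' Inactivation experiment design
#'
#' A set of experiments, each specified by per-area retention factors
#' \eqn{\rho_x \in [0, 1]} (1 = intact, 0 = fully inactivated), the
#' observed behavioural threshold, and optionally the observed per-area
#' choice-correlation slopes \eqn{\beta_x} (NA where unmeasured, e.g. in a
#' silenced area).
#'
#' @param rho numeric matrix (experiments x areas) of retention factors,
#'   with column names naming the areas; a vector is taken as one
#'   experiment.
#' @param threshold per-experiment behavioural thresholds (> 0).
#' @param beta optional matrix (experiments x areas) of observed CC slopes;
#'   NA entries are ignored by the solver.
#' @return Object of class \code{"inactivation_design"}.
#' @export
inactivation_design <- function(rho, threshold, beta = NULL) {
  if (is.null(dim(rho))) rho <- matrix(rho, nrow = 1,
                                       dimnames = list(NULL, names(rho)))
  rho <- as.matrix(rho)
  if (is.null(colnames(rho)))
    colnames(rho) <- paste0("pop", seq_len(ncol(rho)))
  if (any(rho < 0 | rho > 1)) stop("retention factors must lie in [0, 1]")
  if (length(threshold) != nrow(rho))
    stop("'threshold' must have one value per experiment")
  if (any(threshold <= 0)) stop("thresholds must be positive")
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    if (!all(dim(beta) == dim(rho)))
      stop("'beta' must have the same shape as 'rho'")
    colnames(beta) <- colnames(rho)
  }
  structure(list(rho = rho, threshold = as.numeric(threshold), beta = beta,
                 areas = colnames(rho)),
            class = "inactivation_design")
}

#' @export
print.inactivation_design <- function(x, ...) {
  cat("Inactivation design:", nrow(x$rho), "experiment(s),",
      length(x$areas), "area(s) [", paste(x$areas, collapse = ", "), "]\n")
  df <- data.frame(x$rho, threshold = x$threshold, check.names = FALSE)
  if (!is.null(x$beta)) {
    bb <- x$beta; colnames(bb) <- paste0("beta_", colnames(bb))
    df <- cbind(df, bb)
  }
  print(df, digits = 4)
  invisible(x)
}

# renormalised scaling after inactivation: a~ = (a * rho) / sum(a * rho)
# (l1 renormalisation keeps the readout unbiased)
scaled_a <- function(a, rho) {
  ar <- a * rho
  s <- sum(ar)
  if (abs(s) < .Machine$double.eps * max(1, max(abs(ar))))
    stop("everything inactivated: sum(a * rho) = 0")
  ar / s
}

#' Behavioural threshold of the coarse model
#'
#' \eqn{\vartheta = \sqrt{\tilde a^T E \tilde a}} where
#' \eqn{\tilde a = (a \odot \rho)/\sum_x a_x \rho_x}. With one area fully
#' retained and the other silenced this reduces to
#' \eqn{\vartheta_{-x}^2 = \epsilon_{yy}}.
#'
#' @param a per-area scaling factors (intact decoder; a'1 = 1).
#' @param E coarse noise matrix (\code{"coarse_noise"} or Z x Z matrix).
#' @param rho per-area retention factors (default 1: intact).
#' @return Threshold in stimulus units.
#' @export
coarse_threshold <- function(a, E, rho = 1) {
  E <- if (inherits(E, "coarse_noise")) E$E else as.matrix(E)
  if (length(rho) == 1L) rho <- rep(rho, length(a))
  at <- scaled_a(a, rho)
  sqrt(drop(crossprod(at, E %*% at)))
}

#' Per-area choice-correlation slopes of the coarse model
#'
#' \eqn{\beta_x = (E \tilde a)_x / (\tilde a^T E \tilde a)} (with the same
#' renormalised \eqn{\tilde a} as \code{\link{coarse_threshold}}). At the
#' optimal scaling (\eqn{a \propto E^{-1} 1}) every \eqn{\beta_x = 1}.
#' \code{mode = "eq19"} drops the quadratic-form denominator, keeping only
#' the l1 normalisation.
#'
#' @inheritParams coarse_threshold
#' @param mode "normalised" (default) or "eq19".
#' @return Named vector of per-area slopes.
#' @export
coarse_cc_slopes <- function(a, E, rho = 1, mode = c("normalised", "eq19")) {
  mode <- match.arg(mode)
  Em <- if (inherits(E, "coarse_noise")) E$E else as.matrix(E)
  if (length(rho) == 1L) rho <- rep(rho, length(a))
  at <- scaled_a(a, rho)
  Ea <- drop(Em %*% at)
  if (mode == "eq19") return(Ea)
  q <- drop(crossprod(at, Ea))
  if (q <= 0) stop("degenerate coarse model: a'Ea = 0")
  Ea / q
}

#' Optimal scaling factors for a coarse noise matrix
#'
#' \eqn{a \propto E^{-1} 1}, renormalised to sum to one: the combination of
#' per-area estimates with minimum variance.
#'
#' @param E coarse noise (\code{"coarse_noise"} or matrix).
#' @return Named scaling vector with a'1 = 1.
#' @export
optimal_scalings <- function(E) {
  Em <- if (inherits(E, "coarse_noise")) E$E else as.matrix(E)
  a <- drop(solve(Em, rep(1, nrow(Em))))
  a <- a / sum(a)
  names(a) <- if (inherits(E, "coarse_noise")) E$areas else colnames(Em)
  a
}

#' Two-population scaling ratio from slopes and inactivation thresholds
#'
#' For uncorrelated areas (\eqn{\gamma = 0}) the ratio factorises:
#' \eqn{a_x/a_y = (\beta_x/\beta_y)(\vartheta_{-x}^2/\vartheta_{-y}^2)}.
#' With interareal correlation \eqn{\gamma = \epsilon_{xy}/\epsilon_{xx}}:
#' \deqn{a_x/a_y = \frac{(\beta_x/\beta_y)(\vartheta_{-x}^2 /
#'   \vartheta_{-y}^2) - \gamma}{1 - (\beta_x/\beta_y)\gamma}.}
#' When the coarse noise magnitudes are known, supplying \code{eps_xx} and
#' \code{eps_yy} uses the exact ratio \eqn{\epsilon_{yy}/\epsilon_{xx}} in
#' place of the squared-threshold ratio (and takes precedence over
#' thresholds).
#'
#' @param beta_x,beta_y per-area CC slopes (> 0).
#' @param theta_minus_x,theta_minus_y behavioural thresholds after fully
#'   inactivating area x (resp. y).
#' @param gamma interareal correlation magnitude
#'   \eqn{\epsilon_{xy}/\epsilon_{xx}} (default 0).
#' @param eps_xx,eps_yy optional exact coarse noise magnitudes.
#' @return The scaling ratio \eqn{a_x/a_y} (may be negative; the magnitude
#'   is usually reported).
#' @export
two_population_ratio <- function(beta_x, beta_y,
                                 theta_minus_x = NULL, theta_minus_y = NULL,
                                 gamma = 0, eps_xx = NULL, eps_yy = NULL) {
  if (beta_x <= 0 || beta_y <= 0) stop("slopes must be positive")
  if (!is.null(eps_xx) && !is.null(eps_yy)) {
    if (eps_xx <= 0 || eps_yy <= 0) stop("noise magnitudes must be positive")
    tratio <- eps_yy / eps_xx
  } else {
    if (is.null(theta_minus_x) || is.null(theta_minus_y))
      stop("supply either both thresholds or both noise magnitudes")
    if (theta_minus_x <= 0 || theta_minus_y <= 0)
      stop("thresholds must be positive")
    tratio <- theta_minus_x^2 / theta_minus_y^2
  }
  b <- beta_x / beta_y
  if (gamma == 0) return(b * tratio)
  den <- 1 - b * gamma
  if (abs(den) < 1e-12)
    stop("singular denominator: 1 - (beta_x/beta_y) * gamma = 0")
  (b * tratio - gamma) / den
}

#' Predicted rescaling of choice correlations under inactivation
#'
#' After fully inactivating the other area y, the choice correlations of
#' area x rescale by \eqn{\zeta_x = (1/\beta_x)(\vartheta_{-y}/\vartheta)}:
#' proportional to the behavioural cost of losing y.
#'
#' @param beta_x CC slope of area x in the intact condition.
#' @param theta_intact intact behavioural threshold.
#' @param theta_minus_other threshold after inactivating the other area.
#' @return The multiplicative CC change \eqn{\zeta_x}.
#' @export
predict_cc_scaling <- function(beta_x, theta_intact, theta_minus_other) {
  if (any(c(beta_x, theta_intact, theta_minus_other) <= 0))
    stop("all inputs must be positive")
  (1 / beta_x) * (theta_minus_other / theta_intact)
}

#' Decoding efficiency
#'
#' \eqn{\eta = J_{decoded}/J_{opt} = \vartheta_{opt}^2 /
#' \vartheta_{decoded}^2}: the fraction of available linear Fisher
#' information recovered by the decoder.
#'
#' @param theta_opt threshold of the optimal decoder.
#' @param theta_decoded threshold of the decoder under study.
#' @return Efficiency in (0, 1].
#' @export
decoding_efficiency <- function(theta_opt, theta_decoded) {
  if (theta_opt <= 0 || theta_decoded <= 0)
    stop("thresholds must be positive")
  if (theta_opt > theta_decoded * (1 + 1e-8))
    warning("theta_opt exceeds theta_decoded; efficiency > 1")
  theta_opt^2 / theta_decoded^2
}

# ---- the fitting function -------------------------------------------------

# pack/unpack: parameters are (a_1..a_{Z-1}, vech of the Cholesky-like
# factor G with E = G G', PSD by construction so the Cauchy-Schwarz bound
# holds automatically)
pack_params <- function(a, E) {
  Z <- length(a)
  G <- t(chol(as.matrix(E) + 1e-12 * diag(Z)))
  c(a[-Z], G[lower.tri(G, diag = TRUE)])
}
unpack_params <- function(par, Z) {
  a_free <- par[seq_len(Z - 1)]
  a <- c(a_free, 1 - sum(a_free))
  G <- matrix(0, Z, Z)
  G[lower.tri(G, diag = TRUE)] <- par[-seq_len(Z - 1)]
  list(a = a, E = G %*% t(G))
}

design_residuals <- function(par, design, beta_mode) {
  Z <- length(design$areas)
  p <- unpack_params(par, Z)
  res <- numeric(0)
  for (i in seq_len(nrow(design$rho))) {
    rho <- design$rho[i, ]
    th2 <- tryCatch(coarse_threshold(p$a, p$E, rho)^2,
                    error = function(e) NA_real_)
    res <- c(res, design$threshold[i]^2 - th2)
    if (!is.null(design$beta)) {
      obs <- design$beta[i, ]
      if (any(is.finite(obs))) {
        pred <- tryCatch(coarse_cc_slopes(p$a, p$E, rho, mode = beta_mode),
                         error = function(e) rep(NA_real_, Z))
        res <- c(res, (obs - pred)[is.finite(obs)])
      }
    }
  }
  res[!is.finite(res)] <- 1e6  # push the optimiser away from degeneracies
  res
}

n_constraints <- function(design) {
  nrow(design$rho) +
    if (is.null(design$beta)) 0L else sum(is.finite(design$beta))
}

#' Infer decoder scaling factors and coarse noise from inactivation data
#'
#' Fits the coarse model in which each inactivation experiment
#' \eqn{\phi} constrains the unknown per-area scaling factors \eqn{a} and
#' the population-level noise covariance E through the squared behavioural
#' threshold \eqn{\theta_\phi^2 = \tilde a_\phi^T E \tilde a_\phi} and,
#' when measured, the per-area choice-correlation slopes
#' \eqn{\beta_{x\phi}} (see \code{\link{coarse_cc_slopes}}), where
#' \eqn{\tilde a_\phi} is the l1-renormalised inactivated scaling. The
#' constraints are multivariate polynomials in (a, E), solved by
#' trust-region nonlinear least squares (Levenberg-Marquardt) with random
#' multi-starts; E is parameterised through a Cholesky-like factor so it
#' stays positive semi-definite (hence satisfies the Cauchy-Schwarz bound
#' \eqn{|\epsilon_{xy}| \le \sqrt{\epsilon_{xx}\epsilon_{yy}}}).
#' Negative recovered scalings are permitted and reported as such.
#'
#' A single area is solved in closed form: \eqn{E = \theta^2}, a = 1.
#' Distinct local optima (the two-scheme degeneracy is a feature of the
#' model) are retained in the result.
#'
#' @param design an \code{\link{inactivation_design}}.
#' @param n_starts number of random multi-starts (default 32).
#' @param beta_mode slope definition passed to
#'   \code{\link{coarse_cc_slopes}}.
#' @param seed integer seed for the multi-start draws.
#' @param maxit maximum Levenberg-Marquardt iterations per start.
#' @return An object of class \code{"decoder_scaling"} with components
#'   \code{a} (named, a'1 = 1), \code{E} (a \code{"coarse_noise"}),
#'   \code{residual_norm}, \code{fitted} / \code{residuals} per
#'   constraint, \code{optima} (distinct local optima as a data frame),
#'   \code{convergence} and the \code{design}. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{plot},
#'   \code{residuals}, \code{fitted}.
#' @export
fit_decoder_scaling <- function(design, n_starts = 32L,
                                beta_mode = c("normalised", "eq19"),
                                seed = 1L, maxit = 200L) {
  stopifnot(inherits(design, "inactivation_design"))
  beta_mode <- match.arg(beta_mode)
  Z <- length(design$areas)
  n_unknown <- Z * (Z + 1) / 2 + (Z - 1)
  if (Z == 1L) {
    E <- coarse_noise(matrix(mean(design$threshold^2), 1, 1,
                             dimnames = list(design$areas, design$areas)))
    a <- stats::setNames(1, design$areas)
    fit <- structure(
      list(a = a, E = E, residual_norm = 0,
           residuals = design$threshold^2 - mean(design$threshold^2),
           fitted = rep(mean(design$threshold^2), length(design$threshold)),
           optima = data.frame(residual_norm = 0),
           convergence = "closed form", design = design,
           beta_mode = beta_mode, call = match.call()),
      class = "decoder_scaling")
    return(fit)
  }
  if (n_constraints(design) < n_unknown)
    stop("under-determined system: ", n_constraints(design),
         " constraints for ", n_unknown, " unknowns")

  set.seed(as.integer(seed))
  th2 <- design$threshold^2
  scale0 <- stats::median(th2)
  starts <- lapply(seq_len(n_starts), function(i) {
    a0 <- stats::rexp(Z); a0 <- a0 / sum(a0)
    d0 <- stats::runif(Z, 0.2, 3) * scale0
    E0 <- diag(d0, Z)
    pack_params(a0, E0)
  })
  # one informed start: equal scalings, diagonal E at the observed scale
  starts[[1]] <- pack_params(rep(1 / Z, Z), diag(rep(scale0, Z), Z))

  best <- NULL
  sols <- list()
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = design_residuals, design = design,
                         beta_mode = beta_mode,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(out)) next
    rn <- sqrt(sum(out$fvec^2))
    sols[[length(sols) + 1L]] <- list(par = out$par, rn = rn,
                                      info = out$info)
    if (is.null(best) || rn < best$rn) best <- sols[[length(sols)]]
  }
  if (is.null(best))
    stop("optimiser failed to converge from every start")

  p <- unpack_params(best$par, Z)
  a <- stats::setNames(p$a, design$areas)
  E <- coarse_noise(p$E, areas = design$areas)
  resid <- design_residuals(best$par, design, beta_mode)

  # distinct local optima, identified by rounded solutions
  keys <- vapply(sols, function(s)
    paste(round(unpack_params(s$par, Z)$a, 4), collapse = ","), character(1))
  uniq <- !duplicated(keys)
  opt_df <- do.call(rbind, lapply(sols[uniq], function(s) {
    ps <- unpack_params(s$par, Z)
    data.frame(t(stats::setNames(ps$a, paste0("a_", design$areas))),
               residual_norm = s$rn)
  }))
  opt_df <- opt_df[order(opt_df$residual_norm), , drop = FALSE]
  rownames(opt_df) <- NULL

  structure(
    list(a = a, E = E, residual_norm = best$rn,
         residuals = resid, fitted = NULL,
         optima = opt_df,
         convergence = if (best$rn < 1e-6 * max(1, scale0))
           "converged" else "local minimum (nonzero residual)",
         design = design, beta_mode = beta_mode, call = match.call()),
    class = "decoder_scaling")
}

#' @export
print.decoder_scaling <- function(x, ...) {
  cat("Coarse decoder scaling fit (", length(x$a), " areas, ",
      nrow(x$design$rho), " experiments)\n", sep = "")
  cat("  scaling factors a (a'1 = 1):\n")
  print(round(x$a, 4))
  cat("  coarse noise E:\n")
  print(round(x$E$E, 4))
  cat(sprintf("  residual norm: %.3g (%s)\n", x$residual_norm,
              x$convergence))
  invisible(x)
}

#' @export
summary.decoder_scaling <- function(object, ...) {
  x <- object
  print(x)
  th <- coarse_threshold(x$a, x$E)
  cat(sprintf("  implied intact threshold: %.4g\n", th))
  beta <- coarse_cc_slopes(x$a, x$E, mode = x$beta_mode)
  cat("  implied intact CC slopes:\n")
  print(round(beta, 4))
  a_opt <- optimal_scalings(x$E)
  cat("  optimal scalings for this E:\n")
  print(round(a_opt, 4))
  if (nrow(x$optima) > 1L) {
    cat("  distinct local optima found:\n")
    print(x$optima, digits = 4)
  }
  invisible(x)
}

#' @export
coef.decoder_scaling <- function(object, ...) {
  E <- object$E$E
  areas <- object$design$areas
  en <- outer(areas, areas, paste, sep = ".")
  c(stats::setNames(object$a, paste0("a_", areas)),
    stats::setNames(E[upper.tri(E, diag = TRUE)],
                    paste0("eps_", en[upper.tri(en, diag = TRUE)])))
}

#' @export
residuals.decoder_scaling <- function(object, ...) object$residuals

#' Predict inactivation outcomes from a fitted coarse decoder
#'
#' Evaluates the fitted coarse model over a grid of retention factors:
#' behavioural thresholds, per-area CC slopes and (for full inactivation
#' of the complementary areas) the CC rescaling \eqn{\zeta}.
#'
#' @param object a \code{"decoder_scaling"} fit.
#' @param rho matrix (rows = conditions) or vector of retention factors;
#'   default: the intact condition.
#' @param what any of "threshold", "beta", "zeta".
#' @param ... unused.
#' @return A data frame with one row per condition: the retention factors,
#'   the predicted threshold, and per-area beta / zeta columns as
#'   requested.
#' @export
predict.decoder_scaling <- function(object,
                                    rho = NULL,
                                    what = c("threshold", "beta", "zeta"),
                                    ...) {
  what <- match.arg(what, several.ok = TRUE)
  areas <- object$design$areas
  Z <- length(areas)
  if (is.null(rho)) rho <- matrix(1, 1, Z, dimnames = list(NULL, areas))
  if (is.null(dim(rho))) rho <- matrix(rho, nrow = 1,
                                       dimnames = list(NULL, names(rho)))
  rho <- as.matrix(rho)
  if (is.null(colnames(rho))) colnames(rho) <- areas
  if (any(rho < 0 | rho > 1)) stop("retention factors must lie in [0, 1]")
  out <- as.data.frame(rho)
  names(out) <- paste0("rho_", colnames(rho))
  th_intact <- coarse_threshold(object$a, object$E)
  beta_intact <- coarse_cc_slopes(object$a, object$E,
                                  mode = object$beta_mode)
  if ("threshold" %in% what)
    out$threshold <- apply(rho, 1, function(r)
      coarse_threshold(object$a, object$E, r))
  if ("beta" %in% what) {
    bm <- t(apply(rho, 1, function(r)
      coarse_cc_slopes(object$a, object$E, r, mode = object$beta_mode)))
    colnames(bm) <- paste0("beta_", areas)
    out <- cbind(out, bm)
  }
  if ("zeta" %in% what) {
    # zeta_x: CC rescaling in area x when every *other* area is silenced
    zeta <- vapply(seq_len(Z), function(x) {
      r <- as.numeric(seq_len(Z) == x)
      th_minus <- coarse_threshold(object$a, object$E, r)
      predict_cc_scaling(beta_intact[x], th_intact, th_minus)
    }, numeric(1))
    for (x in seq_len(Z)) out[[paste0("zeta_", areas[x])]] <- zeta[x]
  }
  out
}

#' Threshold curve along the two-area scaling simplex
#'
#' For a two-area fit, plots \eqn{\vartheta(a_1)} for \eqn{a = (a_1, 1 -
#' a_1)} — the U-shaped performance curve — marking the fitted scaling,
#' the optimal scaling and the two full-inactivation endpoints.
#'
#' @param x a \code{"decoder_scaling"} with two areas.
#' @param n_grid grid resolution along the simplex.
#' @param ... passed to \code{plot}.
#' @export
plot.decoder_scaling <- function(x, n_grid = 201L, ...) {
  if (length(x$a) != 2L)
    stop("the simplex threshold curve is defined for two areas")
  a1 <- seq(0, 1, length.out = n_grid)
  th <- vapply(a1, function(t) coarse_threshold(c(t, 1 - t), x$E),
               numeric(1))
  graphics::plot(a1, th, type = "l",
                 xlab = paste0("a_", x$design$areas[1]),
                 ylab = "behavioural threshold", ...)
  graphics::abline(v = x$a[1], lty = 2)
  graphics::abline(v = optimal_scalings(x$E)[1], lty = 3)
  graphics::points(c(1, 0), c(sqrt(x$E$E[1, 1]), sqrt(x$E$E[2, 2])),
                   pch = 4)
  invisible(x)
}
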