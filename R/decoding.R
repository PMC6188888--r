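#' Decoder specification
#'
#' A linear readout \eqn{\hat s = w^T(r - f(s_0)) + s_0}. For multi-area
#' decoders the global weights decompose as \eqn{w = [a_1 w_1, ..., a_Z
#' w_Z]} with per-area unbiased patterns (\eqn{w_x^T f'_x = 1}) and scaling
#' factors summing to one (\eqn{a^T 1 = 1}); global unbiasedness
#' \eqn{w^T f' = 1} follows.
#'
#' @param w global weight vector (1/(spikes/s) x stimulus units).
#' @param area per-neuron area labels (or single label).
#' @param a per-area scaling factors; defaults to 1 for a single area.
#' @param provenance tag: "optimal", "subspace-p", "mode", "inferred", ...
#' @param deriv optional tuning derivative vector; when given, global
#'   unbiasedness w'f' = 1 is asserted.
#' @return Object of class \code{"decoder_spec"}.
#' @export
decoder_spec <- function(w, area = "pop1", a = NULL,
                         provenance = "custom", deriv = NULL) {
  w <- as.numeric(w)
  if (length(area) == 1L) area <- rep(as.character(area), length(w))
  areas <- unique(area)
  if (is.null(a)) a <- stats::setNames(rep(1 / length(areas), length(areas)),
                                       areas)
  if (abs(sum(a) - 1) > 1e-8) stop("scaling factors must satisfy a'1 = 1")
  if (!is.null(deriv) && abs(sum(w * deriv) - 1) > 1e-6)
    stop("decoder is not unbiased: w'f' must equal 1")
  structure(list(w = w, area = area, a = a, provenance = provenance),
            class = "decoder_spec")
}

#' @export
print.decoder_spec <- function(x, ...) {
  cat(sprintf("Linear decoder (%s): %d neurons, %d area(s)\n",
              x$provenance, length(x$w), length(unique(x$area))))
  if (length(x$a) > 1L) {
    cat("  scaling factors a:\n")
    print(round(x$a, 4))
  }
  invisible(x)
}

get_sigma <- function(cov) {
  if (inherits(cov, "covariance_model")) cov$Sigma else as.matrix(cov)
}
get_weights <- function(decoder) {
  if (inherits(decoder, "decoder_spec")) decoder$w else as.numeric(decoder)
}

#' Locally optimal unbiased linear readout
#'
#' \eqn{w = \Sigma^{-1} f' / (f'^T \Sigma^{-1} f')}, the linear-regression
#' weights normalised for unbiasedness. Singular covariances fall back to
#' the pseudo-inverse with a warning.
#'
#' @param cov a \code{"covariance_model"} or covariance matrix.
#' @param deriv tuning derivative vector f' (must be nonzero).
#' @return A \code{"decoder_spec"} with provenance "optimal".
#' @export
optimal_weights <- function(cov, deriv) {
  Sigma <- get_sigma(cov)
  if (all(deriv == 0)) stop("no signal: f' is identically zero")
  si <- solve_or_ginv(Sigma, deriv)
  w <- as.numeric(si) / drop(crossprod(deriv, si))
  area <- if (inherits(cov, "covariance_model")) cov$area else "pop1"
  decoder_spec(w, area = area, a = area_scalings(w, area, deriv),
               provenance = "optimal", deriv = deriv)
}

# decompose global unbiased weights into per-area scalings a_x = w_x'f'_x
area_scalings <- function(w, area, deriv) {
  if (length(area) == 1L) area <- rep(area, length(w))
  areas <- unique(area)
  a <- vapply(areas, function(z) sum(w[area == z] * deriv[area == z]),
              numeric(1))
  names(a) <- areas
  a
}

#' Optimal readout restricted to leading covariance eigenmodes
#'
#' Projects the signal and the covariance onto the span of the leading p
#' eigenvectors of \eqn{\Sigma}, computes the optimal unbiased weights in
#' that subspace and maps them back to neuron space. \code{p = N}
#' reproduces \code{\link{optimal_weights}}; \code{p = 1} reads out only
#' the largest noise mode.
#'
#' @inheritParams optimal_weights
#' @param p subspace dimension, between 1 and N.
#' @return A \code{"decoder_spec"} with provenance "subspace-p".
#' @export
subspace_weights <- function(cov, deriv, p) {
  Sigma <- get_sigma(cov)
  N <- nrow(Sigma)
  p <- as.integer(p)
  if (p < 1L || p > N) stop("'p' must lie between 1 and N")
  e <- eigen(Sigma, symmetric = TRUE)
  U <- e$vectors[, seq_len(p), drop = FALSE]
  fp <- drop(crossprod(U, deriv))
  if (sqrt(sum(fp^2)) < 1e-12 * sqrt(sum(deriv^2)))
    stop("projected signal is zero in the decoded subspace")
  Sp <- diag(e$values[seq_len(p)], p)
  sp <- solve(Sp, fp)
  wp <- sp / drop(crossprod(fp, sp))
  w <- drop(U %*% wp)
  area <- if (inherits(cov, "covariance_model")) cov$area else "pop1"
  decoder_spec(w, area = area, a = area_scalings(w, area, deriv),
               provenance = paste0("subspace-", p), deriv = deriv)
}

#' Leading-mode decoder with explicit area scalings
#'
#' Builds the coarse readout in which each area contributes through its
#' leading noise mode only: \eqn{w_x = u_x / (f_x'^T u_x)} (unbiased per
#' area), combined with scaling factors a.
#'
#' @param coarse a \code{"coarse_noise"} carrying the mode matrix U.
#' @param pop the matching population.
#' @param a per-area scaling factors, summing to 1 (renormalised if not).
#' @return A \code{"decoder_spec"} with provenance "mode".
#' @export
mode_decoder <- function(coarse, pop, a) {
  stopifnot(inherits(coarse, "coarse_noise"),
            inherits(pop, "neural_population"))
  if (is.null(coarse$U)) stop("'coarse' carries no mode matrix U")
  areas <- coarse$areas
  if (is.null(names(a))) names(a) <- areas
  a <- a[areas] / sum(a[areas])
  w <- numeric(pop$n)
  for (z in seq_along(areas)) {
    idx <- which(pop$area == areas[z])
    u <- coarse$U[idx, z]
    w[idx] <- a[z] * u / sum(u * pop$deriv[idx])
  }
  decoder_spec(w, area = pop$area, a = a, provenance = "mode",
               deriv = pop$deriv)
}

#' Discrimination threshold of a decoder
#'
#' The 68-percent-correct threshold equals the standard deviation of the
#' unbiased estimate: \eqn{\vartheta = \sqrt{w^T \Sigma w}}.
#'
#' @param decoder a \code{"decoder_spec"} or weight vector.
#' @param cov a \code{"covariance_model"} or covariance matrix.
#' @param criterion optional multiplier for alternative percent-correct
#'   criteria (default 1, the 68\% convention).
#' @return Threshold in stimulus units.
#' @export
estimator_threshold <- function(decoder, cov, criterion = 1) {
  w <- get_weights(decoder)
  Sigma <- get_sigma(cov)
  if (length(w) != nrow(Sigma)) stop("dimension mismatch")
  criterion * sqrt(drop(crossprod(w, Sigma %*% w)))
}

#' Single-neuron discrimination thresholds
#'
#' \eqn{\vartheta_k = \sigma_k / |f_k'|}, the inverse square root of each
#' neuron's linear Fisher information. Untuned neurons (f' = 0) get an
#' infinite threshold and are flagged with a warning.
#'
#' @param pop a \code{"neural_population"}.
#' @return Vector of per-neuron thresholds (stimulus units).
#' @export
neuronal_thresholds <- function(pop) {
  stopifnot(inherits(pop, "neural_population"))
  th <- sqrt(pop$sigma2) / abs(pop$deriv)
  if (any(!is.finite(th)))
    warning(sum(!is.finite(th)),
            " untuned neuron(s) with non-finite threshold")
  th
}

#' Choice correlations implied by a decoder
#'
#' \eqn{C_k = (\Sigma w)_k / (\sigma_k \sqrt{w^T \Sigma w})}: the
#' trial-by-trial correlation between neuron k's response and the
#' continuous stimulus estimate, at fixed stimulus.
#'
#' @inheritParams estimator_threshold
#' @return Vector of per-neuron choice correlations in [-1, 1].
#' @export
choice_correlations <- function(decoder, cov) {
  w <- get_weights(decoder)
  Sigma <- get_sigma(cov)
  v <- drop(crossprod(w, Sigma %*% w))
  if (v <= 0) stop("degenerate decoder: zero output variance")
  drop(Sigma %*% w) / (sqrt(diag(Sigma)) * sqrt(v))
}

#' Choice correlations expected under optimal decoding
#'
#' \eqn{C_{k,opt} = \mathrm{sgn}(f_k') \, \vartheta / \vartheta_k}, the
#' signed ratio of behavioural to neuronal threshold (sign convention:
#' positive when the neuron predicts rightward choices by increasing its
#' rate).
#'
#' @param pop a \code{"neural_population"}.
#' @param threshold behavioural threshold \eqn{\vartheta} (> 0).
#' @return Vector of optimal choice correlations.
#' @export
optimal_choice_correlations <- function(pop, threshold) {
  if (threshold <= 0) stop("'threshold' must be positive")
  sign(pop$deriv) * threshold / neuronal_thresholds(pop)
}

#' Eigenmode decomposition of suboptimal choice correlations
#'
#' Writes a decoder as \eqn{w = \Sigma^{-1} g / (f'^T \Sigma^{-1} g)} and
#' decomposes its choice correlations over the covariance eigenmodes
#' \eqn{u^i}: \eqn{C = \sum_i \beta_i C^i_{opt}} with per-mode patterns
#' \eqn{C^i_{opt} = \vartheta\, S^{-1} u^i (u^{iT} f')} (which sum to the
#' optimal pattern) and multipliers
#' \eqn{\beta_i = (g^T u^i) / ((f'^T u^i)(f'^T \Sigma^{-1} g)
#' \vartheta^2)}. Optimal decoding (g = f') gives \eqn{\beta_i = 1} for
#' every mode; decoding a single mode zeroes every other multiplier.
#'
#' @param g readout direction in covariance units (length N), or a
#'   \code{"decoder_spec"} whose g is recovered as \eqn{\Sigma w} up to
#'   scale.
#' @param cov a \code{"covariance_model"} or covariance matrix.
#' @param deriv tuning derivative vector f'.
#' @return List with \code{beta} (per-mode multipliers; NA for modes with
#'   \eqn{u^{iT} f' = 0}, whose multiplier is undefined), \code{C_opt}
#'   (N x N matrix of per-mode optimal patterns, summing over columns to
#'   the optimal choice correlations), \code{contributions} (N x N matrix
#'   of \eqn{\beta_i C^i_{opt}}, defined jointly for every mode), and
#'   \code{C} (the reconstructed choice correlations).
#' @export
eigenmode_betas <- function(g, cov, deriv) {
  Sigma <- get_sigma(cov)
  if (inherits(g, "decoder_spec")) g <- drop(Sigma %*% g$w)
  g <- as.numeric(g)
  fsg <- drop(crossprod(deriv, solve_or_ginv(Sigma, g)))
  if (abs(fsg) < 1e-12 * sqrt(sum(deriv^2)) * sqrt(sum(g^2)))
    stop("f' and g are orthogonal in the inverse-covariance metric; ",
         "the unbiased normalisation is undefined")
  w <- as.numeric(solve_or_ginv(Sigma, g)) / fsg
  th2 <- drop(crossprod(w, Sigma %*% w))
  th <- sqrt(th2)
  e <- eigen(Sigma, symmetric = TRUE)
  U <- e$vectors
  # sign convention u.f' >= 0 (modes orthogonal to f' left as returned)
  flip <- drop(crossprod(U, deriv)) < 0
  U[, flip] <- -U[, flip]
  uf <- drop(crossprod(U, deriv))
  ug <- drop(crossprod(U, g))
  ok <- abs(uf) > 1e-12 * sqrt(sum(deriv^2))
  beta <- rep(NA_real_, length(g))
  beta[ok] <- ug[ok] / (uf[ok] * fsg * th2)
  S_inv <- 1 / sqrt(diag(Sigma))
  n <- length(g)
  C_opt <- th * (S_inv * U) * rep(uf, each = n)
  # beta_i * C_opt^i = (g'u^i) S^-1 u^i / (fsg * th): finite for every mode
  contributions <- (S_inv * U) * rep(ug / (fsg * th), each = n)
  list(beta = beta, C_opt = C_opt, contributions = contributions,
       C = rowSums(contributions))
}

#' Root-mean-squared choice correlation of a decoder
#'
#' @inheritParams estimator_threshold
#' @return Scalar RMS of the per-neuron choice correlations.
#' @export
rms_choice_correlation <- function(decoder, cov) {
  sqrt(mean(choice_correlations(decoder, cov)^2))
}
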