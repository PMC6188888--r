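#' Grand choice probability per neuron
#'
#' For each stimulus level with at least \code{min_choices_per_side} choices
#' in each direction, responses are split by the animal's choice (rightward
#' vs leftward), balanced z-scored within the level (centred on the
#' unweighted mean of the two choice-group means and scaled by the
#' unweighted mean of the two choice-group SDs, so that both groups weigh
#' equally regardless of choice imbalance), pooled across levels, and the
#' grand CP is the rank-based area under the ROC curve
#' \eqn{P(r^+ > r^-)} with ties counted half.
#'
#' Neurons for which no stimulus level passes the minimum-choice criterion
#' get \code{NA} (flagged) and should be excluded from slope fits.
#'
#' @param trials a \code{"trial_table"} with binary choices.
#' @param min_choices_per_side minimum choices in each direction for a
#'   stimulus level to contribute (default 3).
#' @return Named numeric vector of per-neuron CPs in [0, 1], with attribute
#'   \code{"n_used"} giving per-neuron usable-trial counts.
#' @export
choice_probability <- function(trials, min_choices_per_side = 3L) {
  if (!all(trials$choice %in% c(-1L, 1L)))
    stop("'choice' must be coded -1/+1")
  r <- trial_responses(trials)
  n_neuron <- ncol(r)
  levels_s <- unique(trials$stimulus)
  cp <- rep(NA_real_, n_neuron)
  n_used <- integer(n_neuron)
  names(cp) <- colnames(r)
  # which levels are usable is common to all neurons
  usable <- vapply(levels_s, function(s) {
    ch <- trials$choice[trials$stimulus == s]
    sum(ch > 0) >= min_choices_per_side && sum(ch < 0) >= min_choices_per_side
  }, TRUE)
  if (!any(usable)) {
    warning("no stimulus level satisfies the minimum-choice criterion; ",
            "CP undefined for all neurons")
    attr(cp, "n_used") <- n_used
    return(cp)
  }
  for (k in seq_len(n_neuron)) {
    zp <- numeric(0); zm <- numeric(0)
    for (s in levels_s[usable]) {
      idx <- trials$stimulus == s
      rp <- r[idx & trials$choice > 0, k]
      rm <- r[idx & trials$choice < 0, k]
      mu <- (mean(rp) + mean(rm)) / 2
      sd2 <- (stats::sd(rp) + stats::sd(rm)) / 2
      if (!is.finite(sd2) || sd2 == 0) sd2 <- 1  # degenerate level: centre only
      zp <- c(zp, (rp - mu) / sd2)
      zm <- c(zm, (rm - mu) / sd2)
    }
    cp[k] <- rank_auc(zp, zm)
    n_used[k] <- length(zp) + length(zm)
  }
  attr(cp, "n_used") <- n_used
  cp
}

# P(x > y) with ties counted half: Mann-Whitney AUC via mean ranks.
rank_auc <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) return(NA_real_)
  rk <- rank(c(x, y))
  (sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Convert choice probability to choice correlation
#'
#' Small-correlation linearisation \eqn{C = (\pi/\sqrt 2)(CP - 1/2)} under
#' joint Gaussianity of response and estimate, clipped to [-1, 1].
#'
#' @param cp choice probabilities in [0, 1].
#' @return Choice correlations in [-1, 1].
#' @seealso \code{\link{cc_to_cp}} for the inverse map.
#' @export
cp_to_cc <- function(cp) {
  if (any(cp < 0 | cp > 1, na.rm = TRUE)) stop("CP must lie in [0, 1]")
  pmin(pmax((pi / sqrt(2)) * (cp - 0.5), -1), 1)
}

#' Convert choice correlation to choice probability
#' @param cc choice correlations in [-1, 1].
#' @return Choice probabilities.
#' @export
cc_to_cp <- function(cc) {
  if (any(abs(cc) > 1, na.rm = TRUE)) stop("CC must lie in [-1, 1]")
  0.5 + cc * sqrt(2) / pi
}

#' Correlation between response and binary choice
#'
#' Under joint Gaussianity, the correlation of a neuron's response with the
#' sign of the estimate is attenuated relative to its choice correlation:
#' \eqn{\mathrm{Corr}(r_k, \mathrm{sgn}(\hat s)) = \sqrt{2/\pi}\, C_k
#' \approx 0.8\, C_k}.
#'
#' @param cc choice correlations (with the continuous estimate).
#' @return Predicted correlations with the binary choice.
#' @seealso \code{\link{empirical_binary_cc}} for the Monte-Carlo estimator.
#' @export
binary_choice_correlation <- function(cc) {
  if (any(abs(cc) > 1, na.rm = TRUE)) stop("CC must lie in [-1, 1]")
  sqrt(2 / pi) * cc
}

#' Empirical correlation of responses with the binary choice
#'
#' Monte-Carlo counterpart of \code{\link{binary_choice_correlation}}:
#' \eqn{\mathrm{Corr}(r_k, \mathrm{sgn}(\hat s))} computed over a trial
#' table, per stimulus level and pooled by Fisher-free averaging weighted
#' by trial counts.
#'
#' @param trials a \code{"trial_table"}.
#' @return Per-neuron correlations with the choice.
#' @export
empirical_binary_cc <- function(trials) {
  r <- trial_responses(trials)
  levels_s <- unique(trials$stimulus)
  acc <- matrix(0, length(levels_s), ncol(r))
  wt <- numeric(length(levels_s))
  for (i in seq_along(levels_s)) {
    idx <- trials$stimulus == levels_s[i]
    ch <- trials$choice[idx]
    if (length(unique(ch)) < 2L) next
    acc[i, ] <- apply(r[idx, , drop = FALSE], 2, stats::cor, y = ch)
    wt[i] <- sum(idx)
  }
  drop(crossprod(acc, wt)) / sum(wt)
}

#' Slope of observed vs optimal choice correlations
#'
#' Fits the per-area multiplier \eqn{\beta} relating measured choice
#' correlations to the optimal prediction \eqn{\vartheta/\vartheta_k}, by
#' least squares through the origin (the theory predicts pure
#' proportionality; a free intercept is available). The confidence interval
#' is a percentile bootstrap over neurons.
#'
#' @param c_obs observed per-neuron choice correlations.
#' @param c_opt optimal per-neuron choice correlations (same length).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @param intercept fit a free intercept instead of through-origin.
#' @return List with \code{beta}, \code{ci} (length 2), \code{r} (Pearson
#'   correlation), \code{n} (neurons used) and \code{intercept} (if fitted).
#' @export
fit_cc_slope <- function(c_obs, c_opt, n_boot = 1000L, seed = 1L,
                         conf = 0.95, intercept = FALSE) {
  ok <- is.finite(c_obs) & is.finite(c_opt)
  c_obs <- c_obs[ok]; c_opt <- c_opt[ok]
  n <- length(c_obs)
  if (n < 2L) stop("need at least 2 finite paired choice correlations")
  if (all(c_opt == 0)) stop("all optimal choice correlations are zero")
  slope_fun <- if (intercept) {
    function(x, y) unname(stats::coef(stats::lm(y ~ x))[2])
  } else {
    function(x, y) sum(x * y) / sum(x * x)
  }
  beta <- slope_fun(c_opt, c_obs)
  icpt <- if (intercept) unname(stats::coef(stats::lm(c_obs ~ c_opt))[1])
          else 0
  set.seed(as.integer(seed))
  bs <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    if (all(c_opt[idx] == 0)) return(NA_real_)
    slope_fun(c_opt[idx], c_obs[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
  r <- if (stats::sd(c_obs) > 0 && stats::sd(c_opt) > 0)
    stats::cor(c_obs, c_opt) else NA_real_
  list(beta = beta, ci = ci, r = r, n = n, intercept = icpt)
}

#' Per-area choice statistics from a trial table
#'
#' Convenience pipeline: grand CPs, their conversion to choice
#' correlations, and per-area slopes against the optimal prediction built
#' from the population's neuronal thresholds and the behavioural threshold
#' measured from the estimates in the table (or supplied).
#'
#' @param trials a \code{"trial_table"}.
#' @param pop the generating \code{"neural_population"}.
#' @param threshold behavioural threshold; default: SD of the estimate at
#'   the reference stimulus.
#' @param min_choices_per_side passed to \code{\link{choice_probability}}.
#' @param n_boot,seed passed to \code{\link{fit_cc_slope}}.
#' @return List of class \code{"choice_stats"}: per-neuron \code{cp},
#'   \code{cc}, \code{cc_opt}, behavioural \code{threshold} and per-area
#'   \code{slopes} (list of \code{\link{fit_cc_slope}} results).
#' @export
choice_stats <- function(trials, pop, threshold = NULL,
                         min_choices_per_side = 3L,
                         n_boot = 1000L, seed = 1L) {
  if (is.null(threshold)) {
    at_ref <- trials$stimulus == pop$s0
    if (!any(at_ref)) at_ref <- rep(TRUE, nrow(trials))
    if (!"estimate" %in% names(trials))
      stop("'threshold' must be supplied when the table has no estimates")
    threshold <- stats::sd(trials$estimate[at_ref])
  }
  cp <- choice_probability(trials, min_choices_per_side)
  cc <- cp_to_cc(cp)
  cc_opt <- optimal_choice_correlations(pop, threshold)
  slopes <- lapply(area_levels(pop), function(z) {
    idx <- pop$area == z
    fit_cc_slope(cc[idx], cc_opt[idx], n_boot = n_boot, seed = seed)
  })
  names(slopes) <- area_levels(pop)
  structure(list(cp = cp, cc = cc, cc_opt = cc_opt,
                 threshold = threshold, slopes = slopes,
                 areas = area_levels(pop)),
            class = "choice_stats")
}

#' @export
print.choice_stats <- function(x, ...) {
  cat("Choice statistics:", length(x$cp), "neurons;",
      sum(is.na(x$cp)), "with undefined CP\n")
  cat(sprintf("  behavioural threshold: %.4g\n", x$threshold))
  for (z in x$areas) {
    s <- x$slopes[[z]]
    cat(sprintf("  area %-8s beta = %.3f  [%.3f, %.3f]  (r = %.2f, n = %d)\n",
                z, s$beta, s$ci[1], s$ci[2], s$r, s$n))
  }
  invisible(x)
}
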