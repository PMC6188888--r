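#' Tuning parameters for a synthetic heading-tuned population
#'
#' Bundles the generative parameters of a von Mises population:
#' \eqn{f_i(s) = b_i + h_i e^{\kappa_i \cos(s - s_i)}}, with baselines
#' \eqn{b_i \sim \mathrm{Poisson}(\bar b)}, heights
#' \eqn{h_i \sim \mathrm{Poisson}(\bar h)}, concentrations
#' \eqn{\kappa_i \sim |N(\mu_\kappa, \sigma_\kappa^2)|} and preferred
#' stimuli uniform on the stimulus domain.
#'
#' @param n_neurons number of neurons (positive integer).
#' @param baseline_mean mean baseline rate \eqn{\bar b} (spikes/s).
#' @param height_mean mean tuning height \eqn{\bar h} (spikes/s).
#' @param kappa_mean,kappa_sd mean and standard deviation of the normal from
#'   which concentrations are drawn before rectification (dimensionless).
#' @param stimulus_domain length-2 interval of the stimulus variable.
#'   Defaults to the circular domain \eqn{(-\pi, \pi]} (radians); heading
#'   tasks may instead use a linear domain in degrees around 0.
#' @param circular logical; is the stimulus variable circular on the domain?
#' @param reference_stimulus reference \eqn{s_0} at which derivatives and
#'   variances are evaluated.
#'
#' @return An object of class \code{"tuning_params"}.
#' @export
tuning_params <- function(n_neurons,
                          baseline_mean = 5,
                          height_mean = 15,
                          kappa_mean = 1,
                          kappa_sd = 0.5,
                          stimulus_domain = c(-pi, pi),
                          circular = TRUE,
                          reference_stimulus = 0) {
  n_neurons <- as.integer(n_neurons)
  if (is.na(n_neurons) || n_neurons < 1L)
    stop("'n_neurons' must be a positive integer")
  if (baseline_mean < 0 || height_mean < 0)
    stop("'baseline_mean' and 'height_mean' must be non-negative")
  if (length(stimulus_domain) != 2L || diff(stimulus_domain) <= 0)
    stop("'stimulus_domain' must be an increasing length-2 interval")
  structure(
    list(n_neurons = n_neurons,
         baseline_mean = baseline_mean,
         height_mean = height_mean,
         kappa_mean = kappa_mean,
         kappa_sd = kappa_sd,
         stimulus_domain = as.numeric(stimulus_domain),
         circular = isTRUE(circular),
         reference_stimulus = reference_stimulus),
    class = "tuning_params")
}

#' Draw a synthetic neural population
#'
#' Samples per-neuron tuning parameters from a \code{\link{tuning_params}}
#' specification and evaluates, at the reference stimulus, the mean rate
#' \eqn{f_i(s_0)}, the analytic tuning derivative \eqn{f_i'(s_0)} and the
#' Poisson-like noise variance \eqn{\sigma_i^2 = f_i(s_0)} (variances equal
#' mean responses).
#'
#' @param params a \code{\link{tuning_params}} object.
#' @param seed integer seed; identical seeds give identical populations.
#' @param area area label(s): a single label or a character vector of length
#'   \code{n_neurons} partitioning neurons into areas.
#'
#' @return An object of class \code{"neural_population"}: a list with
#'   per-neuron fields \code{b}, \code{h}, \code{kappa}, \code{pref},
#'   \code{f0}, \code{deriv}, \code{sigma2}, the partition \code{area} and
#'   the generative parameters.
#' @seealso \code{\link{tuning_curve}}, \code{\link{simulate_trials}}
#' @export
build_population <- function(params, seed = 1L, area = "pop1") {
  stopifnot(inherits(params, "tuning_params"))
  n <- params$n_neurons
  if (length(area) == 1L) area <- rep(as.character(area), n)
  if (length(area) != n) stop("'area' must have length 1 or n_neurons")
  set.seed(as.integer(seed))
  b <- stats::rpois(n, params$baseline_mean)
  h <- stats::rpois(n, params$height_mean)
  # a neuron with b = h = 0 has zero mean rate and zero variance; redraw
  dead <- which(b + h == 0)
  while (length(dead) > 0L) {
    b[dead] <- stats::rpois(length(dead), params$baseline_mean)
    h[dead] <- stats::rpois(length(dead), params$height_mean)
    if (params$baseline_mean + params$height_mean == 0) {
      b[dead] <- 1  # fully flat spec: keep a positive variance
      break
    }
    dead <- which(b + h == 0)
  }
  kappa <- abs(stats::rnorm(n, params$kappa_mean, params$kappa_sd))
  dom <- params$stimulus_domain
  pref <- stats::runif(n, dom[1], dom[2])
  s0 <- params$reference_stimulus
  pop <- structure(
    list(n = n, area = as.character(area),
         b = b, h = h, kappa = kappa, pref = pref,
         s0 = s0, domain = dom, circular = params$circular,
         params = params),
    class = "neural_population")
  pop$f0 <- as.numeric(tuning_curve(pop, s0))
  pop$deriv <- as.numeric(tuning_derivative(pop, s0))
  pop$sigma2 <- pop$f0
  pop
}

#' Evaluate population tuning curves
#'
#' @param pop a \code{"neural_population"}.
#' @param s numeric vector of stimulus values.
#' @return A \code{length(s) x n} matrix of mean rates \eqn{f_i(s)}.
#' @export
tuning_curve <- function(pop, s) {
  stopifnot(inherits(pop, "neural_population"))
  d <- outer(s, pop$pref, "-")
  f <- sweep(exp(sweep(cos(d), 2, pop$kappa, "*")), 2, pop$h, "*")
  sweep(f, 2, pop$b, "+")
}

#' Analytic derivative of the tuning curves
#'
#' \eqn{f_i'(s) = -h_i \kappa_i \sin(s - s_i) e^{\kappa_i \cos(s - s_i)}}.
#'
#' @inheritParams tuning_curve
#' @return A \code{length(s) x n} matrix of derivatives.
#' @export
tuning_derivative <- function(pop, s) {
  stopifnot(inherits(pop, "neural_population"))
  d <- outer(s, pop$pref, "-")
  e <- exp(sweep(cos(d), 2, pop$kappa, "*"))
  -sweep(sin(d) * e, 2, pop$h * pop$kappa, "*")
}

#' Area labels of a population, in order of first appearance
#' @param pop a \code{"neural_population"} or object carrying \code{$area}.
#' @return character vector of distinct area labels.
#' @export
area_levels <- function(pop) unique(pop$area)

#' @export
print.neural_population <- function(x, ...) {
  areas <- table(factor(x$area, levels = area_levels(x)))
  cat("Synthetic neural population:", x$n, "neurons in",
      length(areas), "area(s)\n")
  for (a in names(areas))
    cat(sprintf("  %-8s %4d neurons\n", a, areas[[a]]))
  cat(sprintf("  reference stimulus s0 = %g; domain [%g, %g]%s\n",
              x$s0, x$domain[1], x$domain[2],
              if (x$circular) " (circular)" else ""))
  cat(sprintf("  mean rate at s0: %.2f spikes/s (range %.2f-%.2f)\n",
              mean(x$f0), min(x$f0), max(x$f0)))
  invisible(x)
}

#' Stack populations from several areas into one
#'
#' Convenience for building multi-area populations with different generative
#' parameters per area. All populations must share the stimulus domain and
#' reference stimulus.
#'
#' @param ... \code{"neural_population"} objects with distinct area labels.
#' @return A single \code{"neural_population"}.
#' @export
combine_populations <- function(...) {
  pops <- list(...)
  stopifnot(length(pops) >= 1L,
            all(vapply(pops, inherits, TRUE, "neural_population")))
  ref <- pops[[1]]
  for (p in pops[-1]) {
    if (!isTRUE(all.equal(p$domain, ref$domain)) || p$s0 != ref$s0 ||
        p$circular != ref$circular)
      stop("populations must share stimulus domain and reference stimulus")
  }
  fields <- c("area", "b", "h", "kappa", "pref", "f0", "deriv", "sigma2")
  out <- ref
  for (f in fields) out[[f]] <- unlist(lapply(pops, `[[`, f), use.names = FALSE)
  out$n <- length(out$b)
  out$params <- lapply(pops, `[[`, "params")
  out
}
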