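#' Simulate trials from a population, noise model and decoder
#'
#' Draws single-trial responses from a multivariate Gaussian with mean
#' \eqn{f(s)} and the given noise covariance, forms the continuous estimate
#' \eqn{\hat s = w^T (r - f(s_0)) + s_0} and the binary choice
#' \eqn{\mathrm{sgn}(\hat s - s_0)} (ties assigned +1). Only the first two
#' response moments matter for the downstream analysis, so Gaussian draws
#' stand in for spike counts.
#'
#' @param pop a \code{"neural_population"}.
#' @param cov a \code{"covariance_model"} matching the population.
#' @param decoder a \code{"decoder_spec"} (unbiased: w'f' = 1).
#' @param stimuli vector of stimulus values to present.
#' @param n_trials_per_stimulus trials per stimulus value.
#' @param seed integer seed; identical seeds give identical tables.
#' @return A \code{data.frame} of class \code{"trial_table"} with columns
#'   \code{trial_id}, \code{stimulus}, \code{choice}, \code{estimate} and
#'   one response column \code{r_0001}... per neuron (spikes/s).
#' @export
simulate_trials <- function(pop, cov, decoder, stimuli,
                            n_trials_per_stimulus, seed = 1L) {
  stopifnot(inherits(pop, "neural_population"))
  Sigma <- get_sigma(cov)
  if (nrow(Sigma) != pop$n) stop("covariance dimension mismatch")
  w <- get_weights(decoder)
  if (abs(sum(w * pop$deriv) - 1) > 1e-6)
    stop("decoder is not unbiased: w'f' must equal 1")
  set.seed(as.integer(seed))
  n_per <- as.integer(n_trials_per_stimulus)
  f0 <- pop$f0
  out <- vector("list", length(stimuli))
  for (i in seq_along(stimuli)) {
    s <- stimuli[i]
    mu <- drop(tuning_curve(pop, s))
    r <- if (max(abs(Sigma)) == 0) {
      matrix(mu, n_per, pop$n, byrow = TRUE)
    } else {
      MASS::mvrnorm(n_per, mu = mu, Sigma = Sigma)
    }
    if (n_per == 1L) r <- matrix(r, 1L)
    est <- drop(r %*% w) - sum(f0 * w) + pop$s0
    out[[i]] <- data.frame(stimulus = s, estimate = est,
                           choice = ifelse(est >= pop$s0, 1L, -1L))
    out[[i]] <- cbind(out[[i]], r)
  }
  tab <- do.call(rbind, out)
  resp_names <- sprintf("r_%04d", seq_len(pop$n))
  names(tab) <- c("stimulus", "estimate", "choice", resp_names)
  tab <- cbind(trial_id = seq_len(nrow(tab)),
               tab[, c("stimulus", "choice", "estimate", resp_names)])
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Response matrix of a trial table
#' @param trials a \code{"trial_table"} data frame.
#' @return Numeric matrix, trials x neurons.
#' @export
trial_responses <- function(trials) {
  as.matrix(trials[, grep("^r_\\d+$", names(trials)), drop = FALSE])
}

#' Write a trial table as CSV
#'
#' Columns \code{trial_id, stimulus, choice, estimate, r_0001, ...}; header
#' mandatory, UTF-8, '.' decimal. Floats carry full precision so the file
#' round-trips bit-identically.
#'
#' @param trials a \code{"trial_table"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  tab <- as.data.frame(trials)
  num <- vapply(tab, is.double, TRUE)
  tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(tab, utf8, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#' @param path CSV file written by \code{\link{write_trial_table}} (or any
#'   CSV with the same column layout).
#' @return A \code{"trial_table"} data frame.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, encoding = "UTF-8")
  need <- c("trial_id", "stimulus", "choice")
  if (!all(need %in% names(tab)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  class(tab) <- c("trial_table", "data.frame")
  tab
}
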