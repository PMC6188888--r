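#' Write an inactivation design as JSON
#'
#' One record per experiment: \code{rho} as a per-area map, the observed
#' \code{threshold}, and optionally a per-area \code{beta} map (unmeasured
#' slopes omitted).
#'
#' @param design an \code{\link{inactivation_design}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "inactivation_design"))
  experiments <- lapply(seq_len(nrow(design$rho)), function(i) {
    rec <- list(rho = as.list(design$rho[i, ]),
                threshold = design$threshold[i])
    if (!is.null(design$beta)) {
      b <- design$beta[i, ]
      b <- b[is.finite(b)]
      if (length(b)) rec$beta <- as.list(b)
    }
    rec
  })
  jsonlite::write_json(list(areas = design$areas, experiments = experiments),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an inactivation design from JSON
#' @param path file written by \code{\link{write_design_json}} (or matching
#'   that schema).
#' @return An \code{\link{inactivation_design}}.
#' @export
read_design_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$experiments) || !length(obj$experiments))
    stop("design JSON must contain a non-empty 'experiments' list")
  areas <- if (!is.null(obj$areas)) unlist(obj$areas)
           else names(obj$experiments[[1]]$rho)
  get_row <- function(rec, field) {
    v <- rep(NA_real_, length(areas))
    names(v) <- areas
    got <- rec[[field]]
    if (!is.null(got)) v[names(got)] <- unlist(got)
    v
  }
  rho <- t(vapply(obj$experiments, get_row, numeric(length(areas)), "rho"))
  if (any(is.na(rho))) stop("every experiment must give rho for every area")
  threshold <- vapply(obj$experiments, function(r) {
    if (is.null(r$threshold)) stop("every experiment needs a threshold")
    as.numeric(r$threshold)
  }, numeric(1))
  has_beta <- any(vapply(obj$experiments,
                         function(r) !is.null(r$beta), TRUE))
  beta <- if (has_beta)
    t(vapply(obj$experiments, get_row, numeric(length(areas)), "beta"))
  else NULL
  colnames(rho) <- areas
  inactivation_design(rho, threshold, beta)
}

#' Write a fitted coarse decoder as JSON
#'
#' Serialises the scaling factors, the coarse noise matrix, residual
#' diagnostics and all distinct local optima.
#'
#' @param fit a \code{"decoder_scaling"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_scaling_json <- function(fit, path) {
  stopifnot(inherits(fit, "decoder_scaling"))
  jsonlite::write_json(
    list(areas = fit$design$areas,
         a = as.list(fit$a),
         E = unname(apply(fit$E$E, 1, as.list, simplify = FALSE)),
         residual_norm = fit$residual_norm,
         convergence = fit$convergence,
         beta_mode = fit$beta_mode,
         optima = fit$optima),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a decoder specification as JSON
#'
#' Areas, per-area weight vectors, scaling factors and provenance.
#'
#' @param decoder a \code{"decoder_spec"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_decoder_json <- function(decoder, path) {
  stopifnot(inherits(decoder, "decoder_spec"))
  areas <- unique(decoder$area)
  w_areas <- lapply(areas, function(z) decoder$w[decoder$area == z])
  names(w_areas) <- areas
  jsonlite::write_json(
    list(areas = areas, a = as.list(decoder$a), weights = w_areas,
         provenance = decoder$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a decoder specification from JSON
#' @param path file written by \code{\link{write_decoder_json}}.
#' @return A \code{"decoder_spec"}.
#' @export
read_decoder_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  areas <- obj$areas
  w <- unlist(obj$weights[areas], use.names = FALSE)
  area <- rep(areas, vapply(obj$weights[areas], length, 1L))
  decoder_spec(w, area = area, a = unlist(obj$a)[areas],
               provenance = obj$provenance)
}

#' Write a covariance model as CSV with a JSON sidecar
#'
#' Dense CSV of the covariance plus a sidecar recording the partition and
#' model tag, so the pair round-trips.
#'
#' @param cov a \code{"covariance_model"}.
#' @param path CSV path; the sidecar is \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_covariance <- function(cov, path) {
  stopifnot(inherits(cov, "covariance_model"))
  m <- matrix(sprintf("%.17g", cov$Sigma), nrow(cov$Sigma))
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(area = cov$area, model = cov$model),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a covariance model written by \code{\link{write_covariance}}
#' @param path CSV path with JSON sidecar.
#' @return A \code{"covariance_model"}.
#' @export
read_covariance <- function(path) {
  Sigma <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(Sigma) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  covariance_model(Sigma, side$area, model = side$model, check = FALSE)
}
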