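#' Printed calibration pairs between structure size and Delta-L
#'
#' The nine (nucleotides, Delta-L) pairs reported for the hTERT promoter
#' constructs: the 3/5/7-nt inter-quadruplex releases, the 14-nt G-triplex
#' intermediate, the 18-nt 5'-quadruplex (with the 21-nt cooperative
#' signature), the 25-nt size, and the 48-nt and 68-nt fully folded states.
#'
#' @return A data.frame with columns `n_nt` and `delta_l_nm`.
#' @export
default_calibration_pairs <- function() {
  data.frame(
    n_nt = c(3, 5, 7, 14, 18, 21, 25, 48, 68),
    delta_l_nm = c(1.2, 1.7, 2.5, 4.9, 6.3, 7.5, 8.4, 18, 25)
  )
}

#' Calibrate the Delta-L to nucleotide conversion
#'
#' Fits the straight-line map Delta-L = slope * N + intercept by least
#' squares over calibration pairs. The slope absorbs the effective ssDNA
#' contour per released nucleotide and the intercept the end-to-end
#' correction of the folded structure. With the default pairs the fit gives
#' slope ~0.371 nm/nt and intercept ~ -0.23 nm; individual pairs deviate by
#' up to ~0.65 nm, so the line is an effective calibration, not an exact law.
#'
#' @param pairs Data frame with columns `n_nt` and `delta_l_nm`; at least two
#'   distinct `n_nt` values are required.
#' @return An object of class `conversion_model` with elements `slope`
#'   (nm/nt), `intercept` (nm), `pairs`, `residuals` and `fitted`.
#' @export
calibrate_conversion <- function(pairs = default_calibration_pairs()) {
  stopifnot(is.data.frame(pairs),
            all(c("n_nt", "delta_l_nm") %in% names(pairs)))
  if (length(unique(pairs$n_nt)) < 2L)
    stop("degenerate calibration: need at least 2 distinct nucleotide counts",
         call. = FALSE)
  fit <- stats::lm(delta_l_nm ~ n_nt, data = pairs)
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pairs = pairs,
    residuals = unname(stats::resid(fit)),
    fitted = unname(stats::fitted(fit))
  )
  if (out$slope <= 0)
    stop("calibration produced a non-positive slope", call. = FALSE)
  class(out) <- "conversion_model"
  out
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf(
    "Delta-L conversion: dL = %.4f nm/nt * N %+.4f nm (%d pairs, max |res| %.2f nm)\n",
    x$slope, x$intercept, nrow(x$pairs), max(abs(x$residuals))))
  invisible(x)
}

#' Convert a contour-length change to a nucleotide count
#'
#' @param delta_l Delta-L values in nm (positive).
#' @param model A [calibrate_conversion()] model.
#' @param round If `TRUE` (default) round to the nearest whole nucleotide;
#'   otherwise return the unrounded estimate.
#' @return Nucleotide counts. Values that map below one nucleotide are
#'   returned as-is with a warning (sub-nucleotide release), not an error.
#' @export
delta_l_to_nt <- function(delta_l, model, round = TRUE) {
  stopifnot(inherits(model, "conversion_model"))
  if (any(delta_l <= 0))
    stop("delta_l must be positive", call. = FALSE)
  n <- (delta_l - model$intercept) / model$slope
  if (any(n < 1))
    warning("Delta-L maps below one nucleotide (sub-nucleotide release)",
            call. = FALSE)
  if (round) n <- round(n)
  n
}

#' Expected Delta-L for a structure of n nucleotides
#'
#' @param n Nucleotide counts (n >= 1; n = 0 returns the intercept with a
#'   warning since it is unphysical).
#' @inheritParams delta_l_to_nt
#' @return Delta-L in nm.
#' @export
nt_to_delta_l <- function(n, model) {
  stopifnot(inherits(model, "conversion_model"))
  if (any(n < 0)) stop("n must be non-negative", call. = FALSE)
  if (any(n == 0))
    warning("n = 0 is unphysical; returning the model intercept",
            call. = FALSE)
  model$slope * n + model$intercept
}

#' Serialise a conversion model to structured text
#'
#' Writes slope, intercept, calibration pairs and residuals as JSON.
#'
#' @param model A `conversion_model`.
#' @param path Output file path.
#' @export
write_conversion_model <- function(model, path) {
  stopifnot(inherits(model, "conversion_model"))
  jsonlite::write_json(
    list(slope = model$slope, intercept = model$intercept,
         pairs = model$pairs, residuals = model$residuals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_conversion_model
#' @export
read_conversion_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(slope = x$slope, intercept = x$intercept,
              pairs = as.data.frame(x$pairs),
              residuals = x$residuals,
              fitted = x$slope * x$pairs$n_nt + x$intercept)
  class(out) <- "conversion_model"
  out
}
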