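#' Worm-like-chain parameter set
#'
#' Parameters of the Marko-Siggia worm-like chain, optionally with an
#' enthalpic stretch modulus (extensible WLC). ssDNA released by unfolding is
#' modelled as an inextensible chain (persistence length ~0.8 nm, contour
#' 0.45 nm/nt); the dsDNA handles as an extensible chain (P = 50 nm,
#' K = 1200 pN, rise 0.338 nm/bp).
#'
#' @param persistence_length Persistence length in nm (> 0).
#' @param contour_length Contour length in nm (>= 0).
#' @param stretch_modulus Stretch modulus in pN; `Inf` disables the
#'   enthalpic term (inextensible chain).
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(persistence_length, contour_length,
                       stretch_modulus = Inf) {
  stopifnot(is.numeric(persistence_length), persistence_length > 0,
            is.numeric(contour_length), contour_length >= 0,
            is.numeric(stretch_modulus), stretch_modulus > 0)
  structure(list(persistence_length = persistence_length,
                 contour_length = contour_length,
                 stretch_modulus = stretch_modulus),
            class = "wlc_params")
}

# Marko-Siggia interpolation force at fractional extension u (inextensible)
ms_force <- function(u, persistence_length, constants) {
  (constants$kT / persistence_length) *
    (1 / (4 * (1 - u)^2) - 0.25 + u)
}

# Fractional extension of an inextensible Marko-Siggia chain at force F.
# Vectorised damped Newton iteration; the force law is strictly monotone in
# u on (0, 1) so this converges for any positive force.
wlc_phi <- function(force, persistence_length, constants) {
  out <- numeric(length(force))
  pos <- which(force > 0)
  if (!length(pos)) return(out)
  f <- force[pos]
  kTP <- constants$kT / persistence_length
  # high-force asymptotic start, clamped into the open interval
  u <- pmin(0.98, pmax(0.02, 1 - 0.5 * sqrt(kTP / f)))
  for (i in seq_len(100)) {
    g <- kTP * (1 / (4 * (1 - u)^2) - 0.25 + u) - f
    gp <- kTP * (1 / (2 * (1 - u)^3) + 1)
    step <- g / gp
    step <- pmax(pmin(step, 0.45 * (1 - u)), -0.45 * u)
    u <- u - step
    if (max(abs(g)) < 1e-12) break
  }
  out[pos] <- u
  out
}

#' Worm-like-chain force at a given extension
#'
#' Marko-Siggia interpolation formula, solved self-consistently when the
#' stretch modulus is finite:
#' \deqn{F = (k_BT/P)[1/(4(1-x/L+F/K)^2) - 1/4 + x/L - F/K].}
#'
#' @param extension Extension in nm (vectorised). For an inextensible chain
#'   the extension must satisfy `0 <= extension < contour_length`.
#' @param params A [wlc_params()] object.
#' @param constants A [physical_constants()] object.
#' @return Force in pN, strictly increasing in extension.
#' @export
wlc_force <- function(extension, params, constants = physical_constants()) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(extension < 0))
    stop("extension must be non-negative", call. = FALSE)
  L <- params$contour_length
  P <- params$persistence_length
  K <- params$stretch_modulus
  if (is.infinite(K)) {
    if (any(extension >= L))
      stop("extension must be below the contour length for an inextensible chain",
           call. = FALSE)
    return(ifelse(extension == 0, 0, ms_force(extension / L, P, constants)))
  }
  vapply(extension, function(x) {
    if (x == 0) return(0)
    fn <- function(f) f - ms_force(x / L - f / K, P, constants)
    # the entropic coordinate u = x/L - f/K must stay below 1, which bounds
    # the force from below when x exceeds the contour length; the residual
    # is negative at that bound and the upper end is expanded until it
    # changes sign
    lo <- max(0, (x / L - 1) * K) + 1e-8
    hi <- max(2 * lo + 10, 2 * abs(ms_force(min(x / L, 0.97), P, constants)))
    it <- 0
    while (fn(hi) < 0 && it < 60) { hi <- hi * 2; it <- it + 1 }
    if (fn(hi) < 0 || fn(lo) > 0)
      stop("self-consistent extensible WLC solve failed to bracket (x = ",
           signif(x, 6), " nm)", call. = FALSE)
    stats::uniroot(fn, c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
}

#' Worm-like-chain extension at a given force
#'
#' Inverse of [wlc_force()]. For the inextensible chain the fractional
#' extension is solved directly; the extensible chain adds the enthalpic
#' term `F/K`.
#'
#' @inheritParams wlc_force
#' @param force Force in pN (vectorised, non-negative).
#' @return Extension in nm; `wlc_force(wlc_extension(F))` recovers `F` to
#'   better than 1e-6 relative.
#' @export
wlc_extension <- function(force, params, constants = physical_constants()) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(force < 0))
    stop("force must be non-negative", call. = FALSE)
  phi <- wlc_phi(force, params$persistence_length, constants)
  if (is.infinite(params$stretch_modulus))
    params$contour_length * phi
  else
    params$contour_length * (phi + force / params$stretch_modulus)
}

#' Reversible stretching free energy of a worm-like chain
#'
#' Work required to stretch the chain quasi-statically from zero force to
#' `force`: \eqn{\Delta G = \int_0^{x(F)} F_{wlc}(x)\,dx}. Evaluated as
#' \eqn{L[F\phi(F) - \int_0^F \phi(f) df]} (plus \eqn{L F^2/2K} for the
#' extensible chain), with the integral by adaptive quadrature. Scales
#' linearly with contour length.
#'
#' @inheritParams wlc_extension
#' @return Free energy in pN nm.
#' @export
stretch_free_energy <- function(force, params,
                                constants = physical_constants()) {
  stopifnot(inherits(params, "wlc_params"))
  if (any(force < 0))
    stop("force must be non-negative", call. = FALSE)
  P <- params$persistence_length
  L <- params$contour_length
  vapply(force, function(f) {
    if (f == 0 || L == 0) return(0)
    Phi <- stats::integrate(function(g) wlc_phi(g, P, constants), 0, f,
                            rel.tol = 1e-9, abs.tol = 1e-12)$value
    g <- L * (f * wlc_phi(f, P, constants) - Phi)
    if (is.finite(params$stretch_modulus))
      g <- g + L * f^2 / (2 * params$stretch_modulus)
    g
  }, numeric(1))
}

# ---- cached fractional-extension profiles -------------------------------
#
# The simulator and the energetics module evaluate phi(F) and its integral
# on dense force grids; a spline profile per (persistence length, kT) pair
# avoids re-solving the chain at every call.
.profile_cache <- new.env(parent = emptyenv())

polymer_profile <- function(persistence_length, constants,
                            f_max = 160, step = 0.02) {
  key <- sprintf("%.8g_%.8g_%g_%g", persistence_length, constants$kT,
                 f_max, step)
  hit <- .profile_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- seq(0, f_max, by = step)
  phi <- wlc_phi(f, persistence_length, constants)
  Phi <- c(0, cumsum((phi[-1] + phi[-length(phi)]) / 2) * step)
  prof <- list(
    phi = stats::splinefun(f, phi, method = "hyman"),
    Phi = stats::splinefun(f, Phi, method = "hyman"),
    f_max = f_max
  )
  .profile_cache[[key]] <- prof
  prof
}

# fractional ssDNA extension and its stretch integral at force F
ssdna_phi <- function(force, constants, persistence_length = 0.8) {
  polymer_profile(persistence_length, constants)$phi(force)
}

ssdna_Phi <- function(force, constants, persistence_length = 0.8) {
  polymer_profile(persistence_length, constants)$Phi(force)
}
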