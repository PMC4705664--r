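#' Rupture-detection configuration
#'
#' @param window Running-median window (samples) for the extension-increment
#'   baseline; odd.
#' @param threshold Detection threshold in multiples of the median absolute
#'   deviation of the detrended extension increments.
#' @param min_jump_nm Absolute floor on the detectable extension jump;
#'   guards against a vanishing MAD on noise-free data.
#' @param fit_window Samples used on each side of a jump for the local
#'   linear fits that measure the jump height.
#' @param merge_df_pn Events closer than this in force are merged
#'   (instrument ringing protection).
#' @param min_force_pn,max_force_pn Force range searched for ruptures; the
#'   upper bound excludes the overstretching plateau.
#' @param min_se_nm Floor on the reported Delta-L standard error.
#' @return A list of class `detect_config`.
#' @export
detect_config <- function(window = 11, threshold = 5, min_jump_nm = 0.3,
                          fit_window = 15, merge_df_pn = 0.5,
                          min_force_pn = 2, max_force_pn = 55,
                          min_se_nm = 0.01) {
  stopifnot(window %% 2 == 1, window >= 3, threshold > 0,
            min_jump_nm > 0, fit_window >= 4)
  structure(list(window = window, threshold = threshold,
                 min_jump_nm = min_jump_nm, fit_window = fit_window,
                 merge_df_pn = merge_df_pn, min_force_pn = min_force_pn,
                 max_force_pn = max_force_pn, min_se_nm = min_se_nm),
            class = "detect_config")
}

#' Detect rupture events in a stretch trace
#'
#' Ruptures appear as discontinuous extension jumps at near-constant force.
#' The detector removes a running-median baseline from the sample-to-sample
#' extension increments and flags increments exceeding
#' `threshold * MAD` (with an absolute floor); each flagged jump is then
#' quantified by local linear fits of extension versus force on both sides,
#' and the jump height is converted to a change in contour length with
#' [delta_l_from_jump()]. Two noise figures accompany each event:
#' `delta_l_plateau_sd_nm`, the per-sample Delta-L noise scale inferred
#' from the fit residuals (the expected scatter of the corresponding
#' Delta-L versus force plateau), and `delta_l_se_nm`, the event-level
#' standard error after averaging over the fitted samples, which is the
#' appropriate kernel scale for population deconvolution.
#'
#' @param trace A stretch-direction [fx_trace()].
#' @param config A [detect_config()].
#' @param constants A [physical_constants()] object.
#' @param ss_persistence ssDNA persistence length (nm) used for the
#'   fractional-extension correction.
#' @return A data frame of events: molecule_id, cycle, rank, f_rupture_pn,
#'   delta_x_nm, delta_l_nm, delta_l_se_nm, low_force, assigned_state (NA).
#' @export
detect_ruptures <- function(trace, config = detect_config(),
                            constants = physical_constants(),
                            ss_persistence = 0.8) {
  stopifnot(inherits(trace, "fx_trace"))
  if (trace$direction != "stretch")
    stop("rupture detection expects a stretch-direction trace",
         call. = FALSE)
  x <- trace$samples$extension_nm
  f <- trace$samples$force_pn
  if (length(x) < config$window + 2 * config$fit_window)
    stop("trace shorter than the detection window", call. = FALSE)
  lo <- which(f >= config$min_force_pn)
  hi <- which(f <= config$max_force_pn)
  if (!length(lo) || !length(hi))
    stop("no samples inside the detection force range", call. = FALSE)
  i0 <- min(lo); i1 <- max(hi)
  idx <- i0:i1
  d <- diff(x[idx])
  base <- stats::runmed(d, config$window)
  resid <- d - base
  sigma <- stats::mad(resid)
  thr <- max(config$threshold * sigma, config$min_jump_nm)
  hits <- which(resid > thr)
  if (!length(hits)) return(empty_events(trace))

  # collapse adjacent flagged increments into single candidates
  groups <- split(hits, cumsum(c(1, diff(hits) > 2)))
  cand <- vapply(groups, function(g) g[which.max(d[g])], numeric(1))
  cand <- sort(unname(cand)) + i0 - 1   # absolute sample index of the jump

  rows <- lapply(cand, function(i) {
    jump_measure(x, f, i, cand, config, constants, ss_persistence, i0, i1)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$f_rupture_pn), , drop = FALSE]

  # merge ringing: events closer than merge_df_pn in force become one
  if (nrow(ev) > 1 && config$merge_df_pn > 0) {
    grp <- cumsum(c(1, diff(ev$f_rupture_pn) > config$merge_df_pn))
    ev <- do.call(rbind, lapply(split(ev, grp), function(g) {
      if (nrow(g) == 1) return(g)
      out <- g[1, , drop = FALSE]
      out$delta_x_nm <- sum(g$delta_x_nm)
      out$delta_l_nm <- sum(g$delta_l_nm)
      out$delta_l_se_nm <- sqrt(sum(g$delta_l_se_nm^2))
      out$delta_l_plateau_sd_nm <- sqrt(sum(g$delta_l_plateau_sd_nm^2))
      out$f_rupture_pn <- g$f_rupture_pn[1]
      out
    }))
  }
  ev$molecule_id <- trace$molecule_id
  ev$cycle <- trace$cycle
  ev$rank <- seq_len(nrow(ev))
  ev$assigned_state <- NA_character_
  rownames(ev) <- NULL
  ev[, c("molecule_id", "cycle", "rank", "f_rupture_pn", "delta_x_nm",
         "delta_l_nm", "delta_l_se_nm", "delta_l_plateau_sd_nm",
         "low_force", "assigned_state")]
}

empty_events <- function(trace) {
  data.frame(molecule_id = character(), cycle = integer(), rank = integer(),
             f_rupture_pn = numeric(), delta_x_nm = numeric(),
             delta_l_nm = numeric(), delta_l_se_nm = numeric(),
             delta_l_plateau_sd_nm = numeric(),
             low_force = logical(), assigned_state = character())
}

# Quantify one jump. The ramp is linear in time, so extension and force
# are regressed on the sample index (regressing extension on the recorded
# force over a narrow window would put the force noise on the predictor
# side and destabilise the fit). The reported Delta-L standard error is
# the per-sample Delta-L noise scale, i.e. the expected scatter of the
# corresponding Delta-L versus force plateau, combining the extension
# residuals with the force noise propagated through the tether compliance
# and the fractional-extension correction.
jump_measure <- function(x, f, i, all_cand, config, constants,
                         ss_persistence, i0, i1) {
  w <- config$fit_window
  left_lim <- max(i0, max(all_cand[all_cand < i] + 1, i0))
  right_lim <- min(i1, min(all_cand[all_cand > i], i1))
  li <- max(left_lim, i - w + 1):i
  ri <- (i + 1):min(right_lim, i + w)
  fit_at <- function(ii, y) {
    # linear trend in sample index, evaluated at the jump boundary i + 0.5
    if (length(ii) >= 4) {
      fit <- stats::lm(y[ii] ~ ii)
      # noise-free traces fit exactly; the zero-residual warning is expected
      s <- suppressWarnings(summary(fit)$sigma)
      list(mu = unname(stats::coef(fit)[1] + stats::coef(fit)[2] * (i + 0.5)),
           s = s,
           slope = unname(stats::coef(fit)[2]))
    } else {
      list(mu = mean(y[ii]), s = stats::sd(y[ii]), slope = 0)
    }
  }
  xl <- fit_at(li, x); xr <- fit_at(ri, x)
  fl <- fit_at(li, f); fr <- fit_at(ri, f)
  delta_x <- xr$mu - xl$mu
  f_r <- (fl$mu + fr$mu) / 2
  prof <- polymer_profile(ss_persistence, constants)
  phi <- prof$phi(f_r)
  dphi <- prof$phi(f_r, deriv = 1)
  sigma_f <- sqrt(mean(c(fl$s, fr$s)^2, na.rm = TRUE))
  if (!is.finite(sigma_f)) sigma_f <- 0
  sd_x <- sqrt(mean(c(xl$s, xr$s)^2, na.rm = TRUE))
  if (!is.finite(sd_x)) sd_x <- 0
  df_dt <- mean(c(fl$slope, fr$slope))
  dx_df <- if (df_dt > 0) mean(c(xl$slope, xr$slope)) / df_dt else 0
  # per-sample Delta-L noise: extension residuals and force noise through
  # the local compliance, plus the phi(F) correction sensitivity
  se_sample <- sqrt((sd_x^2 + (dx_df * sigma_f)^2) / phi^2 +
                      (delta_x * dphi / phi^2)^2 * sigma_f^2)
  dl <- delta_l_from_jump(delta_x, f_r, se_delta_x = 0,
                          constants = constants,
                          ss_persistence = ss_persistence)
  # event-level standard error: the plateau-scale noise averaged over the
  # samples entering the two side fits
  n_eff <- length(li) + length(ri)
  data.frame(f_rupture_pn = f_r, delta_x_nm = delta_x,
             delta_l_nm = dl$delta_l_nm,
             delta_l_se_nm = max(se_sample / sqrt(n_eff), config$min_se_nm),
             delta_l_plateau_sd_nm = se_sample,
             low_force = dl$low_force)
}

#' Convert an extension jump to a change in contour length
#'
#' At rupture force F the released ssDNA is only fractionally extended, so
#' the contour-length change is `delta_L = delta_x / phi_ss(F)` with
#' `phi_ss` the Marko-Siggia fractional extension. The standard error is
#' propagated to first order from the jump uncertainty.
#'
#' @param delta_x Extension jump in nm (> 0).
#' @param f_rupture Rupture force in pN (> 0).
#' @param se_delta_x Standard error of the jump (per-sample scale), nm.
#' @param constants A [physical_constants()] object.
#' @param ss_persistence ssDNA persistence length in nm.
#' @return A data frame with `delta_l_nm`, `se_nm` and `low_force` (TRUE
#'   when `phi_ss <= 0.1`, where the conversion is unreliable).
#' @export
delta_l_from_jump <- function(delta_x, f_rupture, se_delta_x = 0,
                              constants = physical_constants(),
                              ss_persistence = 0.8) {
  stopifnot(all(delta_x > 0), all(f_rupture > 0))
  phi <- ssdna_phi(f_rupture, constants, ss_persistence)
  low <- phi <= 0.1
  if (any(low))
    warning("rupture force too low for a reliable Delta-L conversion (phi <= 0.1)",
            call. = FALSE)
  data.frame(delta_l_nm = delta_x / phi, se_nm = se_delta_x / phi,
             low_force = low)
}

#' Fit the fully released tether baseline of a stretch trace
#'
#' Least-squares fit of `x(F) = L_ds (phi_ds(F) + F/K) + L_rel phi_ss(F)`
#' over the post-unfolding branch (forces above the last detected rupture,
#' below the overstretching region), linear in the dsDNA handle contour
#' `L_ds` and the released ssDNA contour `L_rel`.
#'
#' @param trace A stretch [fx_trace()].
#' @param events Detected events for the trace (optional); the fit region
#'   starts 1 pN above the last rupture.
#' @param f_range Optional explicit force range `c(lo, hi)` for the fit.
#' @param constants A [physical_constants()] object.
#' @param ss_persistence,ds_persistence,ds_modulus Polymer parameters.
#' @return A list with `l_ds`, `l_released`, and `predict(force)`.
#' @export
fit_baseline <- function(trace, events = NULL, f_range = NULL,
                         constants = physical_constants(),
                         ss_persistence = 0.8, ds_persistence = 50,
                         ds_modulus = 1200) {
  x <- trace$samples$extension_nm
  f <- trace$samples$force_pn
  if (is.null(f_range)) {
    lo <- if (!is.null(events) && nrow(events))
      max(events$f_rupture_pn) + 1 else max(5, stats::quantile(f, 0.5))
    f_range <- c(lo, 55)
  }
  keep <- f >= f_range[1] & f <= f_range[2]
  if (sum(keep) < 10)
    stop("baseline fit failure: too few samples in the fit range",
         call. = FALSE)
  pds <- polymer_profile(ds_persistence, constants)
  pss <- polymer_profile(ss_persistence, constants)
  b_ds <- pds$phi(f[keep]) + f[keep] / ds_modulus
  b_ss <- pss$phi(f[keep])
  fit <- stats::lm(x[keep] ~ b_ds + b_ss - 1)
  l_ds <- unname(stats::coef(fit)[1])
  l_rel <- unname(stats::coef(fit)[2])
  list(l_ds = l_ds, l_released = l_rel,
       predict = function(force)
         l_ds * (pds$phi(force) + force / ds_modulus) +
         l_rel * pss$phi(force))
}

#' Delta-L versus force representation of a stretch trace
#'
#' Converts a force-extension record into the remaining folded contour at
#' each force: `delta_L(F) = (x_baseline(F) - x(F)) / phi_ss(F)`, with the
#' baseline the fully released branch from [fit_baseline()]. Plateaus of
#' this curve correspond to folded states; the fully unfolded branch sits
#' at zero.
#'
#' @param trace A stretch [fx_trace()].
#' @param baseline A [fit_baseline()] result.
#' @param f_range Force range to evaluate, pN.
#' @param constants A [physical_constants()] object.
#' @param ss_persistence ssDNA persistence length, nm.
#' @return A data frame with `force_pn` and `delta_l_nm`.
#' @export
delta_l_force_plot <- function(trace, baseline, f_range = c(2, 55),
                               constants = physical_constants(),
                               ss_persistence = 0.8) {
  x <- trace$samples$extension_nm
  f <- trace$samples$force_pn
  keep <- f >= f_range[1] & f <= f_range[2]
  phi <- ssdna_phi(f[keep], constants, ss_persistence)
  data.frame(force_pn = f[keep],
             delta_l_nm = (baseline$predict(f[keep]) - x[keep]) / phi)
}

#' Single-tether overstretching fingerprint
#'
#' A single dsDNA tether shows a near-horizontal saw-tooth plateau at
#' ~65 pN. Returns `TRUE` if such a plateau (sufficient extension span at
#' small force-versus-extension slope) exists within `overstretch +/- tol`,
#' `FALSE` if the trace reaches that force range without one (e.g. a
#' doubled tether whose plateau sits near 130 pN), and `NA` (indeterminate)
#' if the trace never reaches 60 pN.
#'
#' @param trace An [fx_trace()].
#' @param overstretch Expected plateau force, pN.
#' @param tol Half-width of the plateau search window, pN.
#' @param slope_max Maximum |dF/dx| (pN/nm) for a plateau.
#' @param min_span_nm Minimum extension span of the plateau.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
tether_fingerprint <- function(trace, overstretch = 65, tol = 5,
                               slope_max = 0.08, min_span_nm = 15) {
  f <- trace$samples$force_pn
  x <- trace$samples$extension_nm
  if (max(f) < 60) return(NA)
  win <- abs(f - overstretch) <= tol
  if (sum(win) < 10) return(FALSE)
  span <- diff(range(x[win]))
  if (span < min_span_nm) return(FALSE)
  slope <- abs(unname(stats::coef(stats::lm(f[win] ~ x[win]))[2]))
  isTRUE(span >= min_span_nm && slope <= slope_max)
}
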