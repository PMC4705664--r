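#' Bell-Evans rupture kinetics under a force ramp
#'
#' For `k(F) = k0 exp(F dx / kT)` and a constant loading rate `r`, the
#' rupture-force density is
#' \deqn{p(F) = (k(F)/r) \exp[(k_0 k_BT)/(r\,dx)\,(1 - e^{F dx/k_BT})]}
#' with mode \eqn{F^* = (k_BT/dx)\,\ln(r\,dx/(k_0 k_BT))}.
#'
#' @param species A [structure_species()] with calibrated `k0`.
#' @param loading_rate Ramp rate in pN/s.
#' @param constants A [physical_constants()] object.
#' @param force Forces at which to evaluate (pN).
#' @param from Hazard-restart force: the species only becomes rupturable at
#'   this force (used for staged, hierarchy-respecting rupture).
#' @return `bell_evans_cdf` the cumulative rupture probability;
#'   `bell_evans_mode` the modal rupture force in pN.
#' @export
bell_evans_cdf <- function(force, species, loading_rate,
                           constants = physical_constants(), from = 0) {
  kT <- constants$kT
  dx <- species$dx_ts
  a <- species$k0 * kT / (loading_rate * dx)
  1 - exp(a * (exp(from * dx / kT) - exp(force * dx / kT)))
}

#' @rdname bell_evans_cdf
#' @export
bell_evans_mode <- function(species, loading_rate,
                            constants = physical_constants()) {
  kT <- constants$kT
  kT / species$dx_ts *
    log(loading_rate * species$dx_ts / (species$k0 * kT))
}

#' Sample rupture forces from the Bell-Evans ramp distribution
#'
#' Exact inverse-CDF sampling. With `from > 0` the hazard starts at `from`
#' (the species was shielded by an outer structure until that force).
#'
#' @inheritParams bell_evans_cdf
#' @param n Number of draws.
#' @return Rupture forces in pN.
#' @export
sample_rupture_force <- function(species, loading_rate,
                                 constants = physical_constants(),
                                 n = 1, from = 0) {
  stopifnot(inherits(species, "structure_species"), !is.null(species$k0),
            loading_rate > 0, from >= 0)
  kT <- constants$kT
  dx <- species$dx_ts
  u <- stats::runif(n)
  kT / dx * log(exp(from * dx / kT) -
                  (loading_rate * dx) / (species$k0 * kT) * log(u))
}

# ---- event-level simulation --------------------------------------------

#' Simulate rupture-event logs for a scenario
#'
#' Draws, cycle by cycle, the refolding configuration, cooperative merges,
#' and staged Bell-Evans rupture forces, without rendering full
#' force-extension traces. Within a configuration, stage `i + 1` only
#' becomes rupturable at the last rupture force of stage `i` (hazard
#' restart), so event order always respects the construct hierarchy.
#' Species whose drawn force exceeds the ramp maximum stay folded and
#' produce no event.
#'
#' @param sc A [scenario()].
#' @param n_cycles Pulling cycles per molecule.
#' @param n_molecules Number of molecules.
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @return A list with `events` (one row per rupture: molecule_id, cycle,
#'   rank, species, n_nt, delta_l_nm, delta_x_nm, f_rupture_pn, config,
#'   cooperative) and `cycles` (per-cycle summary: configuration, summed
#'   Delta-L, broken/complete flags).
#' @export
simulate_events <- function(sc, n_cycles, n_molecules = 1, seed = NULL) {
  stopifnot(inherits(sc, "ramp_scenario"), n_cycles >= 1, n_molecules >= 1)
  if (!is.null(seed)) set.seed(seed)
  probs <- vapply(sc$configurations, `[[`, numeric(1), "prob")
  ev_list <- list()
  cyc_list <- list()
  k <- 0L
  for (mol in seq_len(n_molecules)) {
    mol_id <- sprintf("mol%03d", mol)
    for (cyc in seq_len(n_cycles)) {
      k <- k + 1L
      drawn <- simulate_cycle_events(sc, probs)
      broken <- FALSE
      if (sc$premature_break_prob > 0 &&
          stats::runif(1) < sc$premature_break_prob) {
        broken <- TRUE
        f_break <- stats::runif(1, 10, 45)
        drawn$events <- drawn$events[drawn$events$f_rupture_pn < f_break, ,
                                     drop = FALSE]
      }
      ev <- drawn$events
      if (nrow(ev)) {
        ev$molecule_id <- mol_id
        ev$cycle <- cyc
        ev$rank <- seq_len(nrow(ev))
        ev_list[[k]] <- ev
      }
      cyc_list[[k]] <- data.frame(
        molecule_id = mol_id, cycle = cyc, config = drawn$config,
        cooperative = drawn$cooperative, broken = broken,
        complete = !broken && drawn$all_ruptured,
        sum_delta_l_nm = sum(ev$delta_l_nm),
        n_events = nrow(ev))
      if (broken) break
    }
  }
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(species = character(), n_nt = integer(),
               delta_l_nm = numeric(), delta_x_nm = numeric(),
               f_rupture_pn = numeric(), config = integer(),
               cooperative = logical(), molecule_id = character(),
               cycle = integer(), rank = integer())
  rownames(events) <- NULL
  cycles <- do.call(rbind, cyc_list)
  rownames(cycles) <- NULL
  list(events = events[, c("molecule_id", "cycle", "rank", "species",
                           "n_nt", "delta_l_nm", "delta_x_nm",
                           "f_rupture_pn", "config", "cooperative")],
       cycles = cycles)
}

# one cycle's rupture schedule (no noise, no trace)
simulate_cycle_events <- function(sc, probs) {
  cfg_i <- sample.int(length(sc$configurations), 1, prob = probs)
  stages <- sc$configurations[[cfg_i]]$stages
  # refolding failures drop species from the cycle
  if (!is.null(sc$refold_probs)) {
    stages <- lapply(stages, function(st)
      st[stats::runif(length(st)) <
           ifelse(is.na(sc$refold_probs[st]), 1, sc$refold_probs[st])])
    stages <- stages[vapply(stages, length, integer(1)) > 0]
  }
  # cooperative merging of a singleton dependent stage with its
  # prerequisite stage
  cooperative <- FALSE
  if (length(stages) >= 2) {
    i <- 2
    while (i <= length(stages)) {
      st <- stages[[i]]
      if (length(st) == 1L) {
        spd <- sc$species[[st]]
        prev <- stages[[i - 1]]
        if (spd$coop_prob > 0 && length(prev) == 1L &&
            prev %in% spd$prerequisites &&
            stats::runif(1) < spd$coop_prob) {
          stages[[i - 1]] <- paste(prev, st, sep = "+")
          stages <- stages[-i]
          cooperative <- TRUE
          next
        }
      }
      i <- i + 1
    }
  }
  rows <- list()
  from <- 0
  all_ruptured <- TRUE
  for (st in stages) {
    fs <- vapply(st, function(sid) {
      spx <- if (sid %in% names(sc$species)) sc$species[[sid]] else
        sc$merged[[sub(".*\\+", "", sid)]]
      sample_rupture_force(spx, sc$loading_rate, sc$constants,
                           from = from)
    }, numeric(1))
    ord <- order(fs)
    for (j in ord) {
      sid <- st[j]
      spx <- if (sid %in% names(sc$species)) sc$species[[sid]] else
        sc$merged[[sub(".*\\+", "", sid)]]
      if (fs[j] <= sc$max_force) {
        phi <- ssdna_phi(fs[j], sc$constants)
        rows[[length(rows) + 1L]] <- data.frame(
          species = spx$id, n_nt = spx$n_nt, delta_l_nm = spx$delta_l,
          delta_x_nm = spx$delta_l * phi, f_rupture_pn = fs[j],
          config = cfg_i, cooperative = cooperative && grepl("\\+", sid))
      } else {
        all_ruptured <- FALSE
      }
    }
    from <- max(from, fs)
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), n_nt = integer(),
               delta_l_nm = numeric(), delta_x_nm = numeric(),
               f_rupture_pn = numeric(), config = integer(),
               cooperative = logical())
  list(events = events, config = cfg_i, cooperative = cooperative,
       all_ruptured = all_ruptured)
}

# ---- trace rendering ----------------------------------------------------

#' Simulate one stretch/relax force-ramp cycle
#'
#' Renders the force-extension record of one cycle. The tether extension at
#' force F sums the extensible-WLC extension of the dsDNA handles and the
#' Marko-Siggia extension of the ssDNA contour released by all ruptures
#' below F. Gaussian noise (`noise_sd`) is applied to the recorded force;
#' extension follows the ramp deterministically. When the ramp exceeds the
#' overstretching force a saw-tooth plateau is appended as the
#' single-tether fingerprint. The relax trace follows the fully released
#' branch back to zero force (unfolding hysteresis).
#'
#' @param sc A [scenario()].
#' @param events Optional pre-drawn rupture schedule (a data frame with
#'   columns `species`, `delta_l_nm`, `f_rupture_pn`, as produced by
#'   [simulate_events()]); when `NULL` a schedule is drawn.
#' @param molecule_id,cycle Labels stored in the trace.
#' @return A list with elements `stretch` and `relax` ([fx_trace()]
#'   objects) and `events` (the schedule used).
#' @export
simulate_cycle <- function(sc, events = NULL, molecule_id = "mol001",
                           cycle = 1L) {
  stopifnot(inherits(sc, "ramp_scenario"))
  if (is.null(events)) {
    probs <- vapply(sc$configurations, `[[`, numeric(1), "prob")
    events <- simulate_cycle_events(sc, probs)$events
  }
  con <- sc$constants
  ramp_top <- min(sc$max_force, sc$overstretch_force)
  df <- sc$loading_rate / sc$sample_rate
  f_true <- seq(0, ramp_top, by = df)
  ds <- handle_extension(f_true, sc, con)
  released <- outer(f_true, events$f_rupture_pn, ">=") %*% events$delta_l_nm
  x <- ds + as.numeric(released) * ssdna_phi(f_true, con)
  f_rec <- f_true + if (sc$noise_sd > 0)
    stats::rnorm(length(f_true), 0, sc$noise_sd) else 0
  meta <- list(scenario = sc$label, scenario_hash = sc$hash,
               loading_rate_pn_s = sc$loading_rate,
               temperature_k = con$temperature,
               noise_sd_pn = sc$noise_sd, sample_rate_hz = sc$sample_rate)
  if (sc$max_force >= sc$overstretch_force) {
    n_plat <- 240L
    x_end <- x[length(x)]
    x_plat <- x_end + seq_len(n_plat) / n_plat * 0.12 *
      sum(sc$handle_bp) * RISE_DS
    saw <- 1.2 * (2 * abs(seq_len(n_plat) %% 40L / 40 - 0.5) - 0.5)
    f_plat <- sc$overstretch_force + saw + if (sc$noise_sd > 0)
      stats::rnorm(n_plat, 0, sc$noise_sd) else 0
    x <- c(x, x_plat)
    f_rec <- c(f_rec, f_plat)
  }
  stretch <- fx_trace(molecule_id, cycle, "stretch",
                      extension = x, force = pmax(f_rec, 0),
                      metadata = meta)
  # relax: fully released branch (hysteresis; refolding occurs near zero force)
  f_rel <- seq(ramp_top, 0, by = -df)
  x_rel <- handle_extension(f_rel, sc, con) +
    sum(events$delta_l_nm) * ssdna_phi(f_rel, con)
  f_rel_rec <- f_rel + if (sc$noise_sd > 0)
    stats::rnorm(length(f_rel), 0, sc$noise_sd) else 0
  relax <- fx_trace(molecule_id, cycle, "relax",
                    extension = x_rel, force = pmax(f_rel_rec, 0),
                    metadata = meta)
  list(stretch = stretch, relax = relax, events = events)
}

handle_extension <- function(force, sc, constants) {
  L <- sum(sc$handle_bp) * RISE_DS
  prof <- polymer_profile(50, constants)
  L * (prof$phi(force) + force / 1200)
}

#' Simulate a full force-ramp data set
#'
#' Runs [simulate_events()] and renders each cycle's stretch and relax
#' traces. With the same seed the output is reproducible bit for bit.
#'
#' @inheritParams simulate_events
#' @param traces If `FALSE`, skip trace rendering (event log only).
#' @return A list with `traces` (list of [fx_trace()]), `events`, and
#'   `cycles` as in [simulate_events()].
#' @export
simulate_ramps <- function(sc, n_cycles, n_molecules = 1, seed = NULL,
                           traces = TRUE) {
  log <- simulate_events(sc, n_cycles, n_molecules, seed = seed)
  if (!traces)
    return(list(traces = list(), events = log$events, cycles = log$cycles))
  out <- vector("list", 2L * nrow(log$cycles))
  j <- 0L
  for (i in seq_len(nrow(log$cycles))) {
    cyc <- log$cycles[i, ]
    ev <- log$events[log$events$molecule_id == cyc$molecule_id &
                       log$events$cycle == cyc$cycle, , drop = FALSE]
    pair <- simulate_cycle(sc, events = ev, molecule_id = cyc$molecule_id,
                           cycle = cyc$cycle)
    out[[j + 1L]] <- pair$stretch
    out[[j + 2L]] <- pair$relax
    j <- j + 2L
  }
  list(traces = out[seq_len(j)], events = log$events, cycles = log$cycles)
}
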