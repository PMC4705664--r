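# shared fixtures and independent oracles

pc <- physical_constants()
conv <- calibrate_conversion()

# independent bracketed-bisection solve of the Marko-Siggia force law
oracle_ms_force <- function(frac, persistence, kT = pc$kT) {
  (kT / persistence) * (1 / (4 * (1 - frac)^2) - 0.25 + frac)
}
oracle_ms_frac <- function(force, persistence, kT = pc$kT) {
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (oracle_ms_force(mid, persistence, kT) < force) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# a single-species scenario with conversion-calibrated Delta-L
one_species_scenario <- function(n_nt = 47, delta_g = 16, dx_ts = 3,
                                 delta_l = nt_to_delta_l(n_nt, conv),
                                 noise_sd = 0.2, ...) {
  scenario(sprintf("one%d", n_nt),
           list(structure_species("SP", n_nt, delta_g, dx_ts,
                                  delta_l = delta_l)),
           list(list(prob = 1, stages = list("SP"))),
           noise_sd = noise_sd, conversion = conv, ...)
}

# greedy matching of detected against ground-truth events
match_events <- function(true_ev, det, f_tol = 1, dl_rel = 0.25) {
  tp <- 0; fn <- 0
  for (k in unique(paste(true_ev$molecule_id, true_ev$cycle))) {
    te <- true_ev[paste(true_ev$molecule_id, true_ev$cycle) == k, ,
                  drop = FALSE]
    de <- det[paste(det$molecule_id, det$cycle) == k, , drop = FALSE]
    used <- rep(FALSE, nrow(de))
    for (i in seq_len(nrow(te))) {
      j <- which(!used &
                   abs(de$f_rupture_pn - te$f_rupture_pn[i]) < f_tol &
                   abs(de$delta_l_nm - te$delta_l_nm[i]) <
                     dl_rel * te$delta_l_nm[i] + 0.5)
      if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1 } else fn <- fn + 1
    }
  }
  c(recall = tp / (tp + fn),
    fp_rate = (nrow(det) - tp) / max(nrow(det), 1))
}

# works of first-rupture events split by generating species
first_rank_works <- function(events, species_id) {
  first <- events[events$rank == 1 & events$species == species_id, ,
                  drop = FALSE]
  unfolding_work(first$f_rupture_pn, first$delta_x_nm, first$delta_l_nm)
}
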