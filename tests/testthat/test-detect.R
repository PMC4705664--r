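test_that("a noise-free single-species cycle yields exactly one event at the logged force", {
  sc <- one_species_scenario(noise_sd = 0)
  cyc <- simulate_cycle(sc, events = data.frame(
    species = "SP", delta_l_nm = nt_to_delta_l(47, conv),
    f_rupture_pn = 30))
  ev <- detect_ruptures(cyc$stretch)
  expect_equal(nrow(ev), 1L)
  df <- sc$loading_rate / sc$sample_rate
  expect_lt(abs(ev$f_rupture_pn - 30), 2 * df)
  expect_equal(ev$delta_l_nm, nt_to_delta_l(47, conv), tolerance = 5e-3)
  # a cycle with nothing folded produces no events
  smooth <- simulate_cycle(sc, events = cyc$events[0, ])
  expect_equal(nrow(detect_ruptures(smooth$stretch)), 0L)
})

test_that("Delta-L estimates are invariant to the rupture force", {
  sc <- one_species_scenario(n_nt = 18, delta_g = 8, dx_ts = 7,
                             noise_sd = 0)
  dls <- vapply(c(15, 35), function(fr) {
    cyc <- simulate_cycle(sc, events = data.frame(
      species = "SP", delta_l_nm = nt_to_delta_l(18, conv),
      f_rupture_pn = fr))
    detect_ruptures(cyc$stretch)$delta_l_nm
  }, numeric(1))
  expect_lt(abs(diff(dls)), 1e-3)
})

test_that("extension jumps convert to Delta-L through the fractional extension", {
  out <- delta_l_from_jump(1.825, 20, constants = pc)
  expect_equal(out$delta_l_nm, 2.5, tolerance = 5e-3)
  expect_false(out$low_force)
  # at high force the correction disappears: Delta-L -> Delta-x
  hi <- delta_l_from_jump(5, 150, constants = pc)
  expect_lt(abs(hi$delta_l_nm / 5 - 1), 0.11)
  mid <- delta_l_from_jump(5, 40, constants = pc)
  expect_lt(abs(hi$delta_l_nm / 5 - 1), abs(mid$delta_l_nm / 5 - 1))
  lo20 <- delta_l_from_jump(1, 20, constants = pc)$delta_l_nm
  expect_gt(lo20, 1)   # phi < 1 inflates the jump into contour
  expect_warning(low <- delta_l_from_jump(0.2, 0.5, constants = pc),
                 "too low")
  expect_true(low$low_force)
})

test_that("detection recovers simulator ground truth at the stated noise level", {
  sc <- builtin_scenarios("NMS5-12")
  sim <- simulate_ramps(sc, n_cycles = 100, seed = 42)
  st <- Filter(function(t) t$direction == "stretch", sim$traces)
  det <- do.call(rbind, lapply(st, detect_ruptures))
  m <- match_events(sim$events, det)
  expect_gte(m["recall"], 0.95)
  expect_lte(m["fp_rate"], 0.02)
})

test_that("the Delta-L versus force plot shows folded plateaus and a zero unfolded branch", {
  sc <- one_species_scenario(noise_sd = 0)
  dl47 <- nt_to_delta_l(47, conv)
  cyc <- simulate_cycle(sc, events = data.frame(
    species = "SP", delta_l_nm = dl47, f_rupture_pn = 30))
  ev <- detect_ruptures(cyc$stretch)
  bl <- fit_baseline(cyc$stretch, events = ev)
  dlf <- delta_l_force_plot(cyc$stretch, bl)
  pre <- dlf$force_pn > 15 & dlf$force_pn < 29.5
  post <- dlf$force_pn > 30.5
  expect_equal(mean(dlf$delta_l_nm[pre]), dl47, tolerance = 1e-2)
  expect_lt(max(abs(dlf$delta_l_nm[post])), 1e-2)
  expect_error(fit_baseline(cyc$stretch, f_range = c(54.9, 55)), "baseline")
})

test_that("reported plateau noise matches the observed Delta-L-F scatter", {
  sc <- builtin_scenarios("NMS5-12")
  sim <- simulate_ramps(sc, n_cycles = 12, seed = 5)
  st <- Filter(function(t) t$direction == "stretch", sim$traces)
  ratios <- c()
  for (tr in st) {
    ev <- suppressWarnings(detect_ruptures(tr))
    if (!nrow(ev)) next
    bl <- fit_baseline(tr, events = ev)
    dlf <- delta_l_force_plot(tr, bl)
    for (i in seq_len(nrow(ev))) {
      f0 <- ev$f_rupture_pn[i]
      lo <- if (i == 1) max(3, f0 - 4) else
        max(ev$f_rupture_pn[i - 1] + 0.7, f0 - 4)
      win <- dlf$force_pn > lo & dlf$force_pn < f0 - 0.3
      if (sum(win) > 20)
        ratios <- c(ratios, sd(dlf$delta_l_nm[win]) /
                      ev$delta_l_plateau_sd_nm[i])
    }
  }
  expect_gt(length(ratios), 10)
  expect_lt(abs(median(ratios) - 1), 0.3)
})

test_that("the 65 pN plateau identifies a single tether", {
  sc <- one_species_scenario()
  full <- simulate_cycle(sc, events = data.frame(
    species = "SP", delta_l_nm = nt_to_delta_l(47, conv),
    f_rupture_pn = 30))
  expect_true(tether_fingerprint(full$stretch))
  # ramp truncated below the plateau: indeterminate, not false
  sc50 <- one_species_scenario(max_force = 50)
  trunc <- simulate_cycle(sc50, events = full$events)
  expect_true(is.na(tether_fingerprint(trunc$stretch)))
  # doubled tether: plateau at ~130 pN, absent from the 60-70 pN window
  scd <- one_species_scenario(max_force = 70, overstretch_force = 130)
  doubled <- simulate_cycle(scd, events = full$events)
  expect_false(tether_fingerprint(doubled$stretch))
})
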