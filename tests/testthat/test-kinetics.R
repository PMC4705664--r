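test_that("Bell-Evans modal force matches the closed form and shifts with loading rate", {
  sp <- structure_species("X", 10, 5, 1.0, k0 = 1e-4)
  expect_equal(bell_evans_mode(sp, 5.5, pc), 38.87, tolerance = 1e-3)
  shift <- bell_evans_mode(sp, 55, pc) - bell_evans_mode(sp, 5.5, pc)
  expect_equal(shift, pc$kT / 1.0 * log(10), tolerance = 1e-9)
})

test_that("rupture-force draws follow the analytic distribution", {
  sp <- structure_species("X", 10, 5, 1.0, k0 = 1e-4)
  set.seed(42)
  f <- sample_rupture_force(sp, 5.5, pc, n = 2e4)
  # empirical mode against the closed form
  d <- density(f)
  expect_lt(abs(d$x[which.max(d$y)] - bell_evans_mode(sp, 5.5, pc)), 1.5)
  # Kolmogorov-Smirnov distance against the analytic CDF
  ks <- max(abs(ecdf(f)(sort(f)) - bell_evans_cdf(sort(f), sp, 5.5, pc)))
  expect_lt(ks, 0.02)
})

test_that("hazard-restarted draws follow the conditional distribution", {
  sp <- structure_species("X", 10, 5, 1.0, k0 = 1e-4)
  set.seed(1)
  f <- sample_rupture_force(sp, 5.5, pc, n = 2e4, from = 35)
  expect_true(all(f >= 35))
  cdf <- function(x) bell_evans_cdf(x, sp, 5.5, pc, from = 35)
  ks <- max(abs(ecdf(f)(sort(f)) - cdf(sort(f))))
  expect_lt(ks, 0.02)
})

test_that("calibrated k0 makes the Jarzynski average match the stated free energy", {
  for (pars in list(c(dg = 8, dx = 7, n = 18), c(dg = 2, dx = 1.5, n = 3))) {
    sp <- structure_species("X", pars["n"], pars["dg"], pars["dx"],
                            delta_l = nt_to_delta_l(pars[["n"]], conv))
    sp$k0 <- calibrate_k0(sp, 5.5, pc)
    # oracle: fine-grid quadrature of E[exp(-W/kT)] with independent
    # cumulative-trapezoid stretching work
    fg <- seq(0, 140, by = 0.01)
    phi <- vapply(fg, function(f) if (f == 0) 0 else
      oracle_ms_frac(f, 0.8), numeric(1))
    W <- sp$delta_l * c(0, cumsum((phi[-1] + phi[-length(phi)]) / 2) * 0.01)
    dens <- (sp$k0 * exp(fg * sp$dx_ts / pc$kT) / 5.5) *
      exp((sp$k0 * pc$kT) / (5.5 * sp$dx_ts) *
            (1 - exp(fg * sp$dx_ts / pc$kT)))
    lhs <- -pc$kT * log(sum(dens * exp(-(W - min(W)) / pc$kT)) * 0.01) +
      min(W)
    expect_equal(lhs / pc$kcal_per_mol_pn_nm, pars[["dg"]],
                 tolerance = 5e-3)
  }
})

test_that("built-in scenarios carry the published construct anatomy", {
  all5 <- builtin_scenarios()
  expect_named(all5, c("NMS1-4", "NMS5-12", "hTERT1-12", "truncated1-4",
                       "truncated1-4+7nt"))
  expect_equal(builtin_scenarios("hTERT1-12")$species$QQI7$n_nt, 7)
  expect_equal(builtin_scenarios("NMS5-12")$species$QQI5$n_nt, 5)
  expect_equal(builtin_scenarios("NMS1-4")$species$QQI3$n_nt, 3)
  # the inter-quadruplex tail alone folds nothing: no stacking species
  t7 <- builtin_scenarios("truncated1-4+7nt")
  expect_false(any(grepl("QQI", names(t7$species))))
  # unicode dashes in labels are tolerated
  expect_equal(builtin_scenarios("NMS5–12")$label, "NMS5-12")
  expect_error(builtin_scenarios("NMS2-9"), "unknown scenario")
  # modal rupture forces stay in the experimentally observed force window
  for (sc in all5)
    for (sp in sc$species)
      expect_true(bell_evans_mode(sp, sc$loading_rate, pc) > 10 &&
                    bell_evans_mode(sp, sc$loading_rate, pc) < 50)
})

test_that("event simulation is deterministic and respects the species hierarchy", {
  sc <- builtin_scenarios("NMS5-12")
  a <- simulate_events(sc, n_cycles = 50, seed = 99)
  b <- simulate_events(sc, n_cycles = 50, seed = 99)
  expect_identical(a, b)
  sim <- simulate_events(sc, n_cycles = 2000, seed = 3)
  ev <- sim$events
  key <- paste(ev$molecule_id, ev$cycle)
  for (k in unique(key)) {
    sub <- ev[key == k, ]
    for (i in seq_len(nrow(sub))) {
      pre <- sc$species[[sub$species[i]]]$prerequisites
      pre <- intersect(pre, sub$species)
      if (length(pre))
        expect_true(all(sub$rank[sub$species %in% pre] < sub$rank[i]))
    }
  }
  # rupture forces stay inside the ramp
  expect_true(all(ev$f_rupture_pn > 0 & ev$f_rupture_pn <= sc$max_force))
})

test_that("the coop_prob mechanism yields the stated single-step fraction", {
  qqi <- structure_species("QQI3", 3, 2, 1.5, delta_l = nt_to_delta_l(3, conv))
  g4 <- structure_species("G4_18", 18, 8, 7.0, prerequisites = "QQI3",
                          coop_prob = 0.3,
                          delta_l = nt_to_delta_l(18, conv))
  sc <- scenario("pair", list(qqi, g4),
                 list(list(prob = 1, stages = list("QQI3", "G4_18"))),
                 conversion = conv)
  sim <- simulate_events(sc, n_cycles = 500, seed = 42)
  key <- paste(sim$events$molecule_id, sim$events$cycle)
  single21 <- tapply(sim$events$n_nt, key,
                     function(n) length(n) == 1 && n == 21)
  expect_lt(abs(mean(single21) - 0.30), 0.05)
})

test_that("rendered cycles reproduce the construction identity for extension jumps", {
  # raw species: released contour defaults to n * 0.45 nm
  sp <- structure_species("RAW18", 18, 8, 7.0)
  sc <- scenario("raw", list(sp), list(list(prob = 1, stages = list("RAW18"))),
                 noise_sd = 0, max_force = 50, conversion = conv)
  f_r <- 21.3
  cyc <- simulate_cycle(sc, events = data.frame(species = "RAW18",
                                                delta_l_nm = 18 * 0.45,
                                                f_rupture_pn = f_r))
  tr <- cyc$stretch
  x <- tr$samples$extension_nm; f <- tr$samples$force_pn
  i <- max(which(f < f_r))
  L_ds <- sum(sc$handle_bp) * 0.338
  handle <- function(force) wlc_extension(force, wlc_params(50, L_ds, 1200), pc)
  jump <- (x[i + 1] - handle(f[i + 1])) - (x[i] - handle(f[i]))
  phi <- wlc_extension(f[i + 1], wlc_params(0.8, 1), pc)
  expect_equal(jump, 18 * 0.45 * phi, tolerance = 1e-6)
  # no species folded: a smooth curve with no extension spikes
  cyc0 <- simulate_cycle(sc, events = cyc$events[0, ])
  d <- diff(cyc0$stretch$samples$extension_nm[
    cyc0$stretch$samples$force_pn > 2 &
    cyc0$stretch$samples$force_pn < 49])
  expect_lt(max(abs(d - stats::runmed(d, 11))), 0.3)
})

test_that("scenarios serialise to structured text and round-trip bit-identically", {
  sc <- builtin_scenarios("NMS1-4")
  path <- tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_identical(back$hash, sc$hash)
  a <- simulate_events(back, 20, seed = 5)
  b <- simulate_events(sc, 20, seed = 5)
  expect_equal(a$events$species, b$events$species)
  expect_equal(a$events$f_rupture_pn, b$events$f_rupture_pn,
               tolerance = 1e-9)
  expect_equal(a$events$delta_l_nm, b$events$delta_l_nm, tolerance = 1e-12)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "x"), bad, auto_unbox = TRUE)
  expect_error(read_scenario(bad), "missing required")
})
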