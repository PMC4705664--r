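test_that("full-fold selection keeps matching cycles and drops the rest", {
  ev <- data.frame(
    molecule_id = c("a", "a", "a", "b", "b"),
    cycle = c(1, 2, 2, 1, 1),
    delta_l_nm = c(25.0, 10.0, 10.0, 12.0, 8.0))
  sel <- select_full_fold_traces(ev, 25, tol_nm = 2)
  cyc <- attr(sel, "cycles")
  expect_true(cyc$selected[cyc$molecule_id == "a" & cyc$cycle == 1])
  expect_false(any(cyc$selected[cyc$molecule_id == "b"]))
  expect_equal(nrow(sel), 1L)
  # the 20 nm cycle of molecule b is below threshold even though b folds
  expect_false(any(sel$molecule_id == "b"))
  expect_equal(construct_full_fold("hTERT1-12"), 25)
  expect_equal(construct_full_fold("NMS5-12"), 18)
  expect_error(construct_full_fold("mystery"), "unknown construct")
})

test_that("molecules with premature tether breaks are excluded against ground truth", {
  sc <- builtin_scenarios("NMS5-12")
  sc$premature_break_prob <- 0.2
  sim <- simulate_events(sc, n_cycles = 1, n_molecules = 120, seed = 21)
  sel <- select_full_fold_traces(sim$events, 18, tol_nm = 2)
  cyc <- attr(sel, "cycles")
  truth <- sim$cycles
  for (i in seq_len(nrow(cyc))) {
    truth_row <- truth[truth$molecule_id == cyc$molecule_id[i] &
                         truth$cycle == cyc$cycle[i], ]
    expect_equal(cyc$selected[i],
                 abs(truth_row$sum_delta_l_nm - 18) <= 2)
  }
  # some broken molecules lost enough structure to be excluded
  broken <- truth$molecule_id[truth$broken]
  expect_gt(length(broken), 5)
  expect_gt(sum(!broken %in% sel$molecule_id), 0)
})

test_that("the fully-unfolded-trace requirement filters molecules", {
  ev <- data.frame(molecule_id = c("a", "b"), cycle = c(1, 1),
                   delta_l_nm = c(25, 25))
  info <- data.frame(molecule_id = c("a", "b"), cycle = c(1, 1),
                     complete = c(TRUE, FALSE))
  sel <- select_full_fold_traces(ev, 25, require_complete = TRUE,
                                 cycles_info = info)
  expect_identical(unique(sel$molecule_id), "a")
  expect_error(select_full_fold_traces(ev, 25, require_complete = TRUE),
               "cycles_info")
})

test_that("binning assigns nearest centers, ranks by occurrence and flags strays", {
  ev <- data.frame(molecule_id = "m", cycle = c(1, 1, 2, 3),
                   f_rupture_pn = c(22, 15, 20, 20),
                   delta_l_nm = c(6.4, 6.5, 6.3, 30))
  out <- bin_and_rank(ev, centers = c(6.45, 15), conv, bin_width = 4)
  # two near-identical Delta-L events in cycle 1: distinguished by rank
  c1 <- out[out$cycle == 1, ]
  expect_identical(sort(c1$rank), c(1L, 2L))
  expect_equal(unique(c1$assigned_nt), 18)
  expect_equal(c1$rank[c1$f_rupture_pn == 15], 1L)
  expect_identical(out$rank[out$cycle == 2], 1L)
  expect_identical(out$assigned_state[out$cycle == 3], "unclassified")
  # exact midpoint ties go to the smaller center
  tie <- bin_and_rank(data.frame(molecule_id = "m", cycle = 1,
                                 f_rupture_pn = 20, delta_l_nm = 10),
                      centers = c(8, 12), conv, bin_width = 8)
  expect_equal(tie$assigned_center_nm, 8)
})

test_that("events bin back to their generating species on the NMS5-12 twin", {
  sc <- builtin_scenarios("NMS5-12")
  sim <- simulate_events(sc, n_cycles = 400, seed = 9)
  ev <- sim$events
  set.seed(10)
  ev$delta_l_obs <- ev$delta_l_nm + rnorm(nrow(ev), 0, 0.15)
  meas <- data.frame(molecule_id = ev$molecule_id, cycle = ev$cycle,
                     f_rupture_pn = ev$f_rupture_pn,
                     delta_l_nm = ev$delta_l_obs)
  centers <- nt_to_delta_l(c(5, 15, 26, 32, 42, 47), conv)
  out <- bin_and_rank(meas, centers, conv)
  expect_gte(mean(out$assigned_nt == ev$n_nt, na.rm = TRUE), 0.95)
})

test_that("transition graphs aggregate counts, normalise percentages and stay acyclic", {
  # all cycles single-step full to unfolded: one edge at 100%
  ev1 <- data.frame(molecule_id = "m", cycle = 1:10, f_rupture_pn = 20,
                    delta_l_nm = nt_to_delta_l(47, conv))
  tg1 <- build_transition_graph(bin_and_rank(ev1, nt_to_delta_l(47, conv),
                                             conv))
  expect_equal(nrow(tg1$edges), 1L)
  expect_equal(tg1$edges$percent, 100)
  # a mixed twin
  sc <- builtin_scenarios("NMS5-12")
  sim <- simulate_events(sc, n_cycles = 300, seed = 11)
  centers <- nt_to_delta_l(c(5, 15, 26, 32, 42, 47), conv)
  asg <- bin_and_rank(sim$events, centers, conv)
  tg <- build_transition_graph(asg)
  expect_true(igraph::is_dag(tg$graph))
  expect_true(all(tg$edges$to_nt < tg$edges$from_nt))
  for (s in unique(tg$edges$from_nt))
    expect_equal(sum(tg$edges$percent[tg$edges$from_nt == s]), 100,
                 tolerance = 0.5)
  # unclassifiable events exclude their cycle, with a report
  bad <- rbind(asg[1:3, ],
               within(asg[1, ], { delta_l_nm <- 30
                                  assigned_nt <- NA_integer_
                                  assigned_state <- "unclassified"
                                  cycle <- 999L }))
  tg_bad <- build_transition_graph(bad)
  expect_length(tg_bad$excluded_cycles, 1L)
})

test_that("hTERT twin pathway shares are recovered from the graph", {
  sc <- builtin_scenarios("hTERT1-12")
  sim <- simulate_events(sc, n_cycles = 500, seed = 12)
  centers <- nt_to_delta_l(c(7, 18, 43, 68), conv)
  asg <- bin_and_rank(sim$events, centers, conv)
  tg <- build_transition_graph(asg)
  n <- tg$n_cycles
  count <- function(from, to) {
    hit <- tg$edges$count[tg$edges$from_nt == from & tg$edges$to_nt == to]
    if (length(hit)) hit else 0
  }
  expect_lt(abs(count(61, 43) / n - 0.65), 0.05)
  expect_lt(abs(count(61, 18) / n - 0.24), 0.05)
  expect_lt(abs(count(68, 0) / n - 0.11), 0.04)
})

test_that("cooperative fractions match the generating probabilities", {
  ff14 <- construct_full_fold("NMS1-4", conv)
  sc <- builtin_scenarios("NMS1-4")
  sim <- simulate_events(sc, n_cycles = 800, seed = 42)
  sel <- select_full_fold_traces(sim$events, ff14)
  coop <- cooperative_fraction(sel, ff14)
  expect_lt(abs(coop$per_trace - 0.30), 0.05)
  expect_true(coop$per_molecule >= coop$per_trace)
  # without any stacking interaction nothing unfolds cooperatively
  qqi <- structure_species("QQI3", 3, 2, 1.5, delta_l = nt_to_delta_l(3, conv))
  g4 <- structure_species("G4_18", 18, 8, 7.0, prerequisites = "QQI3",
                          coop_prob = 0, delta_l = nt_to_delta_l(18, conv))
  sc0 <- scenario("pair0", list(qqi, g4),
                  list(list(prob = 1, stages = list("QQI3", "G4_18"))),
                  conversion = conv)
  sim0 <- simulate_events(sc0, n_cycles = 300, seed = 13)
  coop0 <- cooperative_fraction(sim0$events, nt_to_delta_l(21, conv))
  expect_equal(coop0$per_trace, 0)
  # hTERT all-at-once fraction
  sch <- builtin_scenarios("hTERT1-12")
  simh <- simulate_events(sch, n_cycles = 500, seed = 14)
  selh <- select_full_fold_traces(simh$events, 25)
  expect_lt(abs(cooperative_fraction(selh, 25)$per_trace - 0.11), 0.04)
})

test_that("graph exports write edge lists and GraphML", {
  ev <- data.frame(molecule_id = "m", cycle = 1:5, f_rupture_pn = 20,
                   delta_l_nm = nt_to_delta_l(47, conv))
  tg <- build_transition_graph(bin_and_rank(ev, nt_to_delta_l(47, conv),
                                            conv))
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".graphml")
  write_transition_graph(tg, p1, p2)
  expect_true(file.exists(p1))
  expect_match(readLines(p1)[1], "from_state\tto_state")
  expect_match(paste(readLines(p2), collapse = ""), "graphml")
})
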