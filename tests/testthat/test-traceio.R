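random_traces <- function(n = 5) {
  lapply(seq_len(n), function(i) {
    m <- sample(50:120, 1)
    fx_trace(sprintf("mol%03d", (i - 1) %/% 2 + 1), (i - 1) %% 2 + 1,
             sample(c("stretch", "relax"), 1),
             extension = cumsum(runif(m, 0, 5)),
             force = sort(runif(m, 0, 60)),
             metadata = list(loading_rate_pn_s = 5.5, seed = 7))
  })
}

test_that("traces round-trip losslessly through the TSV dialect", {
  set.seed(10)
  traces <- random_traces(20)
  path <- tempfile(fileext = ".tsv")
  write_trace(traces, path)
  back <- read_trace(path)
  expect_length(back, 20)
  for (tr in traces) {
    hit <- Filter(function(b) b$molecule_id == tr$molecule_id &&
                    b$cycle == tr$cycle && b$direction == tr$direction, back)
    expect_length(hit, 1)
    expect_equal(hit[[1]]$samples$extension_nm, tr$samples$extension_nm,
                 tolerance = 1e-9)
    expect_equal(hit[[1]]$samples$force_pn, tr$samples$force_pn,
                 tolerance = 1e-9)
  }
  # byte-stable dialect
  path2 <- tempfile(fileext = ".tsv")
  write_trace(traces, path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
})

test_that("malformed or empty trace files are reported usefully", {
  # empty body
  p <- tempfile()
  writeLines(c("#format: rampfold-fx-trace v1",
               "#units: extension_nm=nm force_pn=pN"), p)
  expect_warning(out <- read_trace(p), "no data rows")
  expect_length(out, 0)
  # wrong units header
  p2 <- tempfile()
  writeLines(c("#format: rampfold-fx-trace v1",
               "#units: extension_nm=nm force_pn=nN",
               paste(c("molecule_id", "cycle", "direction", "extension_nm",
                       "force_pn"), collapse = "\t"),
               "m1\t1\tstretch\t1.0\t2.0"), p2)
  expect_error(read_trace(p2), "units")
  # missing required column
  p3 <- tempfile()
  writeLines(c("#units: extension_nm=nm force_pn=pN",
               "molecule_id\tcycle\textension_nm\tforce_pn",
               "m1\t1\t1.0\t2.0"), p3)
  expect_error(read_trace(p3), "missing required columns")
  # non-monotone cycle indices within a molecule block
  p4 <- tempfile()
  writeLines(c("#units: extension_nm=nm force_pn=pN",
               "molecule_id\tcycle\tdirection\textension_nm\tforce_pn",
               "m1\t2\tstretch\t1.0\t2.0",
               "m1\t2\tstretch\t2.0\t3.0",
               "m1\t1\tstretch\t1.0\t2.0",
               "m1\t1\tstretch\t2.0\t3.0"), p4)
  expect_error(read_trace(p4), "non-monotone")
  expect_error(read_trace(tempfile()), "no such file")
})

test_that("trace validation enforces the container invariants", {
  expect_error(fx_trace("m", 1, "stretch", 1:3, c(1, 2)), "equal length")
  expect_error(fx_trace("m", 1, "stretch", 1, 1), "at least 2")
  expect_error(fx_trace("m", 1, "stretch", 1:2, c(-1, 2)), "non-negative")
  expect_error(fx_trace("m", 1, "sideways", 1:2, 1:2))
})

test_that("event tables round-trip with provenance headers", {
  ev <- data.frame(molecule_id = "m1", cycle = 1L, rank = 1:2,
                   f_rupture_pn = c(18.2, 25.9),
                   delta_x_nm = c(4.1, 9.7), delta_l_nm = c(6.3, 15.2),
                   delta_l_se_nm = c(0.12, 0.2),
                   assigned_state = c("18nt", "42nt"))
  p <- tempfile(fileext = ".tsv")
  write_events(ev, p, metadata = list(scenario_hash = "abc123", seed = 4))
  expect_true(any(grepl("^#scenario_hash: abc123", readLines(p))))
  back <- read_events(p)
  expect_equal(back$delta_l_nm, ev$delta_l_nm, tolerance = 1e-9)
  expect_equal(back$assigned_state, ev$assigned_state)
})
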