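#' Define a foldable structural species
#'
#' A species is a foldable element of the construct (a G-quadruplex, a
#' hairpin or triplex intermediate, a quadruplex-quadruplex stacking
#' contact, or a cooperative composite of these). Rupture kinetics follow
#' the Bell-Evans model `k(F) = k0 exp(F dx / kT)`.
#'
#' @param id Species label.
#' @param n_nt Nucleotides released when the species ruptures (>= 1).
#' @param delta_g Folding stabilisation free energy in kcal/mol (> 0).
#' @param dx_ts Distance to the transition state in nm (> 0).
#' @param k0 Zero-force unfolding rate in 1/s. If `NULL` it is derived by
#'   [calibrate_k0()] when the species enters a [scenario()], so that the
#'   Jarzynski average of the simulated unfolding work equals `delta_g`.
#' @param prerequisites Ids of species that must rupture before (or jointly
#'   with) this one; the prerequisite graph must be acyclic.
#' @param coop_prob Probability in [0, 1] that the species ruptures jointly
#'   with its prerequisite as one cooperative event.
#' @param delta_l Contour length released on rupture, in nm. Defaults to
#'   `n_nt * 0.45` (bare ssDNA contour); scenario builders typically supply
#'   the calibrated conversion value instead, which also absorbs the folded
#'   end-to-end correction.
#' @return An object of class `structure_species`.
#' @export
structure_species <- function(id, n_nt, delta_g, dx_ts, k0 = NULL,
                              prerequisites = character(), coop_prob = 0,
                              delta_l = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            n_nt >= 1, delta_g > 0, dx_ts > 0,
            coop_prob >= 0, coop_prob <= 1,
            is.null(k0) || k0 > 0)
  if (is.null(delta_l)) delta_l <- n_nt * RISE_SS
  stopifnot(delta_l > 0)
  structure(list(id = id, n_nt = n_nt, delta_g = delta_g, dx_ts = dx_ts,
                 k0 = k0, prerequisites = as.character(prerequisites),
                 coop_prob = coop_prob, delta_l = delta_l),
            class = "structure_species")
}

#' @export
print.structure_species <- function(x, ...) {
  cat(sprintf("species %-10s n=%3d nt  dL=%6.2f nm  dG=%5.1f kcal/mol  dx=%4.2f nm  k0=%s\n",
              x$id, x$n_nt, x$delta_l, x$delta_g, x$dx_ts,
              if (is.null(x$k0)) "(uncalibrated)" else sprintf("%.3g /s", x$k0)))
  invisible(x)
}

#' Thermodynamically consistent zero-force unfolding rate
#'
#' Solves for `k0` such that the simulated nonequilibrium unfolding works
#' satisfy the Jarzynski equality for the species' stated folding free
#' energy: `E[exp(-W(F)/kT)] = exp(-dG/kT)`, where the expectation runs over
#' the Bell-Evans rupture-force density at the given loading rate and
#' `W(F) = delta_l * int_0^F phi_ss(f) df` is the work of releasing and
#' stretching `delta_l` of ssDNA contour at rupture force F. The left-hand
#' side is monotone in `k0`, so the root is unique.
#'
#' @param species A [structure_species()] (its `k0` is ignored).
#' @param loading_rate Force loading rate in pN/s.
#' @param constants A [physical_constants()] object.
#' @param ss_persistence ssDNA persistence length in nm.
#' @return The calibrated `k0` in 1/s.
#' @export
calibrate_k0 <- function(species, loading_rate,
                         constants = physical_constants(),
                         ss_persistence = 0.8) {
  stopifnot(inherits(species, "structure_species"), loading_rate > 0)
  kT <- constants$kT
  dx <- species$dx_ts
  dG <- kcal_to_pn_nm(species$delta_g, constants)
  prof <- polymer_profile(ss_persistence, constants)
  f <- seq(0, prof$f_max, by = 0.02)
  w <- species$delta_l * prof$Phi(f)
  objective <- function(log_k0) {
    k0 <- exp(log_k0)
    dens <- (k0 * exp(f * dx / kT) / loading_rate) *
      exp((k0 * kT) / (loading_rate * dx) * (1 - exp(f * dx / kT)))
    m <- min(w)
    log(sum(dens * exp(-(w - m) / kT)) * 0.02) - m / kT + dG / kT
  }
  exp(stats::uniroot(objective, c(-90, 12), tol = 1e-12)$root)
}

# ---- scenarios ----------------------------------------------------------

#' Assemble a force-ramp simulation scenario
#'
#' A scenario bundles the construct's species, the refolding-configuration
#' mixture that each pulling cycle samples from, and the instrument
#' parameters of the ramp.
#'
#' Each configuration is a list with elements `prob` and `stages`, where
#' `stages` is a list of character vectors of species ids. Stages rupture in
#' order (a later stage only becomes rupturable once the previous stage has
#' fully ruptured, implemented as a hazard restart at the previous stage's
#' last rupture force); species within one stage rupture in the order of
#' their drawn forces. A single-species stage whose species has
#' `coop_prob > 0` and whose prerequisite forms the previous stage is merged
#' with that prerequisite into one cooperative event with probability
#' `coop_prob`.
#'
#' @param label Scenario name.
#' @param species List of [structure_species()] objects.
#' @param configurations List of `list(prob =, stages =)` entries; the
#'   probabilities must sum to one.
#' @param handle_bp Lengths of the two dsDNA handles in base pairs.
#' @param loading_rate Ramp rate in pN/s (5.5 in the experiments modelled).
#' @param max_force Maximum ramp force in pN.
#' @param overstretch_force Force of the dsDNA overstretching plateau used
#'   as the single-tether fingerprint (65 pN).
#' @param noise_sd Gaussian noise on the recorded force, pN.
#' @param sample_rate Sampling rate in Hz.
#' @param refold_probs Named vector of per-species refolding probabilities
#'   between cycles (default 1 for every species).
#' @param premature_break_prob Per-cycle probability that the tether breaks
#'   before the ramp completes; a broken molecule yields no further cycles.
#' @param full_fold_nm Summed Delta-L of the fully folded construct in nm,
#'   used by trace selection. Defaults to the largest configuration total.
#' @param conversion A [calibrate_conversion()] model (stored for analysis
#'   defaults and species sizing by builders).
#' @param constants A [physical_constants()] object.
#' @return An object of class `ramp_scenario`. Species without `k0` are
#'   calibrated at the scenario's loading rate; cooperative composites are
#'   pre-built for every (prerequisite, dependent) pair with
#'   `coop_prob > 0`.
#' @export
scenario <- function(label, species, configurations,
                     handle_bp = c(2028, 2690), loading_rate = 5.5,
                     max_force = 68, overstretch_force = 65,
                     noise_sd = 0.2, sample_rate = 200,
                     refold_probs = NULL, premature_break_prob = 0,
                     full_fold_nm = NULL,
                     conversion = calibrate_conversion(),
                     constants = physical_constants()) {
  stopifnot(length(handle_bp) == 2L, loading_rate > 0, max_force > 0,
            noise_sd >= 0, sample_rate > 0,
            premature_break_prob >= 0, premature_break_prob <= 1)
  if (inherits(species, "structure_species")) species <- list(species)
  ids <- vapply(species, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate species ids", call. = FALSE)
  names(species) <- ids
  check_prereq_dag(species)

  probs <- vapply(configurations, `[[`, numeric(1), "prob")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("configuration probabilities must sum to 1", call. = FALSE)
  for (cfg in configurations) {
    cfg_ids <- unlist(cfg$stages)
    if (!all(cfg_ids %in% ids))
      stop("configuration references unknown species: ",
           paste(setdiff(cfg_ids, ids), collapse = ", "), call. = FALSE)
    seen <- character()
    for (st in cfg$stages) {
      for (sid in st) {
        miss <- setdiff(intersect(species[[sid]]$prerequisites, cfg_ids), seen)
        if (length(miss))
          stop("configuration stage order violates prerequisites of ", sid,
               call. = FALSE)
      }
      seen <- c(seen, st)
    }
  }

  for (i in seq_along(species)) {
    if (is.null(species[[i]]$k0))
      species[[i]]$k0 <- calibrate_k0(species[[i]], loading_rate, constants)
  }

  # pre-build cooperative composites. A cooperative event unravels one
  # merged folded unit, so when both partners' sizes follow the calibrated
  # conversion the composite Delta-L is the conversion of the summed
  # nucleotide count (one folded-end correction), not the sum of the two
  # conversions; otherwise the released contours simply add.
  merged <- list()
  for (sp in species) {
    if (sp$coop_prob > 0 && length(sp$prerequisites) == 1L) {
      pre <- species[[sp$prerequisites]]
      n_sum <- pre$n_nt + sp$n_nt
      dl_sum <-
        if (abs(pre$delta_l - nt_to_delta_l(pre$n_nt, conversion)) < 1e-9 &&
            abs(sp$delta_l - nt_to_delta_l(sp$n_nt, conversion)) < 1e-9)
          nt_to_delta_l(n_sum, conversion)
        else pre$delta_l + sp$delta_l
      comp <- structure_species(
        id = paste(pre$id, sp$id, sep = "+"),
        n_nt = n_sum,
        delta_g = pre$delta_g + sp$delta_g,
        dx_ts = if (!is.null(sp$coop_dx_ts)) sp$coop_dx_ts else sp$dx_ts,
        delta_l = dl_sum)
      comp$k0 <- calibrate_k0(comp, loading_rate, constants)
      merged[[sp$id]] <- comp
    }
  }

  if (is.null(full_fold_nm)) {
    totals <- vapply(configurations, function(cfg)
      sum(vapply(unlist(cfg$stages), function(sid) species[[sid]]$delta_l,
                 numeric(1))), numeric(1))
    full_fold_nm <- max(totals)
  }

  out <- list(label = label, species = species,
              configurations = configurations, merged = merged,
              handle_bp = handle_bp, loading_rate = loading_rate,
              max_force = max_force, overstretch_force = overstretch_force,
              noise_sd = noise_sd, sample_rate = sample_rate,
              refold_probs = refold_probs,
              premature_break_prob = premature_break_prob,
              full_fold_nm = full_fold_nm,
              conversion = conversion, constants = constants)
  out$hash <- scenario_hash(out)
  class(out) <- "ramp_scenario"
  out
}

check_prereq_dag <- function(species) {
  ids <- names(species)
  edges <- do.call(rbind, lapply(species, function(sp) {
    if (length(sp$prerequisites))
      cbind(sp$prerequisites, sp$id)
    else NULL
  }))
  if (is.null(edges)) return(invisible(TRUE))
  if (!all(edges[, 1] %in% ids))
    stop("unknown prerequisite ids: ",
         paste(setdiff(edges[, 1], ids), collapse = ", "), call. = FALSE)
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!igraph::is_dag(g))
    stop("prerequisite graph contains a cycle", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ramp_scenario <- function(x, ...) {
  cat(sprintf("Force-ramp scenario '%s': %d species, %d refolding configurations\n",
              x$label, length(x$species), length(x$configurations)))
  cat(sprintf("  handles %d + %d bp, %.1f pN/s, max %.0f pN, overstretch %.0f pN, noise %.2f pN @ %g Hz\n",
              x$handle_bp[1], x$handle_bp[2], x$loading_rate, x$max_force,
              x$overstretch_force, x$noise_sd, x$sample_rate))
  for (sp in x$species) print(sp)
  invisible(x)
}

# stable content hash (FNV-1a over a deparsed parameter summary)
scenario_hash <- function(sc) {
  key <- paste(sc$label, sc$loading_rate, sc$max_force, sc$noise_sd,
               paste(vapply(sc$species, function(s)
                 paste(s$id, s$n_nt, signif(s$delta_g, 8), signif(s$dx_ts, 8),
                       signif(s$k0, 8), signif(s$delta_l, 8), collapse = ":"),
                 character(1)), collapse = ";"),
               sep = "|")
  fnv1a(key)
}

fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(lo8, b %% 256)
    # 32-bit multiply by the FNV prime 16777619 without double overflow
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Built-in twin scenarios of the hTERT promoter constructs
#'
#' Ready-made scenarios emulating the five constructs studied by native
#' mechanical segmentation of the hTERT 1-12 G-tract region:
#' \describe{
#'   \item{`NMS1-4`}{the 5'-end G-quadruplex (18 nt) with the 3-nt
#'     inter-quadruplex stacking release, a 14-nt G-triplex intermediate
#'     configuration, and a 30\% cooperative single-step fraction among
#'     full-fold cycles.}
#'   \item{`NMS5-12`}{the 3'-end G-quadruplex block with species of
#'     15/26/32/42/47 nt and the 5-nt stacking release; 31\% of cycles
#'     unfold in a single step.}
#'   \item{`hTERT1-12`}{both quadruplexes with the 7-nt stacking release;
#'     refolding configurations realise the 65/24/11 split between
#'     5'-first, 3'-first and all-at-once unfolding.}
#'   \item{`truncated1-4`, `truncated1-4+7nt`}{the isolated 5' quadruplex
#'     with no stacking partner; the extra 7-nt tail does not fold.}
#' }
#' The stacking interaction is assigned 2.0 kcal/mol throughout; per-species
#' `k0` are calibrated for thermodynamic consistency at the scenario's
#' loading rate, with transition-state distances placed so modal rupture
#' forces fall in the experimentally observed 10-45 pN range.
#'
#' @param label A single scenario label, or `NULL` for the named list of all
#'   five. Unicode dashes in labels are tolerated.
#' @param loading_rate Ramp rate in pN/s.
#' @param noise_sd Recorded-force noise in pN.
#' @param constants A [physical_constants()] object.
#' @return A `ramp_scenario`, or a named list of them when `label = NULL`.
#' @export
builtin_scenarios <- function(label = NULL, loading_rate = 5.5,
                              noise_sd = 0.2,
                              constants = physical_constants()) {
  conv <- calibrate_conversion()
  dl <- function(n) nt_to_delta_l(n, conv)
  sp <- function(id, n, dg, dx, prereq = character(), coop = 0)
    structure_species(id, n, dg, dx, prerequisites = prereq,
                      coop_prob = coop, delta_l = dl(n))
  mk <- function(label, species, configurations, full_fold_nm)
    scenario(label, species, configurations,
             loading_rate = loading_rate, noise_sd = noise_sd,
             full_fold_nm = full_fold_nm, conversion = conv,
             constants = constants)

  build <- list(
    "NMS1-4" = function() {
      g4 <- sp("G4_18", 18, 8, 7.0, prereq = "QQI3", coop = 1)
      g4$coop_dx_ts <- 8.5
      mk("NMS1-4",
         list(sp("QQI3", 3, 2, 1.5), g4, sp("TRI14", 14, 5, 2.7)),
         list(list(prob = 0.225, stages = list("QQI3", "G4_18")),
              list(prob = 0.525, stages = list("G4_18")),
              list(prob = 0.250, stages = list("TRI14"))),
         full_fold_nm = dl(21))
    },
    "NMS5-12" = function() {
      mk("NMS5-12",
         list(sp("QQI5", 5, 2, 1.5),
              sp("G4_42", 42, 14, 2.7, prereq = "QQI5"),
              sp("H26", 26, 6, 1.6),
              sp("H15", 15, 4, 0.9),
              sp("P32", 32, 9, 2.5),
              sp("ALL47", 47, 16, 3.0)),
         list(list(prob = 0.31, stages = list("ALL47")),
              list(prob = 0.24, stages = list("QQI5", "G4_42")),
              list(prob = 0.20, stages = list("QQI5", "H26", "H15")),
              list(prob = 0.25, stages = list("P32", "H15"))),
         full_fold_nm = 18)
    },
    "hTERT1-12" = function() {
      mk("hTERT1-12",
         list(sp("QQI7", 7, 2, 1.5),
              sp("G4_5pA", 18, 8, 2.2, prereq = "QQI7"),
              sp("G4_5pB", 18, 8, 1.3, prereq = "QQI7"),
              sp("BLK43", 43, 14, 2.7, prereq = "QQI7"),
              sp("ALL68", 68, 24, 4.0)),
         list(list(prob = 0.11, stages = list("ALL68")),
              list(prob = 0.65, stages = list("QQI7", "G4_5pA", "BLK43")),
              list(prob = 0.24, stages = list("QQI7", "BLK43", "G4_5pB"))),
         full_fold_nm = 25)
    },
    "truncated1-4" = function() {
      mk("truncated1-4",
         list(sp("G4_18", 18, 8, 7.0), sp("TRI14", 14, 5, 2.7)),
         list(list(prob = 0.70, stages = list("G4_18")),
              list(prob = 0.30, stages = list("TRI14"))),
         full_fold_nm = dl(18))
    },
    "truncated1-4+7nt" = function() {
      # the 7-nt inter-quadruplex tail does not fold on its own: same
      # species content as the plain truncation
      mk("truncated1-4+7nt",
         list(sp("G4_18", 18, 8, 7.0), sp("TRI14", 14, 5, 2.7)),
         list(list(prob = 0.70, stages = list("G4_18")),
              list(prob = 0.30, stages = list("TRI14"))),
         full_fold_nm = dl(18))
    }
  )

  if (is.null(label))
    return(lapply(build, function(f) f()))
  key <- normalize_label(label)
  hit <- match(key, vapply(names(build), normalize_label, character(1)))
  if (is.na(hit))
    stop("unknown scenario label '", label, "'; available: ",
         paste(names(build), collapse = ", "), call. = FALSE)
  build[[hit]]()
}

normalize_label <- function(x) {
  x <- gsub("–|—|−", "-", x)
  tolower(gsub("[[:space:]]", "", x))
}

#' Read or write a scenario as structured text
#'
#' Scenarios serialise to JSON (species, configurations and ramp settings).
#' Calibrated `k0` values are stored so a round trip is exact.
#'
#' @param sc A `ramp_scenario`.
#' @param path File path.
#' @export
write_scenario <- function(sc, path) {
  stopifnot(inherits(sc, "ramp_scenario"))
  doc <- list(
    label = sc$label,
    species = lapply(unname(sc$species), function(s)
      s[intersect(c("id", "n_nt", "delta_g", "dx_ts", "k0", "prerequisites",
                    "coop_prob", "delta_l", "coop_dx_ts"), names(s))]),
    configurations = sc$configurations,
    handle_bp = sc$handle_bp, loading_rate = sc$loading_rate,
    max_force = sc$max_force, overstretch_force = sc$overstretch_force,
    noise_sd = sc$noise_sd, sample_rate = sc$sample_rate,
    refold_probs = sc$refold_probs,
    premature_break_prob = sc$premature_break_prob,
    full_fold_nm = sc$full_fold_nm,
    temperature = sc$constants$temperature)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  needed <- c("label", "species", "configurations")
  if (!all(needed %in% names(doc)))
    stop("scenario file missing required fields: ",
         paste(setdiff(needed, names(doc)), collapse = ", "), call. = FALSE)
  species <- lapply(doc$species, function(s) {
    sp <- structure_species(s$id, s$n_nt, s$delta_g, s$dx_ts, k0 = s$k0,
                            prerequisites = unlist(s$prerequisites),
                            coop_prob = s$coop_prob, delta_l = s$delta_l)
    if (!is.null(s$coop_dx_ts)) sp$coop_dx_ts <- s$coop_dx_ts
    sp
  })
  cfgs <- lapply(doc$configurations, function(cfg)
    list(prob = cfg$prob,
         stages = lapply(cfg$stages, function(st) unlist(st))))
  scenario(doc$label, species, cfgs,
           handle_bp = unlist(doc$handle_bp),
           loading_rate = doc$loading_rate, max_force = doc$max_force,
           overstretch_force = doc$overstretch_force,
           noise_sd = doc$noise_sd, sample_rate = doc$sample_rate,
           refold_probs = if (!is.null(doc$refold_probs))
             unlist(doc$refold_probs),
           premature_break_prob = doc$premature_break_prob,
           full_fold_nm = doc$full_fold_nm,
           constants = physical_constants(doc$temperature))
}
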