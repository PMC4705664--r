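#' Full-fold Delta-L of the built-in constructs
#'
#' The summed Delta-L identifying a fully folded molecule: 25 nm (68 nt)
#' for hTERT1-12, 18 nm (48 nt) for NMS5-12, and the calibrated conversion
#' values for the 21-nt NMS1-4 and 18-nt truncated constructs.
#'
#' @param construct Construct label (as in [builtin_scenarios()]).
#' @param conversion A [calibrate_conversion()] model.
#' @return Full-fold Delta-L in nm.
#' @export
construct_full_fold <- function(construct,
                                conversion = calibrate_conversion()) {
  key <- normalize_label(construct)
  known <- c("htert1-12", "nms5-12", "nms1-4", "truncated1-4",
             "truncated1-4+7nt")
  if (!key %in% known)
    stop("unknown construct '", construct, "'", call. = FALSE)
  switch(key,
         "htert1-12" = 25,
         "nms5-12" = 18,
         "nms1-4" = nt_to_delta_l(21, conversion),
         nt_to_delta_l(18, conversion))
}

#' Select molecules and cycles showing the fully folded structure
#'
#' Keeps molecules with at least one cycle whose summed Delta-L falls
#' within `tol_nm` of the construct's full-fold Delta-L, and restricts the
#' returned events to those full-fold cycles. With `require_complete =
#' TRUE` (the hTERT1-12 rule) a molecule must additionally show at least
#' one cycle that unfolds completely during the ramp, as flagged in
#' `cycles_info$complete` (e.g. from the simulator log, or from traces that
#' reach the overstretching fingerprint without a premature break).
#'
#' @param events Event table with `molecule_id`, `cycle`, `delta_l_nm`.
#' @param full_fold_nm Full-fold Delta-L in nm.
#' @param tol_nm Tolerance on the summed Delta-L.
#' @param require_complete Apply the fully-unfolded-trace requirement.
#' @param cycles_info Optional per-cycle data frame with `molecule_id`,
#'   `cycle` and logical `complete`.
#' @param cycles Which cycles of the selected molecules to return:
#'   `"full_fold"` (pathway statistics start from the fully folded state)
#'   or `"all"` (population histograms keep every cycle of a selected
#'   molecule, including partially refolded ones).
#' @return The filtered event table; the per-cycle summary (all cycles,
#'   with `selected` flags) is attached as attribute `"cycles"`.
#' @export
select_full_fold_traces <- function(events, full_fold_nm, tol_nm = 2,
                                    require_complete = FALSE,
                                    cycles_info = NULL,
                                    cycles = c("full_fold", "all")) {
  cycles <- match.arg(cycles)
  stopifnot(is.data.frame(events),
            all(c("molecule_id", "cycle", "delta_l_nm") %in% names(events)))
  key <- interaction(events$molecule_id, events$cycle, drop = TRUE)
  sums <- tapply(events$delta_l_nm, key, sum)
  cyc <- data.frame(molecule_id = tapply(events$molecule_id, key, `[`, 1),
                    cycle = as.integer(tapply(events$cycle, key, `[`, 1)),
                    sum_delta_l_nm = as.numeric(sums))
  cyc$full_fold <- abs(cyc$sum_delta_l_nm - full_fold_nm) <= tol_nm
  keep_mol <- unique(cyc$molecule_id[cyc$full_fold])
  if (require_complete) {
    if (is.null(cycles_info) || !"complete" %in% names(cycles_info))
      stop("require_complete needs cycles_info with a 'complete' column",
           call. = FALSE)
    mol_complete <- unique(cycles_info$molecule_id[cycles_info$complete])
    keep_mol <- intersect(keep_mol, mol_complete)
  }
  cyc$selected <- cyc$molecule_id %in% keep_mol &
    (cyc$full_fold | cycles == "all")
  sel_key <- paste(cyc$molecule_id, cyc$cycle)[cyc$selected]
  out <- events[paste(events$molecule_id, events$cycle) %in% sel_key, ,
                drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cycles") <- cyc
  out
}

#' Assign events to Delta-L populations and rank them
#'
#' Bins each event to the nearest population center (bins of `bin_width`
#' around the centers, the 4 nm default reflecting three standard
#' deviations of typical Delta-L scatter), converts the center to a
#' canonical nucleotide count, and ranks events within each cycle by their
#' order of occurrence. Two transitions of near-identical Delta-L in one
#' trace thus become distinct states distinguished by rank. Events farther
#' than `bin_width / 2` from every center are labelled `"unclassified"`;
#' midpoint ties go to the smaller center.
#'
#' @param events Event table with `molecule_id`, `cycle`, `f_rupture_pn`,
#'   `delta_l_nm`.
#' @param centers Population centers in nm (e.g. from
#'   [podnano_deconvolve()]).
#' @param conversion A [calibrate_conversion()] model.
#' @param bin_width Bin width in nm.
#' @return The event table with `assigned_center_nm`, `assigned_nt`,
#'   `assigned_state` and `rank` columns.
#' @export
bin_and_rank <- function(events, centers, conversion = calibrate_conversion(),
                         bin_width = 4) {
  stopifnot(length(centers) >= 1, bin_width > 0)
  centers <- sort(centers)
  d <- abs(outer(events$delta_l_nm, centers, "-"))
  nearest <- apply(d, 1, which.min)   # ties resolve to the smaller center
  mind <- d[cbind(seq_len(nrow(events)), nearest)]
  ok <- mind <= bin_width / 2
  events$assigned_center_nm <- ifelse(ok, centers[nearest], NA_real_)
  nts <- suppressWarnings(delta_l_to_nt(centers, conversion))
  events$assigned_nt <- ifelse(ok, nts[nearest], NA_integer_)
  events$assigned_state <- ifelse(ok, sprintf("%dnt", nts[nearest]),
                                  "unclassified")
  ord <- order(events$molecule_id, events$cycle, events$f_rupture_pn)
  events <- events[ord, , drop = FALSE]
  key <- paste(events$molecule_id, events$cycle)
  events$rank <- stats::ave(seq_along(key), key, FUN = seq_along)
  rownames(events) <- NULL
  events
}

#' Build the unfolding transition graph
#'
#' Infers the state sequence of every cycle from its own events: the
#' initial state holds the cycle's total assigned nucleotides, and each
#' rupture moves to the state with that event's nucleotides removed. Counts
#' and per-state outgoing percentages are aggregated over cycles. Cycles
#' containing unclassified events are excluded and reported.
#'
#' @param events Output of [bin_and_rank()].
#' @return An object of class `transition_graph`: list with `states`
#'   (remaining-nt labels with visit counts), `edges` (`from_nt`, `to_nt`,
#'   `count`, `percent` of transitions leaving `from_nt`), `graph` (an
#'   igraph DAG), `n_cycles`, and `excluded_cycles`.
#' @export
build_transition_graph <- function(events) {
  stopifnot(all(c("assigned_nt", "rank") %in% names(events)))
  key <- paste(events$molecule_id, events$cycle)
  bad <- unique(key[is.na(events$assigned_nt)])
  use <- !(key %in% bad)
  ev <- events[use, , drop = FALSE]
  if (!nrow(ev)) stop("no classifiable cycles", call. = FALSE)
  key <- key[use]
  from_l <- list(); to_l <- list()
  for (k in unique(key)) {
    nts <- ev$assigned_nt[key == k][order(ev$rank[key == k])]
    s <- sum(nts)
    states <- s - cumsum(c(0, nts))
    if (any(states < 0)) { bad <- c(bad, k); next }
    from_l[[k]] <- states[-length(states)]
    to_l[[k]] <- states[-1]
  }
  from <- unlist(from_l, use.names = FALSE)
  to <- unlist(to_l, use.names = FALSE)
  tab <- stats::aggregate(count ~ from_nt + to_nt,
                          data = data.frame(from_nt = from, to_nt = to,
                                            count = 1),
                          FUN = sum)
  tab <- tab[order(-tab$from_nt, -tab$to_nt), , drop = FALSE]
  out_tot <- tapply(tab$count, tab$from_nt, sum)
  tab$percent <- 100 * tab$count / as.numeric(out_tot[as.character(tab$from_nt)])
  states <- data.frame(nt = sort(unique(c(from, to)), decreasing = TRUE))
  states$n_visits <- vapply(states$nt, function(s)
    sum(from == s) + sum(to == s & s == 0), numeric(1))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(tab$from_nt),
               to = as.character(tab$to_nt)),
    vertices = data.frame(name = as.character(states$nt)))
  rownames(tab) <- NULL
  structure(list(states = states, edges = tab, graph = g,
                 n_cycles = length(unique(key[!(key %in% bad)])),
                 excluded_cycles = unique(bad)),
            class = "transition_graph")
}

#' @export
print.transition_graph <- function(x, ...) {
  cat(sprintf("Unfolding transition graph: %d states, %d edges, %d cycles (%d excluded)\n",
              nrow(x$states), nrow(x$edges), x$n_cycles,
              length(x$excluded_cycles)))
  for (i in seq_len(nrow(x$edges)))
    cat(sprintf("  %3d nt -> %3d nt  %4d  (%5.1f%%)\n",
                x$edges$from_nt[i], x$edges$to_nt[i], x$edges$count[i],
                x$edges$percent[i]))
  invisible(x)
}

#' Export a transition graph
#'
#' Writes the edge list as TSV and, optionally, the graph in GraphML for
#' network-visualisation tools.
#'
#' @param tg A [build_transition_graph()] result.
#' @param edges_path TSV output path.
#' @param graphml_path Optional GraphML output path.
#' @export
write_transition_graph <- function(tg, edges_path, graphml_path = NULL) {
  utils::write.table(
    data.frame(from_state = tg$edges$from_nt, to_state = tg$edges$to_nt,
               count = tg$edges$count,
               percent = sprintf("%.4f", tg$edges$percent)),
    edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(tg$graph, graphml_path, format = "graphml")
  invisible(edges_path)
}

#' Fraction of cycles unfolding cooperatively in a single step
#'
#' A cooperative cycle shows exactly one rupture whose Delta-L matches the
#' construct's fully folded signature. Because the published statistics mix
#' per-trace and per-molecule phrasing, both are reported.
#'
#' @param events Event table (typically after full-fold selection).
#' @param full_fold_nm Cooperative signature Delta-L in nm.
#' @param tol_nm Matching tolerance; tighter than the full-fold selection
#'   tolerance so that single-step events one population below the full
#'   fold are not miscounted as cooperative.
#' @return A list with `per_trace` (fraction of cycles), `per_molecule`
#'   (fraction of molecules with at least one cooperative cycle),
#'   `n_cycles` and `n_molecules`.
#' @export
cooperative_fraction <- function(events, full_fold_nm, tol_nm = 1) {
  key <- interaction(events$molecule_id, events$cycle, drop = TRUE)
  n_ev <- tapply(events$delta_l_nm, key, length)
  sums <- tapply(events$delta_l_nm, key, sum)
  mols <- tapply(events$molecule_id, key, `[`, 1)
  coop <- n_ev == 1 & abs(sums - full_fold_nm) <= tol_nm
  list(per_trace = mean(coop),
       per_molecule = if (length(coop))
         mean(tapply(coop, mols, any)) else NaN,
       n_cycles = length(coop),
       n_molecules = length(unique(mols)))
}
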