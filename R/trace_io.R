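#' Force-extension trace container
#'
#' One stretch or relax ramp of a single tether: ordered (extension, force)
#' samples plus identifying metadata.
#'
#' @param molecule_id Molecule label.
#' @param cycle Cycle index (>= 1).
#' @param direction `"stretch"` or `"relax"`.
#' @param extension Extension samples in nm.
#' @param force Force samples in pN (non-negative), same length.
#' @param metadata Named list carried in file headers (loading rate,
#'   temperature, seed, scenario hash, ...).
#' @return An object of class `fx_trace`.
#' @export
fx_trace <- function(molecule_id, cycle, direction, extension, force,
                     metadata = list()) {
  direction <- match.arg(direction, c("stretch", "relax"))
  if (length(extension) != length(force))
    stop("extension and force must have equal length", call. = FALSE)
  if (length(force) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (any(force < 0))
    stop("force must be non-negative", call. = FALSE)
  structure(list(molecule_id = as.character(molecule_id),
                 cycle = as.integer(cycle), direction = direction,
                 samples = data.frame(extension_nm = as.numeric(extension),
                                      force_pn = as.numeric(force)),
                 metadata = metadata),
            class = "fx_trace")
}

#' @export
print.fx_trace <- function(x, ...) {
  cat(sprintf("F-X trace %s cycle %d (%s): %d samples, %.1f-%.1f pN\n",
              x$molecule_id, x$cycle, x$direction, nrow(x$samples),
              min(x$samples$force_pn), max(x$samples$force_pn)))
  invisible(x)
}

#' @export
plot.fx_trace <- function(x, ...) {
  graphics::plot(x$samples$extension_nm, x$samples$force_pn, type = "l",
                 xlab = "extension (nm)", ylab = "force (pN)",
                 main = sprintf("%s cycle %d (%s)", x$molecule_id, x$cycle,
                                x$direction), ...)
  invisible(x)
}

TRACE_COLUMNS <- c("molecule_id", "cycle", "direction", "extension_nm",
                   "force_pn")

#' Write force-extension traces to tab-separated text
#'
#' One sample per row with columns `molecule_id`, `cycle`, `direction`,
#' `extension_nm`, `force_pn`. Header comment lines (`#`) declare the units
#' and carry metadata from the first trace; the dialect is deterministic, so
#' identical inputs give byte-identical files.
#'
#' @param traces A single [fx_trace()] or a list of them.
#' @param path Output path.
#' @export
write_trace <- function(traces, path) {
  if (inherits(traces, "fx_trace")) traces <- list(traces)
  stopifnot(all(vapply(traces, inherits, logical(1), "fx_trace")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#format: rampfold-fx-trace v1", con)
  writeLines("#units: extension_nm=nm force_pn=pN", con)
  if (length(traces)) {
    meta <- traces[[1]]$metadata
    for (key in names(meta))
      writeLines(sprintf("#%s: %s", key, format(meta[[key]], digits = 12)),
                 con)
  }
  writeLines(paste(TRACE_COLUMNS, collapse = "\t"), con)
  for (tr in traces) {
    n <- nrow(tr$samples)
    writeLines(paste(tr$molecule_id, tr$cycle, tr$direction,
                     sprintf("%.10g", tr$samples$extension_nm),
                     sprintf("%.10g", tr$samples$force_pn), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read force-extension traces written by [write_trace()]
#'
#' @param path Input path.
#' @return A list of [fx_trace()] objects (empty, with a warning, for a file
#'   with no data rows). Missing columns, undeclared units and non-monotone
#'   cycle indices within a molecule/direction block raise format errors;
#'   malformed rows are reported with their line numbers.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  header_meta <- parse_header(lines[is_comment])
  units <- header_meta[["units"]]
  if (is.null(units) || !grepl("extension_nm=nm", units, fixed = TRUE) ||
      !grepl("force_pn=pN", units, fixed = TRUE))
    stop("trace file does not declare extension_nm=nm force_pn=pN units",
         call. = FALSE)
  body_idx <- which(!is_comment & nzchar(lines))
  if (!length(body_idx)) {
    warning("trace file has no data rows", call. = FALSE)
    return(list())
  }
  cols <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!all(TRACE_COLUMNS %in% cols))
    stop("trace file missing required columns: ",
         paste(setdiff(TRACE_COLUMNS, cols), collapse = ", "),
         call. = FALSE)
  rows_idx <- body_idx[-1]
  if (!length(rows_idx)) {
    warning("trace file has a header but no samples", call. = FALSE)
    return(list())
  }
  parts <- strsplit(lines[rows_idx], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad))
    stop("malformed trace rows at line(s) ",
         paste(utils::head(rows_idx[bad], 10), collapse = ", "),
         call. = FALSE)
  m <- do.call(rbind, parts)
  df <- data.frame(molecule_id = m[, match("molecule_id", cols)],
                   cycle = as.integer(m[, match("cycle", cols)]),
                   direction = m[, match("direction", cols)],
                   extension_nm = as.numeric(m[, match("extension_nm", cols)]),
                   force_pn = as.numeric(m[, match("force_pn", cols)]))
  nab <- which(is.na(df$cycle) | is.na(df$extension_nm) | is.na(df$force_pn))
  if (length(nab))
    stop("unparseable numeric fields at line(s) ",
         paste(utils::head(rows_idx[nab], 10), collapse = ", "),
         call. = FALSE)
  meta <- header_meta[setdiff(names(header_meta), c("format", "units"))]
  key <- paste(df$molecule_id, df$direction, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    if (is.unsorted(sub$cycle))
      stop("non-monotone cycle indices for ", sub$molecule_id[1], " (",
           sub$direction[1], ")", call. = FALSE)
    for (cyc in unique(sub$cycle)) {
      s <- sub[sub$cycle == cyc, , drop = FALSE]
      out[[length(out) + 1L]] <- fx_trace(s$molecule_id[1], cyc,
                                          s$direction[1], s$extension_nm,
                                          s$force_pn, metadata = meta)
    }
  }
  out
}

parse_header <- function(lines) {
  lines <- sub("^#", "", lines)
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), keys)
}

EVENT_COLUMNS <- c("molecule_id", "cycle", "rank", "f_rupture_pn",
                   "delta_x_nm", "delta_l_nm", "delta_l_se_nm",
                   "assigned_state")

#' Read and write rupture-event tables
#'
#' Tab-separated event tables with header comments carrying provenance
#' (scenario hash, seed). Columns: molecule_id, cycle, rank, f_rupture_pn,
#' delta_x_nm, delta_l_nm, delta_l_se_nm, assigned_state. Extra columns are
#' preserved.
#'
#' @param events Data frame of rupture events.
#' @param path File path.
#' @param metadata Named list written to header comments.
#' @export
write_events <- function(events, path, metadata = list()) {
  stopifnot(is.data.frame(events))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#format: rampfold-events v1", con)
  writeLines("#units: f_rupture_pn=pN delta_x_nm=nm delta_l_nm=nm delta_l_se_nm=nm",
             con)
  for (key in names(metadata))
    writeLines(sprintf("#%s: %s", key, format(metadata[[key]], digits = 12)),
               con)
  cols <- union(intersect(EVENT_COLUMNS, names(events)), names(events))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(events)) {
    fmt <- vapply(events[cols], function(col) {
      if (is.numeric(col) && !is.integer(col))
        sprintf("%.10g", col)
      else as.character(col)
    }, character(nrow(events)))
    if (nrow(events) == 1L) fmt <- matrix(fmt, nrow = 1L)
    writeLines(apply(fmt, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!nrow(df)) warning("event table is empty", call. = FALSE)
  df
}
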