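# Plain-text lead-field codec: TSV matrix + JSON sidecar + electrode and
# node CSVs. readr writes shortest round-trippable doubles, so
# load(save(lf)) reproduces the matrix exactly.

leadfield_paths <- function(path) {
  list(matrix = paste0(path, "_matrix.tsv"),
       sidecar = paste0(path, "_meta.json"),
       electrodes = paste0(path, "_electrodes.csv"),
       nodes = paste0(path, "_nodes.csv"))
}

#' Save / load a lead field as plain text
#'
#' `save_leadfield()` writes four sibling files sharing the prefix `path`:
#' `<path>_matrix.tsv` (rows = field entries, columns = electrodes),
#' `<path>_meta.json` (dimensions, layout tag, units, seed),
#' `<path>_electrodes.csv` (`label,x,y,z`) and `<path>_nodes.csv`
#' (`x,y,z`). `load_leadfield()` reads them back; the round trip is exact.
#'
#' @param lf A `lead_field`.
#' @param path File-path prefix (no extension).
#' @return `save_leadfield()` returns `path` invisibly; `load_leadfield()`
#'   returns a `lead_field`.
#' @export
save_leadfield <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  p <- leadfield_paths(path)
  # 17 significant digits guarantee an exact double round trip
  body <- apply(lf$matrix, 1, function(r) {
    paste(sprintf("%.17g", r), collapse = "\t")
  })
  writeLines(c(paste(lf$electrode_labels, collapse = "\t"), body), p$matrix)
  jsonlite::write_json(
    list(n_nodes = n_nodes(lf), n_electrodes = n_electrodes(lf),
         layout = lf$component_layout, units = "A/m^2 per mA",
         inner_radius = lf$inner_radius, seed = lf$seed),
    p$sidecar, auto_unbox = TRUE, digits = NA)
  readr::write_csv(
    tibble(label = lf$electrode_labels,
           x = lf$electrode_positions[, 1],
           y = lf$electrode_positions[, 2],
           z = lf$electrode_positions[, 3]),
    p$electrodes, progress = FALSE)
  readr::write_csv(
    tibble(x = lf$node_positions[, 1],
           y = lf$node_positions[, 2],
           z = lf$node_positions[, 3]),
    p$nodes, progress = FALSE)
  invisible(path)
}

#' @rdname save_leadfield
#' @export
load_leadfield <- function(path) {
  p <- leadfield_paths(path)
  for (f in unlist(p)) {
    if (!file.exists(f)) abort(sprintf("lead-field file missing: %s", f))
  }
  meta <- jsonlite::read_json(p$sidecar, simplifyVector = TRUE)
  required <- c("n_nodes", "n_electrodes", "layout")
  if (!all(required %in% names(meta))) {
    abort("lead-field sidecar is missing required metadata fields.")
  }
  if (!identical(meta$layout, "3 consecutive rows per node, Cartesian x,y,z")) {
    abort(sprintf("unknown component layout tag: %s", meta$layout))
  }
  header <- strsplit(readLines(p$matrix, n = 1L), "\t", fixed = TRUE)[[1]]
  vals <- scan(p$matrix, what = double(), skip = 1L, sep = "\t",
               quiet = TRUE)  # base scan parses doubles exactly
  if (length(vals) %% length(header) != 0L) {
    abort("lead-field matrix file is ragged or truncated (row length mismatch).")
  }
  mat <- matrix(vals, ncol = length(header), byrow = TRUE)
  if (ncol(mat) != meta$n_electrodes) {
    abort(sprintf("sidecar says L = %d electrodes but the matrix has %d columns.",
                  meta$n_electrodes, ncol(mat)))
  }
  if (nrow(mat) != 3L * meta$n_nodes) {
    abort(sprintf("sidecar says %d nodes (%d rows) but the matrix has %d rows.",
                  meta$n_nodes, 3L * meta$n_nodes, nrow(mat)))
  }
  el <- readr::read_csv(p$electrodes, show_col_types = FALSE, progress = FALSE)
  nd <- readr::read_csv(p$nodes, show_col_types = FALSE, progress = FALSE)
  if (nrow(el) != meta$n_electrodes || nrow(nd) != meta$n_nodes) {
    abort("electrode/node files do not match the sidecar dimensions.")
  }
  dimnames(mat) <- list(NULL, el$label)
  new_lead_field(mat, el$label, as.matrix(el[, c("x", "y", "z")]),
                 as.matrix(nd[, c("x", "y", "z")]),
                 meta$inner_radius %||% 1, as.integer(meta$seed %||% NA))
}
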