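#' Export a shape-mode decomposition to structured text
#'
#' Writes the mean shape, modes, singular values and variance fractions as
#' JSON, and the shape coefficients as a TSV (`frame`, `time_s`, `B1`..`Bk`).
#'
#' @param decomp a `shape_modes` object.
#' @param json_path output JSON path.
#' @param coeffs_path optional TSV path for the coefficients.
#' @param n_modes number of modes to export (default 4).
#' @return `json_path`, invisibly.
#' @export
write_decomposition <- function(decomp, json_path, coeffs_path = NULL,
                                n_modes = 4) {
  stopifnot(inherits(decomp, "shape_modes"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_flagellar("jsonlite is required for JSON export", "flagellar_parameter_error")
  ks <- seq_len(min(n_modes, length(decomp$singular_values)))
  jsonlite::write_json(
    list(arc_grid_um = decomp$arc_grid,
         psi0_rad = decomp$psi0,
         modes_rad = lapply(ks, function(k) decomp$modes[k, ]),
         singular_values = decomp$singular_values[ks],
         variance_fractions = decomp$variance_fractions[ks]),
    json_path, digits = NA)
  if (!is.null(coeffs_path))
    readr::write_tsv(shape_coefficients(decomp, n_modes = n_modes),
                     coeffs_path, progress = FALSE)
  invisible(json_path)
}

#' Export per-cell kinematics and power tables
#'
#' Writes the batch summary (one row per cell: POF, cycle statistics,
#' variance explained, whole-cell and regional powers in fW, VSL, regional
#' amplitudes) to TSV.
#'
#' @param batch a `batch_analysis`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cell_summary <- function(batch, path) {
  stopifnot(inherits(batch, "batch_analysis"))
  readr::write_tsv(batch$summary, path, progress = FALSE)
  invisible(path)
}
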