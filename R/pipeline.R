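#' Analyze a single cell end-to-end
#'
#' Runs the full pipeline on one centerline series: tangent angles, shape
#' modes, primary oscillation frequency, beat-cycle segmentation and
#' averaging, amplitude envelope, hydrodynamic power dissipation and the
#' projected free-swimming trajectory.
#'
#' @param series a [centerline_series()].
#' @param params an [rft_params()].
#' @param p_phase phase-grid points for the representative cycle.
#' @param boundaries regional boundaries in um (default `c(24, 104)`).
#' @return An object of class `cell_analysis`: list with `decomposition`,
#'   `pof_hz`, `cycles`, `beat_cycle`, `amplitude`, `power`, `trajectory`,
#'   `regional_power`, `regional_amplitude`.
#' @export
analyze_cell <- function(series, params = rft_params(), p_phase = 64,
                         boundaries = c(24, 104)) {
  stopifnot(inherits(series, "centerline_series"))
  field <- tangent_angles(series)
  decomp <- pod_decompose(field)
  pof <- primary_oscillation_frequency(decomp)
  cycles <- segment_beat_cycles(decomp)
  bca <- average_beat_cycle(series, cycles, p_phase = p_phase)
  amp <- flagellar_amplitude(bca)
  vel <- velocities(series)
  pw <- power_fields(vel, params)
  traj <- trajectory_and_vsl(
    translation_velocity(friction_tensor_integral(vel, params)),
    series$times, bca$period)
  structure(
    list(decomposition = decomp, pof_hz = as.numeric(pof),
         pof = pof, cycles = cycles, beat_cycle = bca, amplitude = amp,
         power = pw, trajectory = traj,
         regional_power = regional_summary(pw, boundaries = boundaries,
                                           type = "integral"),
         regional_amplitude = regional_summary(amp, boundaries = boundaries,
                                               type = "mean")),
    class = "cell_analysis")
}

#' @export
print.cell_analysis <- function(x, ...) {
  cat(sprintf("<cell_analysis> POF %.2f Hz | %d cycles | E = %.3g fW | VSL = %.3g um/s\n",
              x$pof_hz, x$beat_cycle$n_cycles, x$power$E_fW,
              x$trajectory$vsl_um_per_s))
  invisible(x)
}

#' @export
#' @method glance cell_analysis
glance.cell_analysis <- function(x, ...) {
  tibble(
    pof_hz = x$pof_hz,
    n_cycles = x$beat_cycle$n_cycles,
    period_s = x$beat_cycle$period,
    var_top2 = variance_explained(x$decomposition, 1:2),
    var_top4 = variance_explained(x$decomposition, 1:4),
    E_fW = x$power$E_fW,
    mid_piece_fW = x$regional_power$value[1] * 1e15,
    principal_piece_fW = x$regional_power$value[2] * 1e15,
    end_piece_fW = x$regional_power$value[3] * 1e15,
    vsl_um_per_s = x$trajectory$vsl_um_per_s,
    amp_mid = x$regional_amplitude$value[1],
    amp_principal = x$regional_amplitude$value[2],
    amp_end = x$regional_amplitude$value[3])
}

#' Analyze a batch of cells with per-cell failure isolation
#'
#' @param cells a tibble with columns `cell_id`, `group` and a `series`
#'   list-column (as from [generate_group()]), or a named list of
#'   [centerline_series()].
#' @inheritParams analyze_cell
#' @return A list of class `batch_analysis`: `results` (named list of
#'   `cell_analysis`), `summary` (one tidy row per cell), `failures`
#'   (tibble of cell_id + condition message for cells that errored).
#' @export
analyze_cells <- function(cells, params = rft_params(), p_phase = 64,
                          boundaries = c(24, 104)) {
  if (is.data.frame(cells)) {
    ids <- cells$cell_id
    groups <- if ("group" %in% names(cells)) cells$group else rep(NA_character_, nrow(cells))
    series_list <- cells$series
  } else {
    ids <- names(cells) %||% sprintf("cell%02d", seq_along(cells))
    groups <- rep(NA_character_, length(cells))
    series_list <- cells
  }
  results <- list(); fails <- list(); rows <- list()
  for (i in seq_along(series_list)) {
    res <- tryCatch(
      analyze_cell(series_list[[i]], params = params, p_phase = p_phase,
                   boundaries = boundaries),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble(cell_id = ids[i],
                                           message = conditionMessage(res))
    } else {
      results[[ids[i]]] <- res
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(cell_id = ids[i], group = groups[i]), glance(res))
    }
  }
  if (length(results) == 0)
    stop_flagellar("all cells failed to analyze", "flagellar_data_error")
  structure(list(results = results,
                 summary = dplyr::bind_rows(rows),
                 failures = dplyr::bind_rows(fails)),
            class = "batch_analysis")
}

#' @export
print.batch_analysis <- function(x, ...) {
  cat(sprintf("<batch_analysis> %d cells analyzed, %d failed\n",
              length(x$results), nrow(x$failures)))
  invisible(x)
}

#' Group-level comparison tables
#'
#' Builds the export-ready group tables: per-group means +/- SD of POF,
#' whole-cell dissipation and VSL; regional power integrals; and the
#' within/between-group Procrustes comparison of representative beat
#' patterns. No hypothesis testing is performed; the tables are meant for
#' downstream statistics tools.
#'
#' @param batch a `batch_analysis` from [analyze_cells()] whose summary has
#'   group labels.
#' @param variant Procrustes variant, `"rms"` (um) or `"sum"`.
#' @return A list of class `group_tables`: `kinematics` (per-group mean/SD
#'   of POF, E, VSL), `regional_power` (per-group regional means +/- SD in
#'   fW), `procrustes` (within/between table), `per_cell` (the batch
#'   summary).
#' @export
compare_groups <- function(batch, variant = c("rms", "sum")) {
  variant <- match.arg(variant)
  stopifnot(inherits(batch, "batch_analysis"))
  sm <- batch$summary
  if (all(is.na(sm$group)))
    stop_flagellar("no group labels present", "flagellar_parameter_error")
  n_per_group <- table(sm$group)
  if (any(n_per_group < 2))
    warn(sprintf("groups with fewer than 2 cells: %s",
                 paste(names(n_per_group)[n_per_group < 2], collapse = ", ")))
  kin <- sm |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      pof_hz_mean = mean(.data$pof_hz), pof_hz_sd = sd(.data$pof_hz),
      E_fW_mean = mean(.data$E_fW), E_fW_sd = sd(.data$E_fW),
      vsl_mean = mean(.data$vsl_um_per_s), vsl_sd = sd(.data$vsl_um_per_s),
      .groups = "drop")
  reg <- sm |>
    tidyr::pivot_longer(dplyr::all_of(c("mid_piece_fW", "principal_piece_fW",
                                        "end_piece_fW")),
                        names_to = "region", values_to = "power_fW") |>
    dplyr::group_by(.data$group, .data$region) |>
    dplyr::summarise(mean_fW = mean(.data$power_fW),
                     sd_fW = sd(.data$power_fW), .groups = "drop")
  patterns <- lapply(batch$results, function(r) r$beat_cycle)
  pro <- group_comparison(patterns, sm$group, variant = variant)
  structure(list(kinematics = kin, regional_power = reg, procrustes = pro,
                 per_cell = sm),
            class = "group_tables")
}

#' @export
print.group_tables <- function(x, ...) {
  cat("<group_tables>\n")
  print(x$kinematics)
  print(x$procrustes)
  invisible(x)
}

#' Simulate a synthetic dataset on disk
#'
#' Writes one centerline TSV per cell in the package dialect plus a JSON
#' ground-truth sidecar, and returns a manifest. A thin orchestration over
#' [generate_group()]; rerunning with the same seed reproduces the files
#' byte for byte.
#'
#' @param out_dir output directory (created if missing).
#' @param specs named list of group-level [wave_spec()] objects; names are
#'   the group labels.
#' @param n_cells cells per group.
#' @param jitter fractional per-cell parameter jitter.
#' @param seed integer seed.
#' @return A tibble manifest (`cell_id`, `group`, `path`), invisibly the
#'   same written to `manifest.tsv`.
#' @export
simulate_dataset <- function(out_dir, specs = list(group1 = wave_spec()),
                             n_cells = 25, jitter = 0.05, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mans <- list()
  for (gi in seq_along(specs)) {
    g <- names(specs)[gi] %||% paste0("group", gi)
    cells <- generate_group(specs[[gi]], n_cells = n_cells, jitter = jitter,
                            group = g, seed = seed + gi)
    paths <- character(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      paths[i] <- file.path(out_dir, paste0(cells$cell_id[i], ".tsv"))
      write_centerlines(cells$series[[i]], paths[i])
    }
    truth <- lapply(cells$series, function(s) {
      gt <- attr(s, "ground_truth")
      gt$envelope <- NULL  # per-arc vector; keep the sidecar compact
      gt
    })
    names(truth) <- cells$cell_id
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(truth, file.path(out_dir, paste0(g, "_truth.json")),
                           auto_unbox = TRUE, digits = NA)
    mans[[gi]] <- tibble(cell_id = cells$cell_id, group = g, path = paths)
  }
  manifest <- dplyr::bind_rows(mans)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  manifest
}
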