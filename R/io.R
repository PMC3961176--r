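# Output formats: sweep CSV, run manifests and regression fixtures.

#' Write a sweep table as CSV
#'
#' Machine-parseable CSV without comments; numeric columns are formatted
#' with a fixed significant-digit rule so re-running an identical manifest
#' reproduces identical bytes.
#'
#' @param table A `sweep_table` (or blending data frame).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_sweep_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.8g", col))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A JSON-serialisable record sufficient to reproduce a run exactly: model
#' id, parameter values, protocol, solver settings and the configurable
#' conventions (pulse-interval semantics, horizon-extension policy).
#'
#' @param model A `motif_model` or `creb_model`.
#' @param protocol A [stimulus_protocol] or `NULL`.
#' @param t_end,dt Solver settings.
#' @param ... Further settings to record (budget, n_grid, scenario, ...).
#' @return A list; write with [write_manifest()].
#' @export
run_manifest <- function(model, protocol = NULL, t_end = 3000, dt = 0.05,
                         ...) {
  list(tool = "motifsynergy",
       version = as.character(utils::packageVersion("motifsynergy")),
       model = if (inherits(model, "motif_model")) model$motif else "creb",
       variant = if (inherits(model, "motif_model")) model$variant else NA,
       parameters = as.list(model$params),
       overrides = if (inherits(model, "motif_model")) model$overrides else NULL,
       protocol = if (is.null(protocol)) NULL else unclass(protocol),
       dt = dt, t_end = t_end,
       horizon_extension = list(enabled = TRUE, t_cap = 24000,
                                interior_fraction = 0.95),
       ...)
}

#' @rdname run_manifest
#' @param manifest A manifest list.
#' @param path Output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Regenerate the package's regression fixtures
#'
#' Deterministically rebuilds the small reference bundle shipped under
#' `inst/extdata/`: a coarsely sampled canonical time course, the blending
#' curves of the (k_dA, k_dB) pair at S = 1, and a degree table for three
#' focal pairs.  Re-running produces byte-identical files.
#'
#' @param dir Output directory (default: a `fixtures` subdirectory of the
#'   working directory).
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- motif_model("canonical_m")
  protocol <- square_pulse(1)
  f1 <- file.path(dir, "canonical_m_s1_timecourse.csv")
  tc <- integrate_rk4(model, protocol, t_end = 600)
  write_time_course(tc, f1, every = 200L)  # every 10 min

  resp <- .memoize_resp(make_response_fn(model, protocol))
  bc <- blending(model, protocol, c("k_dA", "k_dB"), resp = resp)
  f2 <- file.path(dir, "canonical_m_s1_kdA_kdB_blending.csv")
  write_sweep_table(as.data.frame(bc), f2)

  tab <- sweep_all_pairs(model, protocol,
                         pairs = c("k_dA/k_dB", "k_ST/k_dA", "K_T/k_dA"))
  f3 <- file.path(dir, "canonical_m_s1_focal_degrees.csv")
  write_sweep_table(tab, f3)
  invisible(c(f1, f2, f3))
}
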