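#' Write a trace or sweep table to CSV
#'
#' @param x A `pacing_result`, `region_sweep` or plain data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  df <- if (inherits(x, "pacing_result")) x$trace
        else tibble::as_tibble(x)
  readr::write_csv(df, path)
  invisible(path)
}

#' Export a 2D field snapshot as legacy VTK structured points
#'
#' Writes per-node scalar fields of a tissue grid (e.g. `V`, `Ca_i`, `SL`)
#' in ASCII legacy VTK for visualisation.
#'
#' @param grid A `tissue_grid` with states attached.
#' @param path Output file.
#' @param fields State columns to export.
#' @return The path, invisibly.
#' @export
write_vtk_snapshot <- function(grid, path, fields = c("V", "Ca_i", "SL")) {
  if (is.null(grid$states)) stop("grid has no states to export")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "atriamech tissue snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g 1", grid$dx, grid$dx),
               sprintf("POINT_DATA %d", grid$nx * grid$ny)), con)
  for (f in fields) {
    writeLines(c(sprintf("SCALARS %s double 1", f),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(grid$states[, f], digits = 9), con)
  }
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Key-value record (seed, package version, R version, configuration hash)
#' sufficient to reproduce a deterministic run byte-identically.
#'
#' @param config A named list describing the run configuration.
#' @param seed The RNG seed used (if any).
#' @return A named list of class `run_manifest`.
#' @export
run_manifest <- function(config = list(), seed = NA) {
  cfg_chr <- paste(deparse(config[order(names(config))]), collapse = "")
  structure(list(
    package = "atriamech",
    version = as.character(utils::packageVersion("atriamech")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_chr) *
                                        seq_along(utf8ToInt(cfg_chr)) %%
                                        2147483647)),
    timestamp = format(Sys.time(), tz = "UTC")),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$package, x$version, "seed:", x$seed,
      "hash:", x$config_hash, "\n")
  invisible(x)
}
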