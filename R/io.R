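# CSV/JSON readers and writers. Doubles are serialised with %.17g so
# every writer/reader pair round-trips at full precision.

fmt_full <- function(x) {
  if (is.double(x)) vapply(x, function(v) sprintf("%.17g", v),
                           character(1)) else x
}

write_csv_full <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write an experiment dataset as CSV
#'
#' Columns `eeg`, `ees`; full float precision. A sidecar JSON with the
#' dataset metadata (temperature, provenance, generator parameters) is
#' written next to it when `sidecar = TRUE`.
#'
#' @param dataset An [experiment_dataset()].
#' @param path Output CSV path.
#' @param sidecar Write `<path>.meta.json` with the metadata?
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, sidecar = TRUE) {
  stopifnot(inherits(dataset, "experiment_dataset"))
  write_csv_full(dataset[c("eeg", "ees")], path)
  if (sidecar) {
    meta <- list(temperature = attr(dataset, "temperature"),
                 label = attr(dataset, "label"),
                 provenance = attr(dataset, "provenance"),
                 generator = attr(dataset, "generator"))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read an experiment dataset from CSV
#'
#' Expects columns `eeg`, `ees`. If a `<path>.meta.json` sidecar exists it
#' supplies the metadata; otherwise `temperature` must be given.
#'
#' @param path CSV path.
#' @param temperature Fallback temperature (kelvin) when no sidecar.
#' @return An [experiment_dataset()].
#' @export
read_dataset_csv <- function(path, temperature = NA_real_) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("eeg", "ees") %in% names(df)))
    stop("dataset CSV must have columns eeg, ees")
  meta_path <- paste0(path, ".meta.json")
  label <- ""; prov <- "measured"; gen <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    temperature <- meta$temperature %||% temperature
    label <- meta$label %||% ""
    prov <- meta$provenance %||% "measured"
    gen <- meta$generator
  }
  experiment_dataset(df$eeg, df$ees, temperature = temperature,
                     label = label, provenance = prov, generator = gen)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an isotherm scan as CSV
#'
#' Fixed column order `eeg, ees_mean, ees_abs_mean, ees_stderr,
#' energy_per_site, homochiral_fraction, n_samples, seed`, full float
#' precision.
#'
#' @param isotherm An `ising_isotherm` from [isotherm_scan()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(isotherm, path) {
  stopifnot(inherits(isotherm, "ising_isotherm"))
  cols <- c("eeg", "ees_mean", "ees_abs_mean", "ees_stderr",
            "energy_per_site", "homochiral_fraction", "n_samples", "seed")
  write_csv_full(as.data.frame(isotherm)[cols], path)
  invisible(path)
}

#' Read an isotherm CSV back into an `ising_isotherm`
#' @param path CSV path written by [write_isotherm_csv()].
#' @return An `ising_isotherm` data frame (without run attributes).
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("isotherm file not found: ", path)
  df <- utils::read.csv(path)
  structure(df, class = c("ising_isotherm", "data.frame"))
}

#' Write a lattice snapshot as a CSV grid of D/L labels
#' @param lattice A `chirality_lattice`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot_csv <- function(lattice, path) {
  utils::write.table(snapshot(lattice), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a D/L snapshot CSV back into a lattice
#' @param path CSV path written by [write_snapshot_csv()].
#' @return A `chirality_lattice`.
#' @export
read_snapshot_csv <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  grid <- as.matrix(utils::read.csv(path, header = FALSE,
                                    colClasses = "character"))
  dimnames(grid) <- NULL
  grid_to_lattice(grid)
}

#' Write an equilibrium estimate as JSON
#' @param estimate An `equilibrium_estimate`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimate_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "equilibrium_estimate"))
  x <- unclass(estimate)
  x$lattice <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
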