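#' Write / read a pairwise volume as plain text
#'
#' Volumes are stored as a gzip-free CSV of values with a JSON sidecar
#' (`<path>.json`) carrying the kind, grid spacing, and validity mask run
#' lengths, so that serialized results remain diff-able and portable.
#'
#' @param volume a `coherence_volume`
#' @param path CSV output path
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "coherence_volume"))
  utils::write.table(volume$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(kind = volume$kind,
               n_grid = nrow(volume$values),
               spacing = if (!is.null(volume$grid)) volume$grid$spacing else NULL,
               valid_rle = list(lengths = rle(as.vector(volume$valid))$lengths,
                                values = rle(as.vector(volume$valid))$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_volume
#' @param grid optional `source_grid` to attach on read
#' @export
read_volume <- function(path, grid = NULL) {
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  valid <- matrix(inverse.rle(structure(list(
    lengths = meta$valid_rle$lengths,
    values = as.logical(meta$valid_rle$values)), class = "rle")),
    nrow(vals), ncol(vals))
  structure(list(values = vals, valid = valid, grid = grid,
                 kind = meta$kind),
            class = "coherence_volume")
}

#' Read a simulation/sweep configuration from YAML or JSON
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`)
#' @return named list of configuration values
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Write detection records or FROC tables
#'
#' Data frames go to CSV; nested reports (connections, assemblies) to JSON.
#'
#' @param x data frame or list
#' @param path output path (`.csv` or `.json`)
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(x, path, row.names = FALSE)
  }
  invisible(path)
}
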