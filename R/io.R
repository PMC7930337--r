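GENOTYPE_SCHEMA <- 1L

#' Write a genotype to JSON
#'
#' Genotypes are stored with explicit slot names (not bare vectors) so that
#' layout changes are detectable, plus a schema version field.
#'
#' @param g a [genotype()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype <- function(g, path) {
  if (!inherits(g, "wcpg_genotype")) g <- genotype(g)
  jsonlite::write_json(
    list(schema_version = GENOTYPE_SCHEMA,
         values = as.list(unclass(g))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a genotype from JSON
#'
#' Validates the schema version and the slot names against
#' [genotype_layout()] (order in the file does not matter).
#'
#' @param path a JSON file written by [write_genotype()].
#' @return a [genotype()].
#' @export
read_genotype <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != GENOTYPE_SCHEMA)
    stop("unsupported genotype schema version in ", path)
  slots <- genotype_layout()$slot
  vals <- unlist(obj$values)
  if (!setequal(names(vals), slots))
    stop("genotype file slots do not match the layout")
  genotype(vals[slots])
}

#' Export a trace to CSV
#'
#' Long-format neural outputs (time, unit, class, S) and, for embodied
#' traces, a separate midline file (time, rod, x, y).
#'
#' @param trace a `wcpg_trace`.
#' @param path output CSV for the neural outputs.
#' @param midline_path optional output CSV for midline coordinates.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, midline_path = NULL) {
  nt <- length(trace$time)
  df <- data.frame(
    time = rep(trace$time, times = ncol(trace$S)),
    unit = rep(trace$unit, each = nt),
    class = rep(trace$class, each = nt),
    S = as.vector(trace$S))
  write.csv(df, path, row.names = FALSE)
  if (!is.null(midline_path) && !is.null(trace$x)) {
    dm <- data.frame(
      time = rep(trace$time, times = ncol(trace$x)),
      rod = rep(seq_len(ncol(trace$x)), each = nt),
      x = as.vector(trace$x), y = as.vector(trace$y))
    write.csv(dm, midline_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-derive a result directory bit-identically:
#' the configuration snapshot, seeds, package version, timestamp and an
#' inventory of output files with checksums.
#'
#' @param dir run directory.
#' @param config the [wcpg_config()] used.
#' @param seed the seed(s) used.
#' @param note optional free-text description.
#' @return the manifest path, invisibly.
#' @export
run_manifest <- function(dir, config, seed, note = NULL) {
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  inv <- lapply(files, function(f)
    list(file = f,
         md5 = unname(tools::md5sum(file.path(dir, f))),
         bytes = file.info(file.path(dir, f))$size))
  manifest <- list(
    package = "wormCPG",
    version = as.character(utils::packageVersion("wormCPG")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed, note = note, config = unclass(config), files = inv)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
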