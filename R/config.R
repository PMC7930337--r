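.wcpg_env <- new.env(parent = emptyenv())

#' Model configuration
#'
#' Loads the packaged configuration file (parameter ranges, integration steps,
#' fitness constants, GA settings, body and muscle constants). The file, not
#' the code, is the single source of truth for every numerical constant of the
#' model. Physical units throughout are mm, s and kg, so forces are in
#' kg*mm/s^2.
#'
#' @param path path to a configuration JSON; `NULL` uses the packaged default.
#' @param overrides named list merged recursively over the loaded
#'   configuration, e.g. `list(simulation = list(duration = 20))`.
#' @return a `wcpg_config` list with components `ranges`, `simulation`,
#'   `fitness`, `ga`, `body` and `muscle`.
#' @export
#' @examples
#' cfg <- wcpg_config()
#' cfg$fitness$freq_target # target bending frequency, Hz
wcpg_config <- function(path = NULL, overrides = NULL) {
  if (is.null(path)) {
    if (is.null(.wcpg_env$default_config)) {
      p <- system.file("extdata", "wormcpg_config.json", package = "wormCPG",
                       mustWork = TRUE)
      .wcpg_env$default_config <- jsonlite::read_json(p, simplifyVector = TRUE)
    }
    cfg <- .wcpg_env$default_config
  } else {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  required <- c("ranges", "simulation", "fitness", "ga", "body", "muscle")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("configuration is missing section(s): ", paste(missing, collapse = ", "))
  class(cfg) <- c("wcpg_config", "list")
  cfg
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else
      base[[nm]] <- over[[nm]]
  }
  base
}

#' Write a configuration to JSON
#'
#' Round-trips losslessly through [wcpg_config()].
#'
#' @param config a `wcpg_config` list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.wcpg_config <- function(x, ...) {
  cat("wormCPG configuration\n")
  cat(sprintf("  body: %d segments, %.2f mm, drag C_par/C_perp = %.4g/%.4g kg/s\n",
              x$body$n_seg, x$body$length, x$body$drag_par, x$body$drag_perp))
  cat(sprintf("  integration: neural dt %.2g ms, body dt %.2g ms\n",
              x$simulation$dt_neural * 1000, x$simulation$dt_body * 1000))
  cat(sprintf("  targets: %.2f Hz bending, %.2f mm/s velocity\n",
              x$fitness$freq_target, x$fitness$vel_target))
  invisible(x)
}
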