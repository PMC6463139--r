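#' Read a circuit + parameter configuration from YAML or JSON
#'
#' The file holds two top-level sections: \code{circuit} (fields of
#' [circuitConfig()]) and \code{parameters} (fields of
#' [oscillatorParameters()]); both sections and all fields are optional
#' (defaults fill the gaps), but unknown keys anywhere are rejected.
#' Field names match the provenance table ([parameterProvenance()])
#' exactly.
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return list with \code{config} (a \code{dualosc_config}) and
#'   \code{params} (a \code{dualosc_params}).
#' @export
#' @examples
#' cfg <- readModelConfig(system.file("extdata", "example_config.yaml",
#'                                    package = "dualosc"))
#' cfg$config$reporter_kind
readModelConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("config must be .yaml/.yml or .json", call. = FALSE))
  if (!is.list(raw)) stop("config must be a mapping", call. = FALSE)
  unknown_top <- setdiff(names(raw), c("circuit", "parameters"))
  if (length(unknown_top)) {
    stop("unknown top-level config section(s): ",
         paste(unknown_top, collapse = ", "), call. = FALSE)
  }
  circ <- raw$circuit %||% list()
  circ_fields <- c("reporter_kind", "retroactivity_on", "protease_sharing_on",
                   "n_activator_dna", "n_repressor_dna")
  unknown <- setdiff(names(circ), circ_fields)
  if (length(unknown)) {
    stop("unknown circuit field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  config <- do.call(circuitConfig, circ)
  params <- do.call(oscillatorParameters, raw$parameters %||% list())
  list(config = config, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the current configuration to a YAML file
#'
#' @param config a [circuitConfig()].
#' @param params an [oscillatorParameters()] set.
#' @param path output path (.yaml).
#' @return the path, invisibly.
#' @export
writeModelConfig <- function(config, params, path) {
  stopifnot(inherits(config, "dualosc_config"),
            inherits(params, "dualosc_params"))
  yaml::write_yaml(list(circuit = unclass(config),
                        parameters = lapply(unclass(params), as.numeric)),
                   path)
  invisible(path)
}
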