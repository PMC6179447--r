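#' Write a run manifest
#'
#' Records everything needed to replay a pipeline stage: package version,
#' stage name, all parameters, seeds, and MD5 checksums of the input files.
#' The command-line tool writes one next to every output set; a run is
#' reproducible from its manifest alone.
#'
#' @param path output JSON path.
#' @param stage stage name (e.g. `"run"`, `"ldp"`).
#' @param params named list of parameters (must be JSON-representable).
#' @param inputs character vector of input file paths to checksum.
#' @param seed the top-level seed, if any.
#' @return `path`, invisibly.
#' @export
writeRunManifest <- function(path, stage, params = list(),
                             inputs = character(0), seed = NULL) {
  man <- list(
    tool = "catracer",
    version = as.character(utils::packageVersion("catracer")),
    stage = stage,
    seed = seed,
    parameters = params,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
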