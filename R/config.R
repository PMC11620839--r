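# Run configuration serialization: one JSON file holding the model
# parameters and the synthetic-data configuration, round-tripping
# losslessly (parse -> serialize -> parse).

#' @noRd
.slotList <- function(object) {
  nm <- methods::slotNames(class(object))
  setNames(lapply(nm, function(s) slot(object, s)), nm)
}

#' Write a run configuration as JSON
#'
#' Serializes an [InterferenceParams-class] and a
#' [SyntheticConfig-class] into one JSON file that
#' [readRunConfig()] parses back losslessly.
#'
#' @param params an [InterferenceParams-class].
#' @param config a [SyntheticConfig-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' writeRunConfig(interferenceParams(), syntheticConfig(), path)
#' cfg <- readRunConfig(path)
#' @export
writeRunConfig <- function(params, config, path) {
  stopifnot(is(params, "InterferenceParams"), is(config, "SyntheticConfig"))
  payload <- list(
    package = "phageHoming",
    version = as.character(utils::packageVersion("phageHoming")),
    interference = .slotList(params),
    synthetic = .slotList(config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
    dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a run configuration written by [writeRunConfig()]
#'
#' @param path JSON file path.
#' @return list with validated elements \code{params}
#'   ([InterferenceParams-class]) and \code{config}
#'   ([SyntheticConfig-class]).
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert(!is.null(raw$interference) && !is.null(raw$synthetic),
    "not a phageHoming run configuration")
  p <- raw$interference
  params <- interferenceParams(moiA = p$moiA, moiB = p$moiB, h = p$h,
    k = p$k, mu = p$mu, rMax = p$rMax, identity = p$identity,
    identityThreshold = p$identityThreshold,
    compartmentalized = p$compartmentalized, nCells = p$nCells,
    generations = p$generations, seed = p$seed)
  s <- raw$synthetic
  config <- syntheticConfig(seed = s$seed, nReplicates = s$nReplicates,
    titerLog10Sd = s$titerLog10Sd, pCoimport = s$pCoimport,
    nNuclei = s$nNuclei, capsidMeanControl = s$capsidMeanControl,
    capsidMeanTreated = s$capsidMeanTreated,
    capsidDispersion = s$capsidDispersion,
    escaperSiteProbs = as.data.frame(s$escaperSiteProbs),
    genomeIdentity = s$genomeIdentity,
    intronLength = s$intronLength)
  list(params = params, config = config)
}

#' Write count data as CSV
#'
#' Writes per-tomogram capsid counts or import-classification counts
#' with a seed-bearing comment header.
#'
#' @param counts named or unnamed numeric/integer vector.
#' @param path output file path.
#' @param seed optional seed recorded in the header.
#' @param valueName column name for the counts.
#' @return \code{path}, invisibly.
#' @export
writeCountsCsv <- function(counts, path, seed = NULL,
                           valueName = "count") {
  df <- data.frame(
    id = if (is.null(names(counts))) seq_along(counts) else names(counts),
    value = unname(counts))
  names(df)[2L] <- valueName
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
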