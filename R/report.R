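# Report assembly and run manifests for the command-line drivers.

#' Write an outcome or incremental summary to JSON
#'
#' @param x An `outcome_summary`, `incremental_result`, or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  x$ledger <- NULL
  x$conventions <- NULL
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Run manifest for a command invocation
#'
#' Records everything needed to re-run a command to bit-identical outputs:
#' the command, config path, seed, timestamp, package version and the full
#' list of output files, plus the convention switches in force.
#'
#' @param command Command name.
#' @param config Config path or `"builtin"`.
#' @param seed Seed used (NA for deterministic commands).
#' @param outputs Character vector of output file paths.
#' @param conventions A [model_conventions()] object.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(command, config, seed, outputs,
                         conventions = model_conventions()) {
  structure(list(
    command = command, config = config, seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("osimcea")),
    conventions = unclass(conventions),
    outputs = outputs), class = "run_manifest")
}

#' Write a run manifest to JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Base-case report: per-arm totals and incremental columns
#'
#' Display-rounded companion of [base_case_table()]: dollars to integers,
#' LYs/QALYs to 2 decimals, mirroring the published table layout; the
#' unrounded table is attached as attribute `raw`.
#'
#' @param bundle A `cea_bundle`.
#' @param countries Country labels; default all.
#' @return A `data.frame` with display rounding.
#' @export
base_case_report <- function(bundle, countries = names(bundle$countries)) {
  raw <- base_case_table(bundle, countries)
  out <- raw
  for (col in c("total_cost", "icer_per_ly", "icer_per_qaly"))
    out[[col]] <- round(out[[col]])
  for (col in c("total_ly", "total_qaly", "inhb"))
    out[[col]] <- round(out[[col]], 2)
  attr(out, "raw") <- raw
  out
}
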