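#' Assemble a structured analysis report
#'
#' Collects the outputs of the pipeline stages into a single
#' JSON-serializable report with one section per figure-level analysis
#' (nuclei arrangement, responder rates, fold changes, AChR clusters,
#' sarcomere spacing, statistical tests) plus provenance (package version,
#' R version, seed, configuration). Only the supplied stages appear. All
#' masks contributing to one report must share a pixel size: stage entries
#' or `config` elements named `pixel_size` are cross-checked and a
#' conflict is an error.
#'
#' @param nuclei,calcium,achr,sarcomere,qpcr,tests optional stage outputs
#'   (lists or data.frames; e.g. a [summarize_field()] result, a
#'   [population_response_rates()] table, a [fold_change()] table, test
#'   results).
#' @param config named list recorded verbatim in the provenance block.
#' @param seed seed recorded in the provenance block.
#' @return List of class `myoquant_report` with elements `provenance` and
#'   one section per supplied stage. Errors when no stage is supplied.
#' @export
build_report <- function(nuclei = NULL, calcium = NULL, achr = NULL,
                         sarcomere = NULL, qpcr = NULL, tests = NULL,
                         config = list(), seed = NULL) {
  stages <- list(nuclei = nuclei, calcium = calcium, achr = achr,
                 sarcomere = sarcomere, qpcr = qpcr, tests = tests)
  stages <- stages[!vapply(stages, is.null, logical(1))]
  if (length(stages) == 0L) stop("at least one stage output is required")
  ps <- unlist(lapply(c(stages, list(config = config)), function(s)
    if (is.list(s) && is.numeric(s$pixel_size)) s$pixel_size else NULL))
  if (length(ps) > 1L && length(unique(round(ps, 12))) > 1L)
    stop(sprintf("conflicting pixel sizes across inputs: %s",
                 paste(unique(ps), collapse = ", ")))
  strip <- function(x) {
    if (inherits(x, "myoquant_test"))
      return(list(method = x$method, statistic = as.list(x$statistic),
                  p_value = x$p.value, n = x$n, stars = x$stars))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    if (inherits(x, "table")) return(as.list(x))
    x
  }
  structure(c(list(provenance = list(
                package = "myoquant",
                version = as.character(utils::packageVersion("myoquant")),
                r_version = R.version.string,
                seed = seed, config = config)),
              lapply(stages, strip)),
            class = "myoquant_report")
}

#' Write a report (or any result list) as JSON
#'
#' @param report a [build_report()] result or any serializable list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       null = "null")
  invisible(path)
}
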