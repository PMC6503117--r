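# Result serialization and run configuration.

.fmt <- function(x) {
  ifelse(is.na(x), "", sprintf("%.6g", x + 0))  # `+ 0` normalizes -0
}

#' Write simulation or design results to disk
#'
#' Output is bit-stable for fixed inputs: keys sorted, floats formatted
#' `%.6g`. An [MDVSet] becomes rows `emu,m0..mk,fl`; a design-ranking
#' data.frame is written as-is (TSV when `format = "csv"` would lose the
#' ordering semantics it keeps its column layout).
#'
#' @param results an [MDVSet], a data.frame (e.g. from [rankDesigns()]),
#'   or a flux-ratio estimate list from [estimateFluxRatio()]
#' @param path output file path
#' @param format `"csv"` or `"json"`
#' @return `path`, invisibly
#' @export
writeResults <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if ((is(results, "MDVSet") && length(results) == 0) ||
      (is.data.frame(results) && nrow(results) == 0) ||
      (is.list(results) && !is.data.frame(results) &&
       !is(results, "MDVSet") && length(results) == 0))
    stop("no results to write", call. = FALSE)
  if (format == "json") {
    obj <- if (is(results, "MDVSet")) {
      nm <- sort(names(results))
      setNames(lapply(nm, function(n) list(
        mdv = as.numeric(results[[n]]),
        fl = fractionalLabeling(results[[n]]))), nm)
    } else results
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = 6, pretty = TRUE)),
               path)
    return(invisible(path))
  }
  if (is(results, "MDVSet")) {
    tab <- mdvTable(results)
    tab <- tab[order(tab$emu), ]
    num <- vapply(tab[-1], is.numeric, TRUE)
    tab[-1][num] <- lapply(tab[-1][num], .fmt)
    write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else if (is.data.frame(results)) {
    tab <- results
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], .fmt)
    utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    stop("unsupported result type for csv output", call. = FALSE)
  }
  invisible(path)
}

#' Load a YAML run configuration
#'
#' Mirror of the command-line flags: fields `model`, `tracers`, `targets`,
#' `n_samples`, `seed`, `output`, `log_level` (all optional except
#' `model`).
#'
#' @param path YAML file path
#' @return validated named list
#' @export
loadRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read run configurations",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model))
    stop("run configuration must name a model file", call. = FALSE)
  if (!file.exists(cfg$model))
    stop("model file not found: ", cfg$model, call. = FALSE)
  if (!is.null(cfg$seed)) {
    cfg$seed <- as.integer(cfg$seed)
    if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  }
  cfg
}
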