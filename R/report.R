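#' Write an analysis result to JSON
#'
#' Serializes fit/comparison structures with a schema version and
#' provenance block (package version, seed, configuration hash).
#' Non-finite numbers (e.g. a degenerate fit's infinite CI bound)
#' cannot be represented in JSON; they are serialized as `null` and
#' the report gains a top-level `warning_nonfinite = true` flag.
#'
#' @param results a `gamma_fit`, `shift_report`, or any
#'   list/data.frame structure of plain values.
#' @param path output path.
#' @param seed seed recorded in the provenance block (or `NA`).
#' @param config configuration list hashed into the provenance block.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(results, path, seed = NA, config = NULL) {
  payload <- strip_class(results)
  flag <- FALSE
  payload <- rapply(payload, function(x) {
    if (is.numeric(x) && any(!is.finite(x) & !is.na(x))) {
      flag <<- TRUE
      x[!is.finite(x) & !is.na(x)] <- NA
    }
    x
  }, classes = "ANY", how = "replace")
  if (flag) warning("non-finite value(s) serialized as null")
  doc <- list(schema_version = "1.0",
              package = "micromov",
              package_version = as.character(utils::packageVersion("micromov")),
              seed = seed,
              config_hash = config_hash(config),
              warning_nonfinite = flag,
              results = payload)
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e)
                    stop("cannot write to ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  close(con)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "columns")
  invisible(path)
}

#' Read a JSON report written by [write_report_json()]
#'
#' @param path path to the JSON file.
#' @return The parsed document (a list).
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# recursively drop S3 classes so jsonlite serializes plain lists
strip_class <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_class)
  } else x
}

# deterministic md5 of a configuration list (via its canonical JSON)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(strip_class(config), tmp, auto_unbox = TRUE,
                       digits = NA, na = "null")
  unname(tools::md5sum(tmp))
}
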