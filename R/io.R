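# Tabular input and model persistence.

#' Construct an array experiment
#'
#' Pairs glycan structures with their spot RFUs. Duplicate structures are
#' allowed (distinct spots).
#'
#' @param table Data frame with at least `glycan_text` and `rfu` columns
#'   (extra columns preserved).
#' @param glycans Optional list of pre-parsed `glycan_tree` objects, one per
#'   row.
#' @return An object of class `array_experiment`.
#' @export
array_experiment <- function(table, glycans = NULL) {
  stopifnot(is.data.frame(table), all(c("glycan_text", "rfu") %in% names(table)))
  if (is.null(glycans)) glycans <- lapply(table$glycan_text, parse_cfg_glycan)
  stopifnot(length(glycans) == nrow(table))
  structure(list(table = table, glycans = glycans), class = "array_experiment")
}

#' @export
print.array_experiment <- function(x, ...) {
  cat(sprintf("<array_experiment: %d spots, RFU range [%g, %g]>\n",
              nrow(x$table), min(x$table$rfu), max(x$table$rfu)))
  invisible(x)
}

#' Number of spots in an array experiment
#' @param x An `array_experiment`.
#' @export
length.array_experiment <- function(x) nrow(x$table)

ae_subset <- function(ae, idx) {
  array_experiment(ae$table[idx, , drop = FALSE], ae$glycans[idx])
}

#' Read a glycan microarray table
#'
#' Reads a delimited text file with a header containing at least columns
#' `glycan_text` and `rfu`, parses the glycan strings, and returns an
#' [array_experiment()].
#'
#' @param path File path or connection. Delimiter is inferred from the file
#'   extension (`.tsv`/`.txt` tab, otherwise comma) unless `sep` is given.
#' @param sep Optional field delimiter.
#' @param on_parse_error `"error"` (default) aborts listing the offending row
#'   numbers; `"skip"` drops those rows with a warning.
#' @return An `array_experiment`.
#' @export
read_array_table <- function(path, sep = NULL, on_parse_error = c("error", "skip")) {
  on_parse_error <- match.arg(on_parse_error)
  if (is.null(sep)) {
    sep <- if (is.character(path) && grepl("\\.(tsv|txt)$", path)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("glycan_text", "rfu"), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("input table lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop("input table has no rows", call. = FALSE)
  rfu <- suppressWarnings(as.numeric(tab$rfu))
  bad_rfu <- which(is.na(rfu) | rfu < 0)
  if (length(bad_rfu)) {
    stop(sprintf("non-numeric or negative rfu in row(s): %s",
                 paste(bad_rfu, collapse = ", ")), call. = FALSE)
  }
  tab$rfu <- rfu
  parsed <- lapply(tab$glycan_text, function(s) {
    tryCatch(parse_cfg_glycan(s), glycan_parse_error = function(e) e)
  })
  bad <- which(vapply(parsed, inherits, logical(1), what = "condition"))
  if (length(bad)) {
    msg <- sprintf("unparseable glycan(s) in row(s): %s",
                   paste(bad, collapse = ", "))
    if (on_parse_error == "error") stop(msg, call. = FALSE)
    warning(paste(msg, "- skipped"))
    tab <- tab[-bad, , drop = FALSE]
    parsed <- parsed[-bad]
  }
  array_experiment(tab, parsed)
}

.model_format_version <- "1"

#' Serialise a trained model to JSON text
#'
#' The serialisation is lossless: motif codes and texts, coefficients,
#' intercept, the frozen capability map, configuration and seeds all round
#' trip, so a deserialised model gives identical predictions.
#'
#' @param model A `trained_model`.
#' @return A JSON string.
#' @export
serialise_model <- function(model) {
  stopifnot(inherits(model, "trained_model"))
  payload <- list(
    format_version = .model_format_version,
    motifs = model$motifs,
    intercept = model$intercept,
    C = model$C,
    capability_map = lapply(unclass(model$capability_map), as.integer),
    config = model$config,
    seed = model$seed,
    selection = model$selection
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Deserialise a trained model from JSON text
#' @param text JSON produced by [serialise_model()].
#' @return A `trained_model`.
#' @export
deserialise_model <- function(text) {
  payload <- tryCatch(jsonlite::fromJSON(text),
                      error = function(e) stop("corrupted model payload: ",
                                               conditionMessage(e), call. = FALSE))
  if (is.null(payload$format_version) ||
      !identical(as.character(payload$format_version), .model_format_version)) {
    stop(sprintf("model format version mismatch (got %s, expected %s)",
                 payload$format_version, .model_format_version), call. = FALSE)
  }
  motifs <- as.data.frame(payload$motifs, stringsAsFactors = FALSE)
  if (nrow(motifs) == 0L) {
    motifs <- data.frame(code = character(0), parent_anomer = character(0),
                         text = character(0), coef = numeric(0))
  }
  cap <- lapply(payload$capability_map, as.integer)
  structure(
    list(motifs = motifs, coef = motifs$coef, intercept = payload$intercept,
         C = payload$C,
         capability_map = structure(cap, class = "capability_map"),
         config = payload$config, seed = payload$seed,
         selection = payload$selection),
    class = "trained_model"
  )
}
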