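#' Read a SampleTable from the three-file layout
#'
#' The abundance file is a delimited matrix with sample ids in the first
#' column and metabolite ids as header; the two metadata files are keyed by
#' those ids. Comma and tab delimiters are auto-detected; decimal point only.
#' Empty cells and \code{NA} are read as missing values (never zero).
#'
#' @param abundance_path,sample_meta_path,metabolite_meta_path file paths.
#' @return a validated \linkS4class{SampleTable} with
#'   \code{normalizedMode() == "raw"}.
#' @seealso [writeSampleTable()]
#' @export
readSampleTable <- function(abundance_path, sample_meta_path,
                            metabolite_meta_path) {
  ab_dt <- data.table::fread(abundance_path, na.strings = c("", "NA"))
  sm <- as.data.frame(data.table::fread(sample_meta_path,
                                        na.strings = c("", "NA")))
  mm <- as.data.frame(data.table::fread(metabolite_meta_path,
                                        na.strings = c("", "NA")))
  ## all-NA columns come back logical; pin the schema types
  for (col in c("sample_id", "animal_id", "tissue", "role"))
    if (col %in% names(sm)) sm[[col]] <- as.character(sm[[col]])
  for (col in c("dose_gy", "day", "tissue_weight_mg"))
    if (col %in% names(sm)) sm[[col]] <- as.numeric(sm[[col]])
  for (col in c("metabolite_id", "name", "chem_class", "acyl_chain",
                "is_channel"))
    if (col %in% names(mm)) mm[[col]] <- as.character(mm[[col]])
  ids <- as.character(ab_dt[[1]])
  ab <- as.matrix(ab_dt[, -1, drop = FALSE])
  storage.mode(ab) <- "double"
  rownames(ab) <- ids
  if (any(!is.na(ab) & ab < 0)) {
    bad <- which(!is.na(ab) & ab < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample %s, metabolite %s",
                 rownames(ab)[bad[1]], colnames(ab)[bad[2]]))
  }
  SampleTable(ab, sm, mm, normalized = "raw")
}

#' Write a SampleTable to the three-file layout
#'
#' Writes \code{abundances.csv}, \code{samples.csv} and
#' \code{metabolites.csv} under \code{dir}; numerics round-trip at full
#' precision so that \code{readSampleTable} reproduces the table exactly.
#'
#' @param table a \linkS4class{SampleTable}.
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeSampleTable <- function(table, dir) {
  stopifnot(is(table, "SampleTable"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("abundances.csv", "samples.csv",
                            "metabolites.csv"))
  ab <- data.table::data.table(sample_id = rownames(table@abundances))
  ab <- cbind(ab, data.table::as.data.table(table@abundances))
  data.table::fwrite(.fp_frame(ab), paths[1], na = "NA")
  data.table::fwrite(.fp_frame(table@samples), paths[2], na = "NA")
  data.table::fwrite(table@metabolites, paths[3], na = "NA")
  invisible(paths)
}

#' Export a result object to CSV or JSON
#'
#' CSV holds the object's main per-row table at full numeric precision; JSON
#' is a schema-stable dump of all components (for a
#' \linkS4class{TriageResult}, including the confusion matrix and per-class
#' accuracies).
#'
#' @param object a \linkS4class{DiffResult}, \linkS4class{MarkerPanel},
#'   \linkS4class{TriageResult}, \linkS4class{RatioResult},
#'   \linkS4class{QCReport} or \linkS4class{TrajectoryTable}.
#' @param path output file path.
#' @param format "csv" or "json".
#' @return invisibly, \code{path}.
#' @export
setGeneric("exportResults", function(object, path, format = c("csv", "json"))
  standardGeneric("exportResults"))

## render numeric columns at 17 significant digits so that CSV output
## round-trips doubles exactly
.fp_frame <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  }
  df
}

.export_parts <- function(parts, path, format) {
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    data.table::fwrite(.fp_frame(parts$csv), path, na = "NA")
  } else {
    jsonlite::write_json(parts$json, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname exportResults
#' @export
setMethod("exportResults", "DiffResult", function(object, path, format) {
  .export_parts(list(
    csv = object@table,
    json = list(contrast = object@contrast, test = object@test,
                alpha = object@alpha, fdr_max = object@fdr_max,
                table = object@table)), path, format)
})

#' @rdname exportResults
#' @export
setMethod("exportResults", "MarkerPanel", function(object, path, format) {
  .export_parts(list(
    csv = object@table,
    json = list(stage = object@stage, k = object@k, table = object@table)),
    path, format)
})

#' @rdname exportResults
#' @export
setMethod("exportResults", "TriageResult", function(object, path, format) {
  cm <- object@confusion
  .export_parts(list(
    csv = object@predictions,
    json = list(day = object@day, cv_scheme = object@cv_scheme,
                confusion = list(classes = rownames(cm),
                                 matrix = unname(apply(cm, 1, as.list))),
                per_class_accuracy = as.list(object@per_class_accuracy),
                predictions = object@predictions)), path, format)
})

#' @rdname exportResults
#' @export
setMethod("exportResults", "RatioResult", function(object, path, format) {
  .export_parts(list(
    csv = object@per_sample,
    json = list(per_sample = object@per_sample,
                group_stats = object@group_stats,
                kw_p = as.list(object@kw_p), pairwise = object@pairwise,
                notes = object@notes)), path, format)
})

#' @rdname exportResults
#' @export
setMethod("exportResults", "QCReport", function(object, path, format) {
  rsd <- data.frame(metabolite_id = names(object@rsd_per_metabolite),
                    rsd = unname(object@rsd_per_metabolite))
  .export_parts(list(
    csv = rsd,
    json = list(n_metabolites_in = object@n_metabolites_in,
                n_removed_missing = object@n_removed_missing,
                n_removed_rsd = object@n_removed_rsd,
                rsd_per_metabolite = as.list(object@rsd_per_metabolite),
                frac_rsd_lt = as.list(object@frac_rsd_lt),
                qc_within_2sd = as.list(object@qc_within_2sd),
                notes = object@notes)), path, format)
})

#' @rdname exportResults
#' @export
setMethod("exportResults", "TrajectoryTable", function(object, path, format) {
  .export_parts(list(
    csv = object@ratios,
    json = list(ratios = object@ratios, summary = object@summary)),
    path, format)
})

#' Read back an exported CSV result table
#'
#' Convenience reader for files written by [exportResults()] with
#' \code{format = "csv"}; full-precision numerics round-trip exactly.
#'
#' @param path CSV path.
#' @return a data.frame.
#' @export
readResultsCSV <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
}
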