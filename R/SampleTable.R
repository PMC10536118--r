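#' Construct a SampleTable
#'
#' Builds and content-validates the central sample-by-metabolite container.
#' Metadata rows are reordered to match the matrix dimnames. Construction
#' fails on any validation issue of severity "error"; see [validateTable()]
#' for the full rule set.
#'
#' @param abundances numeric matrix (samples x metabolites) with rownames =
#'   sample ids and colnames = metabolite ids. \code{NA} encodes a missing
#'   measurement; zero is a measured intensity.
#' @param samples data.frame of sample annotation (see
#'   \linkS4class{SampleTable}).
#' @param metabolites data.frame of metabolite annotation.
#' @param normalized normalization state of the matrix.
#' @return a validated \linkS4class{SampleTable}.
#' @examples
#' ab <- matrix(c(1, 2, 3, 4), 2, 2,
#'              dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' st <- SampleTable(ab,
#'   samples = data.frame(sample_id = c("s1", "s2"), animal_id = c("a1", "a2"),
#'                        tissue = "plasma", dose_gy = c(0, 10), day = 1,
#'                        role = "study", tissue_weight_mg = NA_real_),
#'   metabolites = data.frame(metabolite_id = c("m1", "m2"),
#'                            name = c("m1", "m2"), chem_class = "other",
#'                            acyl_chain = NA_character_,
#'                            is_channel = NA_character_))
#' nSamples(st)
#' @export
SampleTable <- function(abundances, samples, metabolites,
                        normalized = "raw") {
  stopifnot(is.matrix(abundances))
  storage.mode(abundances) <- "double"
  samples <- as.data.frame(samples)
  metabolites <- as.data.frame(metabolites)
  if (!"tissue_weight_mg" %in% names(samples))
    samples$tissue_weight_mg <- NA_real_
  if (!"acyl_chain" %in% names(metabolites))
    metabolites$acyl_chain <- NA_character_
  if (!"is_channel" %in% names(metabolites))
    metabolites$is_channel <- NA_character_
  if (!"name" %in% names(metabolites))
    metabolites$name <- metabolites$metabolite_id
  samples$sample_id <- as.character(samples$sample_id)
  metabolites$metabolite_id <- as.character(metabolites$metabolite_id)
  ## orphan checks before reordering
  orphan_s <- setdiff(rownames(abundances), samples$sample_id)
  orphan_m <- setdiff(colnames(abundances), metabolites$metabolite_id)
  if (length(orphan_s))
    stop("sample ids absent from sample metadata: ",
         paste(orphan_s, collapse = ", "))
  if (length(orphan_m))
    stop("metabolite ids absent from metabolite metadata: ",
         paste(orphan_m, collapse = ", "))
  extra_s <- setdiff(samples$sample_id, rownames(abundances))
  extra_m <- setdiff(metabolites$metabolite_id, colnames(abundances))
  if (length(extra_s))
    stop("sample metadata ids absent from abundance matrix: ",
         paste(extra_s, collapse = ", "))
  if (length(extra_m))
    stop("metabolite metadata ids absent from abundance matrix: ",
         paste(extra_m, collapse = ", "))
  samples <- samples[match(rownames(abundances), samples$sample_id), ,
                     drop = FALSE]
  metabolites <- metabolites[match(colnames(abundances),
                                   metabolites$metabolite_id), ,
                             drop = FALSE]
  rownames(samples) <- NULL
  rownames(metabolites) <- NULL
  obj <- new("SampleTable", abundances = abundances, samples = samples,
             metabolites = metabolites, normalized = normalized)
  rep <- validateTable(obj)
  if (!rep@ok) {
    err <- rep@issues[rep@issues$severity == "error", , drop = FALSE]
    stop("invalid SampleTable:\n", paste0("  - ", err$message, " [",
                                          err$location, "]",
                                          collapse = "\n"))
  }
  obj
}

#' @rdname SampleTable-accessors
#' @export
setGeneric("abundances", function(object) standardGeneric("abundances"))
#' @rdname SampleTable-accessors
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))
#' @rdname SampleTable-accessors
#' @export
setGeneric("metaboliteData",
           function(object) standardGeneric("metaboliteData"))
#' @rdname SampleTable-accessors
#' @export
setGeneric("normalizedMode",
           function(object) standardGeneric("normalizedMode"))
#' @rdname SampleTable-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname SampleTable-accessors
#' @export
setGeneric("nMetabolites", function(object) standardGeneric("nMetabolites"))

#' Accessors for SampleTable
#'
#' @param object a \linkS4class{SampleTable}.
#' @return \code{abundances}: the numeric matrix; \code{sampleData} /
#'   \code{metaboliteData}: annotation data.frames; \code{normalizedMode}:
#'   normalization state; \code{nSamples} / \code{nMetabolites}: dimensions.
#' @name SampleTable-accessors
#' @aliases abundances sampleData metaboliteData normalizedMode nSamples
#'   nMetabolites
NULL

#' @rdname SampleTable-accessors
#' @export
setMethod("abundances", "SampleTable", function(object) object@abundances)
#' @rdname SampleTable-accessors
#' @export
setMethod("sampleData", "SampleTable", function(object) object@samples)
#' @rdname SampleTable-accessors
#' @export
setMethod("metaboliteData", "SampleTable",
          function(object) object@metabolites)
#' @rdname SampleTable-accessors
#' @export
setMethod("normalizedMode", "SampleTable",
          function(object) object@normalized)
#' @rdname SampleTable-accessors
#' @export
setMethod("nSamples", "SampleTable", function(object) nrow(object@abundances))
#' @rdname SampleTable-accessors
#' @export
setMethod("nMetabolites", "SampleTable",
          function(object) ncol(object@abundances))

#' Subset a SampleTable
#'
#' \code{x[i, j]} subsets samples (rows) and metabolites (columns) with the
#' matching metadata; indices may be logical, integer or id characters.
#'
#' @param x a \linkS4class{SampleTable}.
#' @param i,j sample / metabolite indices.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "SampleTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@abundances))
  if (missing(j)) j <- seq_len(ncol(x@abundances))
  ab <- x@abundances[i, j, drop = FALSE]
  sm <- x@samples[match(rownames(ab), x@samples$sample_id), , drop = FALSE]
  mm <- x@metabolites[match(colnames(ab), x@metabolites$metabolite_id), ,
                      drop = FALSE]
  rownames(sm) <- NULL
  rownames(mm) <- NULL
  new("SampleTable", abundances = ab, samples = sm, metabolites = mm,
      normalized = x@normalized)
})

setMethod("show", "SampleTable", function(object) {
  sm <- object@samples
  cat("SampleTable:", nrow(object@abundances), "samples x",
      ncol(object@abundances), "metabolites (", object@normalized, ")\n")
  cat("  tissue:", paste(unique(sm$tissue), collapse = "/"),
      " study:", sum(sm$role == "study"), " qc:", sum(sm$role == "qc"), "\n")
  dg <- sort(unique(sm$dose_gy[sm$role == "study"]))
  dy <- sort(unique(sm$day[sm$role == "study"]))
  cat("  doses (Gy):", paste(dg, collapse = ", "),
      "  days:", paste(dy, collapse = ", "), "\n")
  miss <- mean(is.na(object@abundances))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
})

#' Validate a SampleTable's content invariants
#'
#' Pure check (the table is never modified): unique ids, metadata/matrix
#' agreement, nonnegative abundances (with cell coordinates on violation),
#' enum-valued tissue/role/normalization, tissue weights present on raw lung
#' study samples, acyl-chain annotation confined to the acylcarnitine family
#' (plus free carnitine/acetylcarnitine), and internal-standard references
#' resolving to IS columns while the table is raw.
#'
#' @param table a \linkS4class{SampleTable}.
#' @return a \linkS4class{ValidationReport}; \code{ok} is \code{TRUE} iff no
#'   issue of severity "error" was found.
#' @export
validateTable <- function(table) {
  stopifnot(is(table, "SampleTable"))
  issues <- list()
  add <- function(severity, message, location = "") {
    issues[[length(issues) + 1L]] <<-
      data.frame(severity = severity, message = message,
                 location = location, stringsAsFactors = FALSE)
  }
  ab <- table@abundances
  sm <- table@samples
  mm <- table@metabolites

  neg <- which(!is.na(ab) & ab < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    for (k in seq_len(min(nrow(neg), 20L)))
      add("error", sprintf("negative abundance %g", ab[neg[k, 1], neg[k, 2]]),
          sprintf("sample %s, metabolite %s", rownames(ab)[neg[k, 1]],
                  colnames(ab)[neg[k, 2]]))
  }
  if (anyDuplicated(sm$sample_id))
    add("error", "duplicate sample ids",
        paste(unique(sm$sample_id[duplicated(sm$sample_id)]),
              collapse = ", "))
  if (anyDuplicated(mm$metabolite_id))
    add("error", "duplicate metabolite ids",
        paste(unique(mm$metabolite_id[duplicated(mm$metabolite_id)]),
              collapse = ", "))
  bad_t <- !sm$tissue %in% .TISSUES
  if (any(bad_t))
    add("error", "tissue must be lung or plasma",
        paste(sm$sample_id[bad_t], collapse = ", "))
  bad_r <- !sm$role %in% .ROLES
  if (any(bad_r))
    add("error", "role must be study or qc",
        paste(sm$sample_id[bad_r], collapse = ", "))
  bad_c <- !mm$chem_class %in% .CHEM_CLASSES
  if (any(bad_c))
    add("error", "unknown chem_class",
        paste(mm$metabolite_id[bad_c], collapse = ", "))
  study <- sm$role == "study"
  if (any(study & is.na(sm$dose_gy)))
    add("error", "study sample without dose_gy",
        paste(sm$sample_id[study & is.na(sm$dose_gy)], collapse = ", "))
  if (table@normalized == "raw") {
    lung_noweight <- study & sm$tissue == "lung" &
      (is.na(sm$tissue_weight_mg) | sm$tissue_weight_mg <= 0)
    if (any(lung_noweight))
      add("error", "lung study sample lacking positive tissue_weight_mg",
          paste(sm$sample_id[lung_noweight], collapse = ", "))
    is_ids <- mm$metabolite_id[mm$chem_class == "internal_standard"]
    chan <- mm$is_channel[mm$chem_class != "internal_standard"]
    bad_ch <- !is.na(chan) & !chan %in% is_ids
    if (any(bad_ch))
      add("error", "is_channel does not name an internal-standard column",
          paste(unique(chan[bad_ch]), collapse = ", "))
    if (any(is.na(chan)))
      add("warning", "metabolite without assigned internal standard",
          paste(mm$metabolite_id[mm$chem_class != "internal_standard"][
            is.na(chan)], collapse = ", "))
  }
  ac_like <- mm$chem_class == "acylcarnitine" |
    tolower(mm$name) %in% c("carnitine", "acetylcarnitine")
  if (any(ac_like & is.na(mm$acyl_chain)))
    add("error", "acylcarnitine-family metabolite without acyl_chain",
        paste(mm$metabolite_id[ac_like & is.na(mm$acyl_chain)],
              collapse = ", "))
  if (any(!ac_like & !is.na(mm$acyl_chain)))
    add("warning", "acyl_chain set outside the acylcarnitine family",
        paste(mm$metabolite_id[!ac_like & !is.na(mm$acyl_chain)],
              collapse = ", "))

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), message = character(0),
               location = character(0), stringsAsFactors = FALSE)
  new("ValidationReport", ok = !any(issues$severity == "error"),
      issues = issues)
}

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport: ", if (object@ok) "OK" else "INVALID", "\n")
  if (nrow(object@issues)) {
    for (k in seq_len(nrow(object@issues)))
      cat(sprintf("  [%s] %s (%s)\n", object@issues$severity[k],
                  object@issues$message[k], object@issues$location[k]))
  } else cat("  no issues\n")
})
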