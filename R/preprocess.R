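#' Internal-standard (and tissue-weight) normalization
#'
#' Divides every metabolite peak area by the sample's assigned
#' internal-standard channel value, and additionally by the sample's tissue
#' weight in mg when \code{mode = "is_weight"} (lung tissue). IS columns are
#' removed from the output; missing cells stay missing. QC samples carry no
#' tissue weight and are IS-normalized only.
#'
#' @param table a raw \linkS4class{SampleTable}; every non-IS metabolite must
#'   have an \code{is_channel} present in the table.
#' @param mode "is" (plasma) or "is_weight" (lung).
#' @return a \linkS4class{SampleTable} with \code{normalizedMode()} set and
#'   IS columns dropped.
#' @export
normalizeTable <- function(table, mode = c("is", "is_weight")) {
  stopifnot(is(table, "SampleTable"))
  mode <- match.arg(mode)
  if (table@normalized != "raw")
    stop("table is already normalized (", table@normalized, ")")
  mm <- table@metabolites
  sm <- table@samples
  ab <- table@abundances
  is_ids <- mm$metabolite_id[mm$chem_class == "internal_standard"]
  targets <- mm$metabolite_id[mm$chem_class != "internal_standard"]
  chan <- mm$is_channel[match(targets, mm$metabolite_id)]
  if (any(is.na(chan) | !chan %in% is_ids))
    stop("metabolites without a resolvable internal standard: ",
         paste(targets[is.na(chan) | !chan %in% is_ids], collapse = ", "))
  if (mode == "is_weight") {
    study <- sm$role == "study"
    if (any(sm$tissue[study] != "lung"))
      stop("is_weight normalization applies to lung tissue only")
    if (any(is.na(sm$tissue_weight_mg[study]) |
            sm$tissue_weight_mg[study] <= 0))
      stop("is_weight normalization requires a positive tissue_weight_mg ",
           "on every study sample")
  } else {
    if (any(sm$tissue[sm$role == "study"] == "lung"))
      stop("lung tissue requires mode = \"is_weight\"")
  }
  for (isid in is_ids) {
    v <- ab[, isid]
    if (any(is.na(v) | v == 0))
      stop(sprintf("internal standard %s is zero or missing for sample %s",
                   isid, rownames(ab)[which(is.na(v) | v == 0)[1]]))
  }
  out <- ab[, targets, drop = FALSE]
  denom <- ab[, chan, drop = FALSE]  # per-target IS column, row-matched
  out <- out / denom
  if (mode == "is_weight") {
    w <- ifelse(sm$role == "study", sm$tissue_weight_mg, 1)
    out <- out / w
  }
  mm_out <- mm[match(targets, mm$metabolite_id), , drop = FALSE]
  rownames(mm_out) <- NULL
  new("SampleTable", abundances = out, samples = sm, metabolites = mm_out,
      normalized = if (mode == "is") "is_normalized" else
        "is_weight_normalized")
}

.qc_rsd <- function(table) {
  qc <- table@samples$role == "qc"
  ab <- table@abundances[qc, , drop = FALSE]
  apply(ab, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    m <- mean(v)
    if (m == 0) return(Inf)
    stats::sd(v) / m
  })
}

#' Missingness and QC-RSD feature filter
#'
#' Retains metabolites whose missing-value fraction over study samples is
#' strictly below \code{max_missing} and whose relative standard deviation
#' over QC injections (sample SD / mean, missing QC values excluded) is
#' strictly below \code{max_rsd}. A metabolite failing both rules is counted
#' once, under missingness. Metabolites with a zero QC mean are removed with
#' a note.
#'
#' @param table a \linkS4class{SampleTable} with at least two QC samples.
#' @param max_missing,max_rsd thresholds in (0, 1]; defaults 0.20 and 0.30.
#' @return list with elements \code{table} (the filtered
#'   \linkS4class{SampleTable}) and \code{report} (a
#'   \linkS4class{QCReport}).
#' @export
qcFilter <- function(table, max_missing = 0.20, max_rsd = 0.30) {
  stopifnot(is(table, "SampleTable"))
  if (max_missing <= 0 || max_missing > 1 || max_rsd <= 0 || max_rsd > 1)
    stop("thresholds must lie in (0, 1]")
  sm <- table@samples
  if (sum(sm$role == "qc") < 2)
    stop("qcFilter requires at least 2 QC samples")
  study <- sm$role == "study"
  ab <- table@abundances
  is_col <- table@metabolites$chem_class == "internal_standard"
  miss_frac <- colMeans(is.na(ab[study, , drop = FALSE]))
  rsd <- .qc_rsd(table)
  notes <- character(0)
  fail_missing <- miss_frac >= max_missing
  fail_rsd <- !fail_missing & (is.na(rsd) | rsd >= max_rsd)
  if (any(is.infinite(rsd)))
    notes <- c(notes, paste("zero QC mean:", paste(
      colnames(ab)[is.infinite(rsd)], collapse = ", ")))
  keep <- !fail_missing & !fail_rsd
  keep[is_col] <- TRUE  # IS channels are not features; never filtered
  report <- new("QCReport",
                n_metabolites_in = sum(!is_col),
                n_removed_missing = sum(fail_missing & !is_col),
                n_removed_rsd = sum(fail_rsd & !is_col),
                rsd_per_metabolite = rsd[!is_col],
                frac_rsd_lt = .frac_rsd_lt(rsd[!is_col]),
                qc_within_2sd = logical(0),
                notes = notes)
  list(table = table[, keep], report = report)
}

.frac_rsd_lt <- function(rsd, thresholds = c(0.10, 0.20, 0.30)) {
  ok <- !is.na(rsd)
  out <- vapply(thresholds, function(th) mean(rsd[ok] < th), numeric(1))
  names(out) <- format(thresholds, nsmall = 2)
  out
}

#' QC stability summary
#'
#' Reports the fraction of metabolites whose QC RSD falls below 10/20/30%,
#' and flags each QC sample whose first principal-component score (PCA of
#' unit-variance-scaled study + QC samples, missing cells mean-imputed) lies
#' within two standard deviations of the QC scores' mean.
#'
#' @param table a \linkS4class{SampleTable} with at least two QC samples.
#' @return a \linkS4class{QCReport}.
#' @export
qcSummary <- function(table) {
  stopifnot(is(table, "SampleTable"))
  sm <- table@samples
  if (sum(sm$role == "qc") < 2)
    stop("qcSummary requires at least 2 QC samples")
  is_col <- table@metabolites$chem_class == "internal_standard"
  rsd <- .qc_rsd(table)[!is_col]
  ab <- table@abundances[, !is_col, drop = FALSE]
  ## mean-impute and unit-variance scale for the score plot
  for (j in seq_len(ncol(ab))) {
    v <- ab[, j]
    if (anyNA(v)) ab[is.na(v), j] <- mean(v, na.rm = TRUE)
  }
  sds <- apply(ab, 2, stats::sd)
  keep <- sds > 0
  pc <- stats::prcomp(ab[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  sc1 <- pc$x[, 1]
  qc_idx <- sm$role == "qc"
  qs <- sc1[qc_idx]
  within <- abs(qs - mean(qs)) <= 2 * stats::sd(qs)
  names(within) <- sm$sample_id[qc_idx]
  new("QCReport",
      n_metabolites_in = sum(!is_col),
      n_removed_missing = 0L, n_removed_rsd = 0L,
      rsd_per_metabolite = rsd,
      frac_rsd_lt = .frac_rsd_lt(rsd),
      qc_within_2sd = within,
      notes = character(0))
}

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@n_metabolites_in, "metabolites in;",
      object@n_removed_missing, "removed (missingness),",
      object@n_removed_rsd, "removed (QC RSD)\n")
  f <- object@frac_rsd_lt
  if (length(f))
    cat(sprintf("  RSD < 10/20/30%%: %.1f / %.1f / %.1f %% of metabolites\n",
                100 * f[1], 100 * f[2], 100 * f[3]))
  if (length(object@qc_within_2sd))
    cat("  QC within 2 SD (PC1):", sum(object@qc_within_2sd), "/",
        length(object@qc_within_2sd), "\n")
})
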