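.CHEM_CLASSES <- c("amino_acid", "bile_acid", "acylcarnitine", "lipid",
                   "organic_acid", "other", "internal_standard")
.NORM_MODES <- c("raw", "is_normalized", "is_weight_normalized")
.TISSUES <- c("lung", "plasma")
.ROLES <- c("study", "qc")

#' SampleTable: sample-by-metabolite abundance container
#'
#' The universal currency of the pipeline: a numeric matrix of peak areas or
#' normalized intensities with samples as rows and metabolites as columns,
#' together with per-sample and per-metabolite annotation. Missing
#' measurements are stored as \code{NA}, never as zero; zero is a legal
#' measured intensity.
#'
#' @slot abundances numeric matrix, samples x metabolites; dimnames carry the
#'   sample and metabolite ids. All present values are nonnegative.
#' @slot samples data.frame with columns \code{sample_id}, \code{animal_id},
#'   \code{tissue} ("lung"/"plasma"), \code{dose_gy}, \code{day},
#'   \code{role} ("study"/"qc") and \code{tissue_weight_mg} (required for
#'   lung study samples while the table is raw). QC samples carry \code{NA}
#'   dose and day.
#' @slot metabolites data.frame with columns \code{metabolite_id},
#'   \code{name}, \code{chem_class}, \code{acyl_chain} (e.g. "C16:0",
#'   "carnitine", "C2"; \code{NA} outside the acylcarnitine family) and
#'   \code{is_channel} (id of the internal-standard column used for
#'   normalization; \code{NA} for the IS columns themselves).
#' @slot normalized one of "raw", "is_normalized", "is_weight_normalized".
#'
#' @seealso [SampleTable()], [validateTable()], [readSampleTable()]
#' @export
setClass("SampleTable",
  representation(abundances = "matrix",
                 samples = "data.frame",
                 metabolites = "data.frame",
                 normalized = "character"))

setValidity("SampleTable", function(object) {
  msg <- character(0)
  ab <- object@abundances
  sm <- object@samples
  mm <- object@metabolites
  need_s <- c("sample_id", "animal_id", "tissue", "dose_gy", "day", "role",
              "tissue_weight_mg")
  need_m <- c("metabolite_id", "name", "chem_class", "acyl_chain",
              "is_channel")
  if (!all(need_s %in% names(sm)))
    msg <- c(msg, paste("samples lacks columns:",
                        paste(setdiff(need_s, names(sm)), collapse = ", ")))
  if (!all(need_m %in% names(mm)))
    msg <- c(msg, paste("metabolites lacks columns:",
                        paste(setdiff(need_m, names(mm)), collapse = ", ")))
  if (nrow(ab) != nrow(sm))
    msg <- c(msg, "abundance row count != number of sample records")
  if (ncol(ab) != nrow(mm))
    msg <- c(msg, "abundance column count != number of metabolite records")
  if (length(msg) == 0) {
    if (anyDuplicated(sm$sample_id))
      msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(mm$metabolite_id))
      msg <- c(msg, "duplicate metabolite ids")
    if (!identical(rownames(ab), as.character(sm$sample_id)))
      msg <- c(msg, "abundance rownames do not match sample ids")
    if (!identical(colnames(ab), as.character(mm$metabolite_id)))
      msg <- c(msg, "abundance colnames do not match metabolite ids")
  }
  if (length(object@normalized) != 1L ||
      !object@normalized %in% .NORM_MODES)
    msg <- c(msg, "normalized must be one of raw/is_normalized/is_weight_normalized")
  if (length(msg)) msg else TRUE
})

#' ValidationReport: outcome of content validation
#'
#' @slot ok logical; \code{TRUE} iff no issue of severity "error".
#' @slot issues data.frame with columns severity ("error"/"warning"),
#'   message, location.
#' @export
setClass("ValidationReport",
  representation(ok = "logical", issues = "data.frame"))

#' QCReport: quality-control summary of a SampleTable
#'
#' Filled by [qcFilter()] (filter accounting, per-metabolite RSD) and by
#' [qcSummary()] (RSD threshold fractions and the PCA two-SD flag for each
#' QC sample).
#'
#' @slot n_metabolites_in,n_removed_missing,n_removed_rsd integer counts.
#' @slot rsd_per_metabolite named numeric, QC relative standard deviation
#'   (sample SD / mean over QC injections).
#' @slot frac_rsd_lt named numeric at thresholds 0.10/0.20/0.30.
#' @slot qc_within_2sd named logical per QC sample: first principal-component
#'   score within two SD of the QC score centre.
#' @slot notes character.
#' @export
setClass("QCReport",
  representation(n_metabolites_in = "integer",
                 n_removed_missing = "integer",
                 n_removed_rsd = "integer",
                 rsd_per_metabolite = "numeric",
                 frac_rsd_lt = "numeric",
                 qc_within_2sd = "logical",
                 notes = "character"))

#' DiffResult: per-metabolite differential screen for one contrast
#'
#' @slot contrast human-readable description (tissue, day, groups, test).
#' @slot test one of "wilcoxon_paired", "mann_whitney", "anova".
#' @slot alpha,fdr_max significance thresholds: significant iff
#'   \code{p < alpha} and \code{q < fdr_max} (BH-adjusted q).
#' @slot table data.frame: metabolite_id, statistic, p, q, log2fc,
#'   significant, note.
#' @export
setClass("DiffResult",
  representation(contrast = "character",
                 test = "character",
                 alpha = "numeric",
                 fdr_max = "numeric",
                 table = "data.frame"))

#' HeatmapZones: clustered fold-change zoning of differential metabolites
#'
#' @slot log2fc_matrix metabolite x dose matrix of log2 fold changes versus
#'   the control group.
#' @slot metabolite_order character, dendrogram ordering.
#' @slot zone_labels named character ("a"/"b"/...) per metabolite.
#' @export
setClass("HeatmapZones",
  representation(log2fc_matrix = "matrix",
                 metabolite_order = "character",
                 zone_labels = "character"))

#' LatentModel: NIPALS PLS / PLS-DA factorization
#'
#' @slot ncomp number of components A.
#' @slot scores n x A score matrix T (mutually orthogonal columns).
#' @slot weights p x A weight matrix W (unit-norm columns).
#' @slot xloadings p x A loading matrix P.
#' @slot yloadings c x A Y-loading matrix Q.
#' @slot ssy per-component explained Y sum of squares, t_a't_a * ||q_a||^2.
#' @slot x_center,x_scale,y_center centering/scaling vectors.
#' @slot R2X,R2Y,Q2 fit statistics (Q2 is NA unless cross-validated).
#' @slot y_levels class labels when fitted as PLS-DA, else character(0).
#' @slot imputed TRUE when missing cells were mean-imputed before fitting.
#' @export
setClass("LatentModel",
  representation(ncomp = "integer", scores = "matrix", weights = "matrix",
                 xloadings = "matrix", yloadings = "matrix", ssy = "numeric",
                 x_center = "numeric", x_scale = "numeric",
                 y_center = "numeric", R2X = "numeric", R2Y = "numeric",
                 Q2 = "numeric", y_levels = "character",
                 imputed = "logical"))

#' OSCResult: orthogonal signal correction of a scaled matrix
#'
#' @slot X_filtered the corrected matrix.
#' @slot osc_scores n x n_osc removed score vectors, each with absolute
#'   Pearson correlation below 1e-6 with every response column.
#' @slot osc_loadings,osc_weights p x n_osc loadings/weights; the weights
#'   reproduce the correction on new samples.
#' @slot removed_variance_fraction fraction of the (scaled) X sum of squares
#'   removed.
#' @export
setClass("OSCResult",
  representation(X_filtered = "matrix", osc_scores = "matrix",
                 osc_loadings = "matrix", osc_weights = "matrix",
                 removed_variance_fraction = "numeric"))

#' KPLSModel: kernel partial least squares
#'
#' @slot kernel "gaussian" or "linear".
#' @slot gamma Gaussian kernel width (exp(-gamma * ||xi - xj||^2)).
#' @slot Xtrain scaled training inputs; x_center/x_scale the scaling used.
#' @slot K uncentered training kernel matrix.
#' @slot Tmat,U score matrices of the kernel-PLS extraction.
#' @slot dual_coef n x c dual regression coefficients: predictions are
#'   \code{Kc_new \%*\% dual_coef + y_center}.
#' @slot y_center response centering; y_levels class labels for DA use.
#' @slot ncomp number of components.
#' @export
setClass("KPLSModel",
  representation(kernel = "character", gamma = "numeric", Xtrain = "matrix",
                 x_center = "numeric", x_scale = "numeric", K = "matrix",
                 Tmat = "matrix", U = "matrix", dual_coef = "matrix",
                 y_center = "numeric", y_levels = "character",
                 ncomp = "integer"))

#' PermutationReport: response permutation test of a PLS model
#'
#' @slot n_perm number of permutations (200 by default).
#' @slot observed_R2Y,observed_Q2 statistics of the unpermuted model.
#' @slot permuted_R2Y,permuted_Q2 length-n_perm vectors under permuted Y.
#' @slot empirical_p_Q2 (1 + #\{permuted Q2 >= observed\}) / (n_perm + 1).
#' @export
setClass("PermutationReport",
  representation(n_perm = "integer", observed_R2Y = "numeric",
                 observed_Q2 = "numeric", permuted_R2Y = "numeric",
                 permuted_Q2 = "numeric", empirical_p_Q2 = "numeric"))

#' MarkerPanel: metabolite panel with selection provenance
#'
#' @slot table data.frame: metabolite_id, vip_lung, vip_plasma, passed_vip,
#'   cross_tissue_r, cross_tissue_p, vip_final, rank.
#' @slot stage one of "intersection", "vip", "correlation", "final".
#' @slot k target panel size at the final stage.
#' @export
setClass("MarkerPanel",
  representation(table = "data.frame", stage = "character", k = "integer"))

#' TriageResult: per-sample injury classification (Table-1 shape)
#'
#' @slot day plasma sampling day.
#' @slot predictions data.frame: sample_id, true_class, predicted_class,
#'   predicted_dose_gy.
#' @slot confusion square integer matrix, rows = true class.
#' @slot per_class_accuracy named numeric, diag(confusion)/rowSums.
#' @slot cv_scheme description ("loo", "kfold", "fitted").
#' @export
setClass("TriageResult",
  representation(day = "integer", predictions = "data.frame",
                 confusion = "matrix", per_class_accuracy = "numeric",
                 cv_scheme = "character"))

#' TrajectoryTable: ratio-to-control time courses
#'
#' @slot ratios data.frame: metabolite_id, dose_gy, day, ratio_to_control.
#' @slot summary data.frame per metabolite x dose: first_significant_day,
#'   monotone_2_to_5, direction.
#' @export
setClass("TrajectoryTable",
  representation(ratios = "data.frame", summary = "data.frame"))

#' CorrelationNetwork: thresholded metabolite Pearson network
#'
#' @slot group description of the sample stratum (tissue, dose, day).
#' @slot nodes data.frame: metabolite_id, direction ("up"/"down"/"ns").
#' @slot edges data.frame: m1, m2 (m1 < m2 lexically), r, p, sign ("+"/"-").
#' @slot r_min,alpha the |r| and p thresholds defining edges.
#' @export
setClass("CorrelationNetwork",
  representation(group = "character", nodes = "data.frame",
                 edges = "data.frame", r_min = "numeric", alpha = "numeric"))

#' RatioResult: CPT1/CPT2 surrogate enzyme activity ratios
#'
#' CPT1 ratio = carnitine / (AC16:1 + AC18:0);
#' CPT2 ratio = (AC16:0 + AC18:1) / AC2.
#'
#' @slot per_sample data.frame: sample_id, dose_gy, cpt1, cpt2.
#' @slot group_stats data.frame per ratio x dose group: median, q25, q75
#'   (linear-interpolation quantiles).
#' @slot kw_p named numeric, Kruskal-Wallis p per ratio.
#' @slot pairwise data.frame: ratio, group, reference, p, mark.
#' @slot notes character.
#' @export
setClass("RatioResult",
  representation(per_sample = "data.frame", group_stats = "data.frame",
                 kw_p = "numeric", pairwise = "data.frame",
                 notes = "character"))
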