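#' Default planted-effect library
#'
#' Builds the effect library that gives synthetic cohorts the qualitative
#' regulation structure seen after whole-thorax irradiation: long-chain
#' acylcarnitines rise from day 1 and stay elevated; free carnitine,
#' short-chain AC5:0 (high dose only), branched-chain amino acids,
#' taurine-conjugated bile acids and urea fall, each with its characteristic
#' onset day. The first \code{n_planted} entries carry a nonzero amplitude;
#' all remaining metabolites are decoys (amplitude 0). The six
#' carnitine-shuttle channels used by the CPT surrogate ratios (carnitine,
#' AC16:1, AC18:0, AC16:0, AC18:1, AC2) are always present in the universe,
#' as planted markers or as decoys.
#'
#' @param n_metabolites size of the metabolite universe (internal standards
#'   not included).
#' @param n_planted number of metabolites with nonzero amplitude; at least 6
#'   (the mandatory archetypes), at most 16 (the named pool).
#' @param amplitude_sd planted effect amplitude: the maximum absolute
#'   log-scale shift at the highest dose and latest day, in units of the
#'   residual log-SD.
#' @param seed integer seed controlling decoy class assignment.
#' @return data.frame with one row per metabolite: metabolite_id, name,
#'   chem_class, acyl_chain, direction, amplitude_sd, dose_shape
#'   ("linear", "saturating", "high_dose_only"), onset_day.
#' @export
defaultEffectLibrary <- function(n_metabolites, n_planted = 7,
                                 amplitude_sd = 3, seed = 1) {
  pool <- data.frame(
    metabolite_id = c("ac_c20_1", "carnitine", "ac_c5_0", "leucine",
                      "taurocholic_acid", "urea", "ac_c16_0", "ac_c18_1",
                      "ac_c9_1", "tauroursodeoxycholic_acid", "cholesterol",
                      "arginine", "ac_c16_1", "ac_c18_0", "indoxyl_sulfate",
                      "lpc_o_18_0"),
    name = c("acylcarnitine C20:1", "carnitine", "acylcarnitine C5:0",
             "leucine", "taurocholic acid", "urea", "acylcarnitine C16:0",
             "acylcarnitine C18:1", "acylcarnitine C9:1",
             "tauroursodeoxycholic acid", "cholesterol", "arginine",
             "acylcarnitine C16:1", "acylcarnitine C18:0",
             "indoxyl sulfate", "LPC(O-18:0)"),
    chem_class = c("acylcarnitine", "other", "acylcarnitine", "amino_acid",
                   "bile_acid", "organic_acid", "acylcarnitine",
                   "acylcarnitine", "acylcarnitine", "bile_acid", "lipid",
                   "amino_acid", "acylcarnitine", "acylcarnitine", "other",
                   "lipid"),
    acyl_chain = c("C20:1", "carnitine", "C5:0", NA, NA, NA, "C16:0",
                   "C18:1", "C9:1", NA, NA, NA, "C16:1", "C18:0", NA, NA),
    direction = c(1, -1, -1, -1, -1, -1, 1, 1, -1, -1, 1, -1, 1, 1, -1, 1),
    dose_shape = c("saturating", "linear", "high_dose_only", "linear",
                   "linear", "linear", "saturating", "saturating", "linear",
                   "linear", "linear", "linear", "saturating", "saturating",
                   "high_dose_only", "linear"),
    onset_day = c(1, 2, 2, 3, 5, 1, 1, 1, 3, 5, 5, 3, 1, 1, 5, 5),
    stringsAsFactors = FALSE)
  if (n_planted < 6)
    stop("n_planted must cover the 6 mandatory archetypes")
  if (n_planted > nrow(pool))
    stop("n_planted exceeds the named pool (", nrow(pool), ")")
  if (n_planted > n_metabolites)
    stop("n_planted exceeds n_metabolites")

  cpt_channels <- c("carnitine", "ac_c16_1", "ac_c18_0", "ac_c16_0",
                    "ac_c18_1", "ac_c2")
  planted <- pool[seq_len(n_planted), , drop = FALSE]
  planted$amplitude_sd <- amplitude_sd
  extra <- setdiff(cpt_channels, planted$metabolite_id)
  extra_rows <- pool[pool$metabolite_id %in% extra, , drop = FALSE]
  if ("ac_c2" %in% extra) {
    extra_rows <- rbind(extra_rows, data.frame(
      metabolite_id = "ac_c2", name = "acetylcarnitine",
      chem_class = "acylcarnitine", acyl_chain = "C2", direction = 0,
      dose_shape = "linear", onset_day = 1, stringsAsFactors = FALSE))
  }
  if (nrow(extra_rows)) {
    extra_rows$amplitude_sd <- 0
    extra_rows$direction <- 0
  }
  named <- rbind(planted, extra_rows)
  n_decoys <- n_metabolites - nrow(named)
  if (n_decoys < 0)
    stop("n_metabolites too small for the planted markers plus the ",
         "carnitine-shuttle channels (need >= ", nrow(named), ")")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  decoys <- data.frame(
    metabolite_id = sprintf("m%03d", seq_len(n_decoys)),
    name = sprintf("metabolite %03d", seq_len(n_decoys)),
    chem_class = sample(c("amino_acid", "lipid", "organic_acid", "other"),
                        n_decoys, replace = TRUE),
    acyl_chain = NA_character_,
    direction = 0, dose_shape = "linear", onset_day = 1,
    amplitude_sd = 0, stringsAsFactors = FALSE)
  out <- rbind(named, decoys)
  rownames(out) <- NULL
  out[, c("metabolite_id", "name", "chem_class", "acyl_chain", "direction",
          "amplitude_sd", "dose_shape", "onset_day")]
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of [simulateCohort()]. The
#' defaults reproduce the study design the pipeline targets: doses
#' 0/10/20/35 Gy with 11/10/9/9 animals, plasma sampled at days 1/2/3/5 and
#' lung at day 5, 67 metabolites of which 7 carry planted dose effects of
#' amplitude 3 residual-SD, residual log-SD 0.3, animal random-effect log-SD
#' 0.1, six pooled QC injections at 10% analytical CV, and 5% missingness
#' completely at random.
#'
#' @param doses_gy dose levels (control first).
#' @param n_per_dose animals per dose (same length as \code{doses_gy}).
#' @param days plasma sampling days; lung is simulated at the last day.
#' @param n_metabolites metabolite universe size (internal standards extra).
#' @param n_planted metabolites with nonzero planted amplitude.
#' @param effect_library optional data.frame as returned by
#'   [defaultEffectLibrary()]; built from the seed when \code{NULL}.
#' @param amplitude_sd planted amplitude in residual-SD units.
#' @param residual_sd_log residual log-scale SD of single measurements.
#' @param animal_sd_log between-animal random effect log-SD (shared across
#'   tissues and days).
#' @param qc_n number of QC injections per table.
#' @param qc_rsd analytical coefficient of variation of QC injections.
#' @param missing_rate MCAR missing-cell probability among study samples,
#'   in [0, 0.5).
#' @param seed integer; the single stream for all randomness.
#' @return a validated list of class \code{SimConfig}.
#' @export
simConfig <- function(doses_gy = c(0, 10, 20, 35),
                      n_per_dose = c(11, 10, 9, 9),
                      days = c(1, 2, 3, 5),
                      n_metabolites = 67,
                      n_planted = 7,
                      effect_library = NULL,
                      amplitude_sd = 3,
                      residual_sd_log = 0.3,
                      animal_sd_log = 0.1,
                      qc_n = 6,
                      qc_rsd = 0.1,
                      missing_rate = 0.05,
                      seed = 1) {
  if (length(doses_gy) < 2 || length(doses_gy) != length(n_per_dose))
    stop("doses_gy and n_per_dose must align and contain >= 2 dose levels")
  if (length(days) < 1) stop("empty day list")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("missing_rate must lie in [0, 0.5)")
  if (residual_sd_log <= 0) stop("residual_sd_log must be positive")
  if (animal_sd_log < 0) stop("animal_sd_log must be nonnegative")
  if (qc_rsd <= 0) stop("qc_rsd must be positive")
  if (n_planted > n_metabolites)
    stop("n_planted exceeds n_metabolites")
  cfg <- list(doses_gy = sort(doses_gy), n_per_dose = n_per_dose[
                order(doses_gy)],
              days = sort(days), n_metabolites = n_metabolites,
              n_planted = n_planted, effect_library = effect_library,
              amplitude_sd = amplitude_sd,
              residual_sd_log = residual_sd_log,
              animal_sd_log = animal_sd_log, qc_n = qc_n, qc_rsd = qc_rsd,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' CohortData: a simulated lung + longitudinal plasma cohort
#'
#' @slot lung \linkS4class{SampleTable}, terminal-day lung tissue.
#' @slot plasma_by_day named list of \linkS4class{SampleTable}, one per day.
#' @slot truth the effect library actually planted.
#' @slot config the \code{SimConfig} used.
#' @export
setClass("CohortData",
  representation(lung = "SampleTable", plasma_by_day = "list",
                 truth = "data.frame", config = "list"))

setMethod("show", "CohortData", function(object) {
  cat("CohortData:", length(object@plasma_by_day), "plasma days + lung,",
      sum(object@truth$amplitude_sd > 0), "planted effects\n")
})

.dose_shape_f <- function(shape, dose_frac, is_max) {
  switch(shape,
         linear = dose_frac,
         saturating = sqrt(dose_frac),
         high_dose_only = as.numeric(is_max),
         stop("unknown dose_shape: ", shape))
}

#' Simulate a whole-thorax irradiation metabolomics cohort
#'
#' Generates lung (terminal day) and per-day plasma sample tables under a
#' log-normal measurement model: for animal a, metabolite m, dose d and day
#' t, \deqn{\log x = \mu_m + u_a + dir_m \cdot amp_m \cdot \sigma
#' \cdot f_{shape}(d/d_{max}) \cdot 1[t \ge onset_m] + \epsilon,} with
#' \eqn{u_a \sim N(0, animal\_sd^2)} shared across tissues and days,
#' \eqn{\epsilon \sim N(0, \sigma^2)} and \eqn{\sigma} the residual log-SD.
#' Abundances are exponentiated (strictly positive) and multiplied by a
#' small per-sample injection factor that the internal-standard channels
#' share, so IS normalization is exercised non-trivially; lung raw areas
#' additionally scale with tissue weight. QC injections are drawn around the
#' pooled study mean with coefficient of variation \code{qc_rsd}. Missing
#' cells are planted completely at random among study samples. The whole
#' cohort is reproducible bit-for-bit from \code{config$seed}.
#'
#' @param config a \code{SimConfig} from [simConfig()].
#' @return a \linkS4class{CohortData}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  old <- .save_rng()
  on.exit(.restore_rng(old))

  lib <- config$effect_library
  if (is.null(lib))
    lib <- defaultEffectLibrary(config$n_metabolites, config$n_planted,
                                config$amplitude_sd, seed = config$seed)
  if (nrow(lib) != config$n_metabolites)
    stop("effect library size does not match n_metabolites")
  set.seed(config$seed)

  doses <- config$doses_gy
  dmax <- max(doses)
  n_met <- nrow(lib)
  met_ids <- lib$metabolite_id

  ## metabolite metadata incl. two internal-standard channels
  is_ids <- c("IS_1", "IS_2")
  is_base <- c(IS_1 = 5e4, IS_2 = 8e4)
  mm <- data.frame(metabolite_id = c(met_ids, is_ids),
                   name = c(lib$name, "internal standard 1",
                            "internal standard 2"),
                   chem_class = c(lib$chem_class, "internal_standard",
                                  "internal_standard"),
                   acyl_chain = c(lib$acyl_chain, NA, NA),
                   is_channel = c(sample(is_ids, n_met, replace = TRUE),
                                  NA, NA),
                   stringsAsFactors = FALSE)

  ## animals
  n_animals <- sum(config$n_per_dose)
  animal_ids <- sprintf("A%02d", seq_len(n_animals))
  animal_dose <- rep(doses, config$n_per_dose)
  u_a <- stats::rnorm(n_animals, 0, config$animal_sd_log)
  names(u_a) <- animal_ids
  mu_m <- stats::runif(n_met, log(1e4), log(1e6))
  inj_sd <- 0.02  # instrument/injection variability shared with IS channels

  make_table <- function(tissue, day) {
    n_study <- n_animals
    sids <- sprintf("%s_d%d_%s", tissue, day, animal_ids)
    weights <- if (tissue == "lung") stats::runif(n_study, 18, 22) else
      rep(NA_real_, n_study)
    shift <- matrix(0, n_study, n_met)
    for (j in seq_len(n_met)) {
      if (lib$amplitude_sd[j] <= 0 || day < lib$onset_day[j]) next
      f <- vapply(animal_dose, function(d)
        .dose_shape_f(lib$dose_shape[j], d / dmax, d == dmax), numeric(1))
      shift[, j] <- lib$direction[j] * lib$amplitude_sd[j] *
        config$residual_sd_log * f
    }
    eps <- matrix(stats::rnorm(n_study * n_met, 0, config$residual_sd_log),
                  n_study, n_met)
    logx <- matrix(mu_m, n_study, n_met, byrow = TRUE) + u_a[animal_ids] +
      shift + eps
    inj <- exp(stats::rnorm(n_study, 0, inj_sd))
    ab <- exp(logx) * inj
    if (tissue == "lung") ab <- ab * (weights / 20)
    is_cols <- outer(inj, is_base) *
      exp(matrix(stats::rnorm(n_study * 2, 0, inj_sd / 2), n_study, 2))
    ## QC injections around the pooled study mean, CV = qc_rsd
    sdlog_qc <- sqrt(log(1 + config$qc_rsd^2))
    pooled <- colMeans(ab)
    qc_inj <- exp(stats::rnorm(config$qc_n, 0, inj_sd))
    qc_ab <- matrix(pooled, config$qc_n, n_met, byrow = TRUE) * qc_inj *
      matrix(stats::rlnorm(config$qc_n * n_met, -sdlog_qc^2 / 2, sdlog_qc),
             config$qc_n, n_met)
    qc_is <- outer(qc_inj, is_base) *
      exp(matrix(stats::rnorm(config$qc_n * 2, 0, inj_sd / 2),
                 config$qc_n, 2))
    ## MCAR missingness among study samples, never in IS channels
    if (config$missing_rate > 0) {
      drop <- matrix(stats::runif(n_study * n_met) < config$missing_rate,
                     n_study, n_met)
      ab[drop] <- NA_real_
    }
    qids <- sprintf("%s_d%d_QC%d", tissue, day, seq_len(config$qc_n))
    full <- rbind(cbind(ab, is_cols), cbind(qc_ab, qc_is))
    dimnames(full) <- list(c(sids, qids), c(met_ids, is_ids))
    sm <- data.frame(
      sample_id = c(sids, qids),
      animal_id = c(animal_ids, rep("QC_pool", config$qc_n)),
      tissue = tissue,
      dose_gy = c(animal_dose, rep(NA_real_, config$qc_n)),
      day = c(rep(as.numeric(day), n_study), rep(NA_real_, config$qc_n)),
      role = c(rep("study", n_study), rep("qc", config$qc_n)),
      tissue_weight_mg = c(weights, rep(NA_real_, config$qc_n)),
      stringsAsFactors = FALSE)
    SampleTable(full, sm, mm, normalized = "raw")
  }

  plasma <- lapply(config$days, function(d) make_table("plasma", d))
  names(plasma) <- paste0("day", config$days)
  lung <- make_table("lung", max(config$days))

  new("CohortData", lung = lung, plasma_by_day = plasma, truth = lib,
      config = unclass(config))
}

#' Write a simulated cohort to disk
#'
#' Writes the three-file layout per tissue/day under \code{dir}
#' (\code{lung/}, \code{plasma_day<d>/}) plus \code{truth.json} with the
#' planted effect library.
#'
#' @param cohort a \linkS4class{CohortData}.
#' @param dir output directory.
#' @return invisibly, \code{dir}.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "CohortData"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeSampleTable(cohort@lung, file.path(dir, "lung"))
  for (nm in names(cohort@plasma_by_day))
    writeSampleTable(cohort@plasma_by_day[[nm]],
                     file.path(dir, paste0("plasma_", nm)))
  jsonlite::write_json(cohort@truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(dir)
}
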