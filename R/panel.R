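#' Union of significant metabolites over plasma screens
#'
#' @param plasma_results list of \linkS4class{DiffResult} (one per day).
#' @return character vector (union of significant metabolite ids).
#' @export
unionDifferential <- function(plasma_results) {
  if (!length(plasma_results)) stop("need at least one DiffResult")
  sets <- lapply(plasma_results, significantMetabolites)
  sort(unique(unlist(sets)))
}

#' Intersection of lung and plasma differential sets
#'
#' @param lung_set,plasma_set character vectors of metabolite ids from the
#'   same namespace.
#' @return the intersection (sorted); empty with a warning when disjoint.
#' @export
intersectTissues <- function(lung_set, plasma_set) {
  out <- sort(intersect(lung_set, plasma_set))
  if (!length(out))
    warning("lung and plasma differential sets are disjoint")
  out
}

.study_matrix <- function(table, metabolites) {
  sm <- table@samples
  study <- sm$role == "study"
  X <- table@abundances[study, metabolites, drop = FALSE]
  list(X = X, dose = sm$dose_gy[study], animal = sm$animal_id[study],
       sample_id = sm$sample_id[study])
}

#' VIP screen of candidate metabolites
#'
#' Fits a 2-component PLS-DA (classes = dose groups, unit-variance scaling)
#' separately in lung and plasma, restricted to the candidate metabolites,
#' and keeps candidates whose VIP exceeds \code{threshold} in at least one
#' tissue (\code{rule = "either"}, default) or in both (\code{"both"}).
#'
#' @param candidates character vector of metabolite ids (>= 2).
#' @param lung,plasma \linkS4class{SampleTable}s containing the candidates.
#' @param ncomp components of the screening PLS-DA (default 2).
#' @param threshold VIP cutoff (default 1; strictly greater-than).
#' @param rule "either" or "both".
#' @return a \linkS4class{MarkerPanel} at stage "vip".
#' @export
vipScreen <- function(candidates, lung, plasma, ncomp = 2, threshold = 1,
                      rule = c("either", "both")) {
  rule <- match.arg(rule)
  if (length(candidates) < 2) stop("need >= 2 candidate metabolites")
  dl <- .study_matrix(lung, candidates)
  dp <- .study_matrix(plasma, candidates)
  vl <- vip(fitPLSDA(dl$X, factor(dl$dose), ncomp))
  vp <- vip(fitPLSDA(dp$X, factor(dp$dose), ncomp))
  passed <- if (rule == "either") vl > threshold | vp > threshold else
    vl > threshold & vp > threshold
  tab <- data.frame(metabolite_id = candidates, vip_lung = unname(vl),
                    vip_plasma = unname(vp), passed_vip = unname(passed),
                    cross_tissue_r = NA_real_, cross_tissue_p = NA_real_,
                    vip_final = NA_real_, rank = NA_integer_,
                    stringsAsFactors = FALSE)
  new("MarkerPanel", table = tab, stage = "vip", k = NA_integer_)
}

#' Cross-tissue correlation of candidate metabolites
#'
#' Pearson correlation between lung and plasma levels across animals present
#' in both tables (matched by \code{animal_id}, study samples only),
#' computed per metabolite; two-sided p from the t distribution.
#'
#' @param lung,plasma_day5 \linkS4class{SampleTable}s sharing >= 3 animals.
#' @param candidates metabolite ids present in both tables.
#' @return data.frame: metabolite_id, r, p, n.
#' @export
crossTissueCorr <- function(lung, plasma_day5, candidates) {
  dl <- .study_matrix(lung, candidates)
  dp <- .study_matrix(plasma_day5, candidates)
  common <- intersect(dl$animal, dp$animal)
  if (length(common) < 3) stop("fewer than 3 matched animals")
  il <- match(common, dl$animal)
  ip <- match(common, dp$animal)
  out <- lapply(candidates, function(m) {
    x <- dl$X[il, m]; y <- dp$X[ip, m]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3)
      return(data.frame(metabolite_id = m, r = NA_real_, p = NA_real_,
                        n = sum(ok)))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(metabolite_id = m, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Final panel selection
#'
#' Annotates the VIP-screened candidates with their cross-tissue
#' correlation, drops those below \code{r_min} in absolute value (default 0:
#' annotate only), refits the plasma PLS-DA on the survivors and returns the
#' top \code{k} by final VIP. Ties are broken alphabetically.
#'
#' @param screened a \linkS4class{MarkerPanel} from [vipScreen()].
#' @param corr data.frame from [crossTissueCorr()].
#' @param plasma plasma \linkS4class{SampleTable} for the final refit
#'   (terminal day).
#' @param k panel size (default 7).
#' @param r_min minimum |r| to survive the correlation stage (default 0).
#' @param ncomp components of the final PLS-DA (default 2).
#' @return a \linkS4class{MarkerPanel} at stage "final".
#' @export
selectPanel <- function(screened, corr, plasma, k = 7, r_min = 0,
                        ncomp = 2) {
  stopifnot(is(screened, "MarkerPanel"))
  tab <- screened@table
  tab$cross_tissue_r <- corr$r[match(tab$metabolite_id, corr$metabolite_id)]
  tab$cross_tissue_p <- corr$p[match(tab$metabolite_id, corr$metabolite_id)]
  surv <- tab$passed_vip & !is.na(tab$cross_tissue_r) &
    abs(tab$cross_tissue_r) >= r_min
  survivors <- tab$metabolite_id[surv]
  if (k > length(survivors))
    stop("k exceeds the ", length(survivors), " surviving candidates")
  dp <- .study_matrix(plasma, survivors)
  vf <- vip(fitPLSDA(dp$X, factor(dp$dose), ncomp))
  tab$vip_final[match(survivors, tab$metabolite_id)] <- unname(vf)
  ord <- survivors[order(-vf, survivors)]
  sel <- ord[seq_len(k)]
  tab <- tab[match(sel, tab$metabolite_id), , drop = FALSE]
  tab$rank <- seq_len(k)
  rownames(tab) <- NULL
  new("MarkerPanel", table = tab, stage = "final", k = as.integer(k))
}

#' Metabolite ids of a marker panel
#' @param panel a \linkS4class{MarkerPanel}.
#' @return character vector in rank order.
#' @export
panelMetabolites <- function(panel) {
  stopifnot(is(panel, "MarkerPanel"))
  panel@table$metabolite_id
}

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel (stage", object@stage, "):",
      nrow(object@table), "metabolites\n")
  print(utils::head(object@table, 10))
})

#' Map radiation dose to an injury triage class
#'
#' @param dose_gy dose(s) in Gy.
#' @param doses the configured dose set, ascending (default 0/10/20/35).
#' @param classes class labels matching \code{doses} (default
#'   Control/Mild/Moderate/Severe).
#' @return factor of triage classes.
#' @export
triageMap <- function(dose_gy, doses = c(0, 10, 20, 35),
                      classes = c("Control", "Mild", "Moderate", "Severe")) {
  stopifnot(length(doses) == length(classes))
  i <- match(dose_gy, doses)
  if (anyNA(i))
    stop("dose outside the configured set: ",
         paste(unique(dose_gy[is.na(i)]), collapse = ", "))
  factor(classes[i], levels = classes)
}

#' OSC-KPLS injury triage
#'
#' Cross-validated dose-group classification on a marker panel: for each
#' held-out sample (leave-one-out by default), the training samples are
#' unit-variance scaled, one OSC component (orthogonal to the one-hot class
#' indicators) is removed, a Gaussian kernel PLS is fitted on the corrected
#' matrix, and the held-out sample -- scaled and OSC-corrected with the
#' training parameters -- is assigned a class. A parallel kernel PLS on the
#' numeric dose yields a continuous dose prediction. \code{cv = "none"}
#' reports fitted (training-set) predictions instead.
#'
#' Class assignment (\code{class_rule}): the default "mahalanobis" places
#' the held-out sample in the model's kernel score space and picks the
#' nearest class centroid under the pooled within-class score covariance
#' (the centroid/Mahalanobis-distance convention of PLS-DA practice).
#' "centroid" uses plain Euclidean distance to the score centroids; "argmax"
#' takes the largest predicted class indicator. With few components and
#' ordered dose classes, argmax is prone to masking the intermediate
#' classes, which is why it is not the default.
#'
#' @param plasma_day a \linkS4class{SampleTable} for one day.
#' @param panel a \linkS4class{MarkerPanel} or character vector of
#'   metabolite ids.
#' @param n_osc OSC components (default 1).
#' @param ncomp kernel-PLS components (default 2).
#' @param cv "loo", "kfold" or "none".
#' @param folds folds for \code{cv = "kfold"}.
#' @param seed integer seed (fold assignment).
#' @param gamma Gaussian kernel width; median heuristic when \code{NULL}.
#' @param class_rule "mahalanobis" (default), "centroid" or "argmax".
#' @param doses,classes triage mapping, see [triageMap()].
#' @return a \linkS4class{TriageResult}.
#' @export
triageEvaluate <- function(plasma_day, panel, n_osc = 1, ncomp = 2,
                           cv = c("loo", "kfold", "none"), folds = 7,
                           seed = 1, gamma = NULL,
                           class_rule = c("mahalanobis", "centroid",
                                          "argmax"),
                           doses = c(0, 10, 20, 35),
                           classes = c("Control", "Mild", "Moderate",
                                       "Severe")) {
  cv <- match.arg(cv)
  class_rule <- match.arg(class_rule)
  ids <- if (is(panel, "MarkerPanel")) panelMetabolites(panel) else panel
  d <- .study_matrix(plasma_day, ids)
  if (anyNA(d$X)) {  # multivariate models need complete cells
    for (j in seq_len(ncol(d$X)))
      d$X[is.na(d$X[, j]), j] <- mean(d$X[, j], na.rm = TRUE)
  }
  true_class <- triageMap(d$dose, doses, classes)
  n <- nrow(d$X)
  Yclass <- stats::model.matrix(~ 0 + true_class)
  colnames(Yclass) <- levels(true_class)

  fit_predict <- function(train, test) {
    sx <- scaleMatrix(d$X[train, , drop = FALSE], "uv")
    osc <- oscFilter(sx$X, Yclass[train, , drop = FALSE], n_osc)
    Xtr <- osc@X_filtered
    Xte <- oscApply(osc, .apply_scaling(d$X[test, , drop = FALSE],
                                        sx$center, sx$scale))
    mcls <- fitKPLS(Xtr, Yclass[train, , drop = FALSE], ncomp,
                    kernel = "gaussian", gamma = gamma, scale = "center")
    mdos <- fitKPLS(Xtr, d$dose[train], ncomp, kernel = "gaussian",
                    gamma = gamma, scale = "center")
    ## Xte is already on the training scale; predict() recenters only
    cls_train <- true_class[train]
    pred_cls <- if (class_rule == "argmax") {
      Yhat <- predict(mcls, Xte)
      levels(true_class)[max.col(Yhat, ties.method = "first")]
    } else {
      ## training centroids through the same cross-kernel projection as the
      ## test scores (the fitted deflation scores live in skewed coordinates)
      Ttr <- kplsScores(mcls, Xtr)
      Tte <- kplsScores(mcls, Xte)
      cent <- apply(Ttr, 2, function(col) tapply(col, cls_train, mean))
      Wi <- if (class_rule == "mahalanobis") {
        Wp <- Reduce(`+`, lapply(levels(cls_train), function(l) {
          Z <- Ttr[cls_train == l, , drop = FALSE]
          if (nrow(Z) < 2) return(matrix(0, ncol(Ttr), ncol(Ttr)))
          crossprod(sweep(Z, 2, colMeans(Z)))
        })) / (nrow(Ttr) - nlevels(cls_train))
        solve(Wp)
      } else diag(ncol(Ttr))
      vapply(seq_len(nrow(Tte)), function(i) {
        dists <- apply(cent, 1, function(cv) {
          dd <- Tte[i, ] - cv
          as.numeric(dd %*% Wi %*% dd)
        })
        rownames(cent)[which.min(dists)]
      }, character(1))
    }
    list(class = pred_cls, dose = as.vector(predict(mdos, Xte)))
  }

  pred_class <- character(n)
  pred_dose <- numeric(n)
  if (cv == "none") {
    r <- fit_predict(seq_len(n), seq_len(n))
    pred_class <- r$class
    pred_dose <- r$dose
    scheme <- "fitted"
  } else {
    fold <- if (cv == "loo") seq_len(n) else {
      old <- .save_rng()
      on.exit(.restore_rng(old))
      set.seed(seed)
      offset <- sample.int(folds, 1) - 1L
      ((seq_len(n) - 1L + offset) %% folds) + 1L
    }
    for (f in unique(fold)) {
      test <- fold == f
      if (all(test)) stop("cross-validation fold covers all samples")
      r <- fit_predict(which(!test), which(test))
      pred_class[test] <- r$class
      pred_dose[test] <- r$dose
    }
    scheme <- if (cv == "loo") "loo" else sprintf("%d-fold", folds)
  }
  pred_class <- factor(pred_class, levels = levels(true_class))
  confusion <- table(true = true_class, predicted = pred_class)
  confusion <- matrix(as.integer(confusion), nrow(confusion),
                      dimnames = dimnames(confusion))
  acc <- diag(confusion) / pmax(rowSums(confusion), 1L)
  dayv <- stats::na.omit(unique(plasma_day@samples$day[
    plasma_day@samples$role == "study"]))
  new("TriageResult",
      day = as.integer(dayv[1]),
      predictions = data.frame(sample_id = d$sample_id,
                               true_class = as.character(true_class),
                               predicted_class = as.character(pred_class),
                               predicted_dose_gy = pred_dose,
                               stringsAsFactors = FALSE),
      confusion = confusion, per_class_accuracy = acc,
      cv_scheme = scheme)
}

setMethod("show", "TriageResult", function(object) {
  cat("TriageResult: day", object@day, "(", object@cv_scheme, ")\n")
  print(object@confusion)
  cat("  per-class accuracy:",
      paste(sprintf("%s %.1f%%", names(object@per_class_accuracy),
                    100 * object@per_class_accuracy), collapse = ", "),
      "\n")
})

#' Ratio-to-control trajectories
#'
#' For each metabolite, irradiated dose group and day, divides the group's
#' mean level by the same-day control mean (ruling out time-related drift).
#' Summarizes per metabolite x dose: the earliest day flagged significant in
#' the per-day screens, whether the ratios change monotonically from day 2
#' onward (successive changes of constant, nonzero sign), and the direction
#' of the terminal response at that dose.
#'
#' @param plasma_by_day named list of \linkS4class{SampleTable} ("day<d>").
#' @param metabolites metabolite ids to trace (e.g. a panel).
#' @param diff_by_day optional named list of \linkS4class{DiffResult}
#'   matching \code{plasma_by_day}.
#' @return a \linkS4class{TrajectoryTable}.
#' @export
trajectories <- function(plasma_by_day, metabolites, diff_by_day = NULL) {
  if (length(plasma_by_day) < 2) stop("need >= 2 days")
  days <- as.integer(sub("^day", "", names(plasma_by_day)))
  rows <- list()
  for (i in seq_along(plasma_by_day)) {
    tb <- plasma_by_day[[i]]
    dg <- doseGroups(tb)
    ab <- tb@abundances
    ctrl <- colMeans(ab[match(dg[[1]], rownames(ab)), metabolites,
                        drop = FALSE], na.rm = TRUE)
    for (g in names(dg)[-1]) {
      m <- colMeans(ab[match(dg[[g]], rownames(ab)), metabolites,
                       drop = FALSE], na.rm = TRUE)
      ratio <- ifelse(ctrl > 0, m / ctrl, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite_id = metabolites,
        dose_gy = as.numeric(sub("dose_", "", g)),
        day = days[i], ratio_to_control = unname(ratio),
        stringsAsFactors = FALSE)
    }
  }
  ratios <- do.call(rbind, rows)

  first_sig <- rep(NA_integer_, length(metabolites))
  names(first_sig) <- metabolites
  if (!is.null(diff_by_day)) {
    dd <- as.integer(sub("^day", "", names(diff_by_day)))
    for (i in order(dd)) {
      sig <- significantMetabolites(diff_by_day[[i]])
      hit <- metabolites %in% sig & is.na(first_sig)
      first_sig[hit] <- dd[i]
    }
  }
  summ <- list()
  for (m in metabolites) {
    for (dose in unique(ratios$dose_gy)) {
      rr <- ratios[ratios$metabolite_id == m & ratios$dose_gy == dose, ]
      rr <- rr[order(rr$day), ]
      late <- rr$ratio_to_control[rr$day >= 2]
      dif <- diff(late[!is.na(late)])
      monotone <- length(dif) > 0 && all(dif != 0) &&
        (all(dif > 0) || all(dif < 0))
      term <- late[length(late)]
      direction <- if (is.na(term) || term == 1) 0L else
        if (term > 1) 1L else -1L
      summ[[length(summ) + 1L]] <- data.frame(
        metabolite_id = m, dose_gy = dose,
        first_significant_day = first_sig[m],
        monotone_2_to_5 = monotone, direction = direction,
        stringsAsFactors = FALSE)
    }
  }
  summ <- do.call(rbind, summ)
  rownames(summ) <- NULL
  new("TrajectoryTable", ratios = ratios, summary = summ)
}
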