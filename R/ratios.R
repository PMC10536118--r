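.find_chain <- function(table, chain) {
  mm <- table@metabolites
  hit <- which(!is.na(mm$acyl_chain) & mm$acyl_chain == chain)
  if (length(hit) != 1)
    stop("need exactly one metabolite with acyl_chain \"", chain, "\"")
  mm$metabolite_id[hit]
}

#' CPT1/CPT2 surrogate enzyme-activity ratios
#'
#' Per-sample carnitine-shuttle ratios from acylcarnitine channels:
#' \deqn{CPT1 = carnitine / (AC16{:}1 + AC18{:}0)}
#' \deqn{CPT2 = (AC16{:}0 + AC18{:}1) / AC2}
#' A missing constituent or zero denominator makes that sample's ratio
#' missing, with a note. Both ratios are invariant to any per-sample scaling
#' (the internal-standard normalization constant cancels).
#'
#' @param table a \linkS4class{SampleTable} containing metabolites with
#'   acyl_chain "carnitine", "C16:1", "C18:0", "C16:0", "C18:1" and "C2".
#' @return a \linkS4class{RatioResult} with the per-sample part filled;
#'   complete it with [ratioGroupTest()].
#' @export
cptRatios <- function(table) {
  stopifnot(is(table, "SampleTable"))
  chains <- c(carnitine = "carnitine", c16_1 = "C16:1", c18_0 = "C18:0",
              c16_0 = "C16:0", c18_1 = "C18:1", c2 = "C2")
  ids <- vapply(chains, function(ch) .find_chain(table, ch), character(1))
  sm <- table@samples
  study <- sm$role == "study"
  ab <- table@abundances[study, ids, drop = FALSE]
  colnames(ab) <- names(chains)
  den1 <- ab[, "c16_1"] + ab[, "c18_0"]
  cpt1 <- ab[, "carnitine"] / den1
  cpt1[!is.na(den1) & den1 == 0] <- NA_real_
  den2 <- ab[, "c2"]
  cpt2 <- (ab[, "c16_0"] + ab[, "c18_1"]) / den2
  cpt2[!is.na(den2) & den2 == 0] <- NA_real_
  notes <- character(0)
  if (anyNA(cpt1))
    notes <- c(notes, sprintf("cpt1 missing for %d sample(s)",
                              sum(is.na(cpt1))))
  if (anyNA(cpt2))
    notes <- c(notes, sprintf("cpt2 missing for %d sample(s)",
                              sum(is.na(cpt2))))
  new("RatioResult",
      per_sample = data.frame(sample_id = sm$sample_id[study],
                              dose_gy = sm$dose_gy[study],
                              cpt1 = unname(cpt1), cpt2 = unname(cpt2),
                              stringsAsFactors = FALSE),
      group_stats = data.frame(), kw_p = numeric(0),
      pairwise = data.frame(), notes = notes)
}

.star_mark <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
}

#' Group statistics for CPT ratios
#'
#' Medians and quartiles (linear-interpolation, type 7) per dose group,
#' tie-corrected Kruskal-Wallis across all groups, and pairwise Mann-Whitney
#' comparisons of each irradiated dose against control and against the
#' lowest irradiated dose, with the conventional star marks
#' (* p < 0.05, ** p < 0.01, *** p < 0.001; # p < 0.05 versus the lowest
#' irradiated dose). Groups with fewer than 3 non-missing ratios are
#' excluded with a note.
#'
#' @param ratios a \linkS4class{RatioResult} from [cptRatios()].
#' @return the completed \linkS4class{RatioResult}.
#' @export
ratioGroupTest <- function(ratios) {
  stopifnot(is(ratios, "RatioResult"))
  ps <- ratios@per_sample
  notes <- ratios@notes
  doses <- sort(unique(ps$dose_gy))
  gstats <- list(); kw <- c(cpt1 = NA_real_, cpt2 = NA_real_)
  pw <- list()
  for (ratio in c("cpt1", "cpt2")) {
    vals <- lapply(doses, function(d) {
      v <- ps[[ratio]][ps$dose_gy == d]
      v[!is.na(v)]
    })
    names(vals) <- doses
    small <- lengths(vals) < 3
    if (any(small)) {
      notes <- c(notes, sprintf("%s: group(s) %s excluded (n < 3)", ratio,
                                paste(doses[small], collapse = ", ")))
    }
    use <- vals[!small]
    used_doses <- doses[!small]
    if (length(use) >= 2) {
      kw[ratio] <- stats::kruskal.test(use)$p.value
    }
    for (i in seq_along(use)) {
      q <- stats::quantile(use[[i]], c(0.25, 0.5, 0.75), type = 7,
                           names = FALSE)
      gstats[[length(gstats) + 1L]] <- data.frame(
        ratio = ratio, dose_gy = used_doses[i], n = length(use[[i]]),
        median = q[2], q25 = q[1], q75 = q[3], stringsAsFactors = FALSE)
    }
    ctrl_dose <- used_doses[1]
    low_irr <- if (length(used_doses) >= 2) used_doses[2] else NA
    for (i in seq_along(use)[-1]) {
      p_ctrl <- mannWhitneyU(use[[i]], use[[1]])$p
      pw[[length(pw) + 1L]] <- data.frame(
        ratio = ratio, group = used_doses[i], reference = ctrl_dose,
        p = p_ctrl, mark = .star_mark(p_ctrl), stringsAsFactors = FALSE)
      if (!is.na(low_irr) && used_doses[i] > low_irr) {
        p_low <- mannWhitneyU(use[[i]], use[[2]])$p
        pw[[length(pw) + 1L]] <- data.frame(
          ratio = ratio, group = used_doses[i], reference = low_irr,
          p = p_low, mark = if (!is.na(p_low) && p_low < 0.05) "#" else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  new("RatioResult", per_sample = ps,
      group_stats = do.call(rbind, gstats),
      kw_p = kw,
      pairwise = if (length(pw)) do.call(rbind, pw) else data.frame(),
      notes = notes)
}

setMethod("show", "RatioResult", function(object) {
  cat("RatioResult:", nrow(object@per_sample), "samples\n")
  if (nrow(object@group_stats)) {
    gs <- object@group_stats
    for (ratio in unique(gs$ratio)) {
      g <- gs[gs$ratio == ratio, ]
      cat(sprintf("  %s (KW p = %.3g): %s\n", toupper(ratio),
                  object@kw_p[ratio],
                  paste(sprintf("%g Gy %.3g (%.3g-%.3g)", g$dose_gy,
                                g$median, g$q25, g$q75), collapse = "; ")))
    }
  }
})

#' Table-2-shaped CSV of CPT ratio statistics
#'
#' Rows CPT1/CPT2, one column per dose group with cells
#' "median (q25-q75) marks".
#'
#' @param ratios a completed \linkS4class{RatioResult}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeRatioTable <- function(ratios, path) {
  stopifnot(is(ratios, "RatioResult"))
  gs <- ratios@group_stats
  if (!nrow(gs)) stop("run ratioGroupTest first")
  pw <- ratios@pairwise
  doses <- sort(unique(gs$dose_gy))
  rows <- lapply(c("cpt1", "cpt2"), function(ratio) {
    cells <- vapply(doses, function(d) {
      g <- gs[gs$ratio == ratio & gs$dose_gy == d, ]
      if (!nrow(g)) return(NA_character_)
      marks <- paste0(pw$mark[pw$ratio == ratio & pw$group == d],
                      collapse = "")
      sprintf("%.4g %s(%.4g-%.4g)", g$median, marks, g$q25, g$q75)
    }, character(1))
    c(toupper(ratio), cells)
  })
  dt <- data.table::as.data.table(do.call(rbind, rows))
  data.table::setnames(dt, c("Enzymes", paste0(doses, " Gy")))
  data.table::fwrite(dt, path)
  invisible(path)
}
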