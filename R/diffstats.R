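## Exact null distribution of the signed-rank statistic over doubled
## midranks (handles ties); returns P(T <= w) for the given weights.
.signed_rank_cdf <- function(ranks2, w2) {
  ## polynomial DP over prod_i (1 + z^{r_i}) / 2^n
  total <- sum(ranks2)
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), pmf[seq_len(total + 1L - r)])
    pmf <- pmf + shifted
  }
  pmf <- pmf / 2^length(ranks2)
  cum <- cumsum(pmf)
  idx <- min(max(floor(w2), 0), total)
  cum[idx + 1L]
}

#' Two-tailed Wilcoxon signed-rank test
#'
#' Paired test on the differences \code{x - y}. Zero differences are dropped
#' (Wilcoxon convention); |differences| are midranked. The null distribution
#' is exact (full sign enumeration via a convolution over doubled midranks,
#' ties supported) for n <= 25 retained pairs, and a normal approximation
#' with tie correction and continuity correction beyond that. W is the sum
#' of ranks of positive differences.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with elements \code{W}, \code{p} and \code{n} (retained
#'   pairs).
#' @export
wilcoxonSignedRank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate pairing: all differences zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    lo <- .signed_rank_cdf(r2, 2 * W)          # P(T <= W)
    hi <- 1 - .signed_rank_cdf(r2, 2 * W - 1)  # P(T >= W)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    if (W == mu) z <- 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(W = W, p = p, n = n)
}

#' Two-tailed Mann-Whitney U test
#'
#' Independent two-group rank-sum test. U counts pairs (a_i, b_j) with
#' a_i > b_j plus half the ties. The null distribution is exact (no ties,
#' total n <= 20, via the rank-sum counting distribution) and a normal
#' approximation with midrank tie correction and continuity correction
#' otherwise.
#'
#' @param a,b numeric vectors (each nonempty).
#' @return list with elements \code{U} and \code{p}.
#' @export
mannWhitneyU <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  m <- length(a); n <- length(b)
  if (m == 0 || n == 0) stop("empty group")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (!has_ties && (m + n) <= 20) {
    lo <- stats::pwilcox(U, m, n)
    hi <- 1 - stats::pwilcox(U - 1, m, n)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- m * n / 2
    ties <- table(r)
    N <- m + n
    sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (abs(U - mu) - 0.5)
    z <- max(z, 0) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(U = U, p = p)
}

#' Classical one-way fixed-effects ANOVA
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2 after
#'   removing NA).
#' @return list with \code{F} and \code{p} ((k-1, N-k) degrees of freedom);
#'   zero within-group variance with unequal means yields \code{F = Inf},
#'   \code{p = 0}.
#' @export
anovaOneway <- function(groups) {
  groups <- lapply(groups, function(v) v[!is.na(v)])
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  N <- sum(lengths(groups))
  gm <- vapply(groups, mean, numeric(1))
  grand <- sum(vapply(groups, sum, numeric(1))) / N
  ssb <- sum(lengths(groups) * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw == 0) {
    if (ssb > 0) return(list(F = Inf, p = 0))
    return(list(F = NaN, p = 1))
  }
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return the BH-adjusted q-values (monotone in p-rank, capped at 1).
#' @export
bhFDR <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group samples of a table by dose
#'
#' @param table a \linkS4class{SampleTable}.
#' @return named list of study sample ids, one element per dose level
#'   (ascending; the control dose first).
#' @export
doseGroups <- function(table) {
  sm <- table@samples
  study <- sm[sm$role == "study", , drop = FALSE]
  doses <- sort(unique(study$dose_gy))
  out <- lapply(doses, function(d) study$sample_id[study$dose_gy == d])
  names(out) <- paste0("dose_", doses)
  out
}

#' Per-metabolite differential screen with BH control
#'
#' Applies the chosen test metabolite-wise across the design's groups and
#' adjusts the resulting p-values by Benjamini-Hochberg within this contrast
#' (one BH family per call). A metabolite is significant iff \code{p < alpha}
#' and \code{q < fdr_max}. The log2 fold change compares the pooled
#' non-reference group mean with the reference (control) group mean, missing
#' values excluded. Metabolites with fewer than 3 observations in any group
#' are excluded from testing (and from the BH family) with a note.
#'
#' @param table a filtered, normalized \linkS4class{SampleTable}.
#' @param design named list of sample-id vectors, the reference group first.
#'   \code{NULL} builds dose groups via [doseGroups()] (for
#'   \code{test = "mann_whitney"}, control versus all irradiated pooled).
#' @param test "mann_whitney" (independent two-group), "wilcoxon_paired"
#'   (two groups matched by animal id) or "anova" (all groups).
#' @param alpha,fdr_max significance thresholds (defaults 0.05 and 0.2).
#' @return a \linkS4class{DiffResult}.
#' @export
differentialScreen <- function(table, design = NULL,
                               test = c("mann_whitney", "wilcoxon_paired",
                                        "anova"),
                               alpha = 0.05, fdr_max = 0.2) {
  stopifnot(is(table, "SampleTable"))
  test <- match.arg(test)
  sm <- table@samples
  if (is.null(design)) {
    dg <- doseGroups(table)
    design <- if (test == "anova") dg else
      list(control = dg[[1]], irradiated = unlist(dg[-1], use.names = FALSE))
  }
  if (length(design) < 2 || any(lengths(design) == 0))
    stop("design must resolve to >= 2 nonempty groups")
  if (test %in% c("mann_whitney", "wilcoxon_paired") && length(design) != 2)
    stop("two-group test requires exactly 2 design groups")
  is_col <- table@metabolites$chem_class == "internal_standard"
  mets <- table@metabolites$metabolite_id[!is_col]
  ab <- table@abundances
  idx <- lapply(design, function(ids) match(ids, rownames(ab)))
  if (anyNA(unlist(idx))) stop("design contains unknown sample ids")

  stat <- p <- log2fc <- rep(NA_real_, length(mets))
  note <- rep("", length(mets))
  for (k in seq_along(mets)) {
    vals <- lapply(idx, function(i) ab[i, mets[k]])
    nn <- vapply(vals, function(v) sum(!is.na(v)), integer(1))
    if (any(nn < 3)) {
      note[k] <- "excluded: < 3 observations in a group"
      next
    }
    res <- switch(test,
      mann_whitney = {
        r <- mannWhitneyU(vals[[2]], vals[[1]])
        list(stat = r$U, p = r$p)
      },
      wilcoxon_paired = {
        a1 <- sm$animal_id[idx[[1]]]
        a2 <- sm$animal_id[idx[[2]]]
        common <- intersect(a1, a2)
        v1 <- vals[[1]][match(common, a1)]
        v2 <- vals[[2]][match(common, a2)]
        ok <- !is.na(v1) & !is.na(v2)
        if (sum(ok) < 3) {
          note[k] <- "excluded: < 3 complete pairs"
          NULL
        } else {
          r <- tryCatch(wilcoxonSignedRank(v2[ok], v1[ok]),
                        error = function(e) NULL)
          if (is.null(r)) {
            note[k] <- "excluded: degenerate pairing"
            NULL
          } else list(stat = r$W, p = r$p)
        }
      },
      anova = {
        r <- anovaOneway(vals)
        list(stat = r$F, p = r$p)
      })
    if (is.null(res)) next
    stat[k] <- res$stat
    p[k] <- res$p
    ref_mean <- mean(vals[[1]], na.rm = TRUE)
    other_mean <- mean(unlist(vals[-1]), na.rm = TRUE)
    log2fc[k] <- if (ref_mean > 0 && other_mean > 0)
      log2(other_mean / ref_mean) else NA_real_
  }
  q <- rep(NA_real_, length(mets))
  tested <- !is.na(p)
  if (any(tested)) q[tested] <- bhFDR(p[tested])
  significant <- !is.na(p) & p < alpha & !is.na(q) & q < fdr_max
  tiss <- paste(unique(sm$tissue), collapse = "/")
  dys <- paste(sort(unique(sm$day[sm$role == "study"])), collapse = ",")
  new("DiffResult",
      contrast = sprintf("%s day %s: %s over %d groups", tiss, dys, test,
                         length(design)),
      test = test, alpha = alpha, fdr_max = fdr_max,
      table = data.frame(metabolite_id = mets, statistic = stat, p = p,
                         q = q, log2fc = log2fc, significant = significant,
                         note = note, stringsAsFactors = FALSE))
}

#' Significant metabolites of a DiffResult
#' @param diff a \linkS4class{DiffResult}.
#' @return character vector of significant metabolite ids.
#' @export
significantMetabolites <- function(diff) {
  stopifnot(is(diff, "DiffResult"))
  diff@table$metabolite_id[diff@table$significant]
}

setMethod("show", "DiffResult", function(object) {
  cat("DiffResult:", object@contrast, "\n")
  cat("  ", sum(object@table$significant), "significant of",
      sum(!is.na(object@table$p)), "tested (p <", object@alpha, ", q <",
      object@fdr_max, ")\n")
})

#' Hierarchically clustered fold-change zones
#'
#' Computes per-dose log2 fold changes (each irradiated dose group versus
#' control) for the significant metabolites of a screen, clusters the
#' fold-change rows (Euclidean distance, average linkage) and cuts the
#' dendrogram into \code{k} zones labelled "a", "b", "c", ... in dendrogram
#' order. Output ordering is deterministic.
#'
#' @param diff a \linkS4class{DiffResult} over \code{table}.
#' @param table the \linkS4class{SampleTable} the screen was run on.
#' @param k number of zones (default 3).
#' @return a \linkS4class{HeatmapZones}.
#' @export
heatmapZones <- function(diff, table, k = 3) {
  stopifnot(is(diff, "DiffResult"), is(table, "SampleTable"))
  sig <- significantMetabolites(diff)
  if (length(sig) < k)
    stop("k exceeds the number of significant metabolites")
  dg <- doseGroups(table)
  ab <- table@abundances
  ctrl <- colMeans(ab[match(dg[[1]], rownames(ab)), sig, drop = FALSE],
                   na.rm = TRUE)
  fc <- vapply(dg[-1], function(ids) {
    m <- colMeans(ab[match(ids, rownames(ab)), sig, drop = FALSE],
                  na.rm = TRUE)
    log2(m / ctrl)
  }, numeric(length(sig)))
  fc <- matrix(fc, nrow = length(sig),
               dimnames = list(sig, names(dg)[-1]))
  hc <- stats::hclust(stats::dist(fc, method = "euclidean"),
                      method = "average")
  cl <- stats::cutree(hc, k = k)
  ord <- hc$order
  ## zones labelled in dendrogram order of first appearance
  first_seen <- unique(cl[ord])
  zone <- letters[match(cl, first_seen)]
  names(zone) <- sig
  new("HeatmapZones", log2fc_matrix = fc,
      metabolite_order = rownames(fc)[ord], zone_labels = zone)
}
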