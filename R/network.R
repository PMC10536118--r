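#' Metabolite Pearson correlation network
#'
#' Computes pairwise Pearson correlations on pairwise-complete observations
#' within one sample stratum and connects metabolite pairs with
#' \code{|r| >= r_min} and two-sided \code{p < alpha} (t distribution on
#' n - 2 df). Although the thresholding convention is often quoted as
#' "r >= 0.7", negative edges are real and are kept: the rule applies to
#' |r|, and each edge carries its sign. Metabolites with fewer than 4
#' complete observations are excluded with a note; pairs with fewer than 4
#' complete pairs are skipped.
#'
#' @param table a \linkS4class{SampleTable}.
#' @param group named list selecting study samples by metadata equality,
#'   e.g. \code{list(dose_gy = 35, day = 5)}; \code{NULL} uses all study
#'   samples.
#' @param metabolites metabolite ids to include; \code{NULL} = all non-IS.
#' @param r_min correlation threshold on |r| (default 0.7).
#' @param alpha p-value threshold (default 0.05).
#' @param diff optional \linkS4class{DiffResult} used to annotate nodes
#'   up/down/ns.
#' @return a \linkS4class{CorrelationNetwork}; edges are undirected, stored
#'   once with m1 < m2 lexically.
#' @export
correlationNetwork <- function(table, group = NULL, metabolites = NULL,
                               r_min = 0.7, alpha = 0.05, diff = NULL) {
  stopifnot(is(table, "SampleTable"))
  sm <- table@samples
  sel <- sm$role == "study"
  if (!is.null(group)) {
    for (nm in names(group)) sel <- sel & !is.na(sm[[nm]]) &
        sm[[nm]] == group[[nm]]
  }
  if (sum(sel) < 4) stop("fewer than 4 samples in the selected group")
  if (is.null(metabolites))
    metabolites <- table@metabolites$metabolite_id[
      table@metabolites$chem_class != "internal_standard"]
  if (length(metabolites) < 2) stop("need >= 2 metabolites")
  X <- table@abundances[sel, metabolites, drop = FALSE]
  n_ok <- colSums(!is.na(X))
  excluded <- metabolites[n_ok < 4]
  if (length(excluded))
    message("excluded (fewer than 4 complete observations): ",
            paste(excluded, collapse = ", "))
  keep <- metabolites[n_ok >= 4]
  X <- X[, keep, drop = FALSE]

  edges <- list()
  if (length(keep) >= 2) {
    for (i in seq_len(length(keep) - 1)) {
      for (j in seq((i + 1), length(keep))) {
        ok <- !is.na(X[, i]) & !is.na(X[, j])
        nn <- sum(ok)
        if (nn < 4) next
        r <- stats::cor(X[ok, i], X[ok, j])
        if (is.na(r)) next
        p <- if (abs(r) >= 1) 0 else {
          tv <- r * sqrt((nn - 2) / (1 - r^2))
          2 * stats::pt(-abs(tv), nn - 2)
        }
        if (abs(r) >= r_min && p < alpha) {
          pair <- sort(c(keep[i], keep[j]))
          edges[[length(edges) + 1L]] <- data.frame(
            m1 = pair[1], m2 = pair[2], r = r, p = p,
            sign = if (r >= 0) "+" else "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(m1 = character(0), m2 = character(0), r = numeric(0),
               p = numeric(0), sign = character(0),
               stringsAsFactors = FALSE)
  edges <- edges[order(edges$m1, edges$m2), , drop = FALSE]
  rownames(edges) <- NULL

  direction <- rep("ns", length(keep))
  if (!is.null(diff)) {
    dt <- diff@table
    ix <- match(keep, dt$metabolite_id)
    hit <- !is.na(ix) & dt$significant[ix]
    direction[hit] <- ifelse(dt$log2fc[ix[hit]] > 0, "up", "down")
  }
  grp <- if (is.null(group)) "all study samples" else
    paste(names(group), unlist(group), sep = "=", collapse = ", ")
  new("CorrelationNetwork", group = grp,
      nodes = data.frame(metabolite_id = keep, direction = direction,
                         stringsAsFactors = FALSE),
      edges = edges, r_min = r_min, alpha = alpha)
}

#' Degree statistics of a correlation network
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @return list with \code{degree} (named integer over all nodes, isolated
#'   nodes at 0), \code{n_edges}, \code{n_positive}, \code{n_negative}.
#' @export
degreeStats <- function(net) {
  stopifnot(is(net, "CorrelationNetwork"))
  deg <- table(factor(c(net@edges$m1, net@edges$m2),
                      levels = net@nodes$metabolite_id))
  list(degree = stats::setNames(as.integer(deg), names(deg)),
       n_edges = nrow(net@edges),
       n_positive = sum(net@edges$sign == "+"),
       n_negative = sum(net@edges$sign == "-"))
}

setMethod("show", "CorrelationNetwork", function(object) {
  ds <- degreeStats(object)
  cat("CorrelationNetwork [", object@group, "]: ", nrow(object@nodes),
      " nodes, ", ds$n_edges, " edges (", ds$n_positive, " +, ",
      ds$n_negative, " -) at |r| >= ", object@r_min, ", p < ",
      object@alpha, "\n", sep = "")
})

#' Export a correlation network
#'
#' SIF: one \code{m1 pos|neg m2} line per edge, isolated nodes as bare
#' lines (Cytoscape convention). GraphML: via igraph, edges carrying r, p
#' and sign, nodes carrying the direction annotation. Output ordering is
#' bit-stable.
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @param path output file.
#' @param format "sif" or "graphml".
#' @return invisibly, \code{path}.
#' @export
exportNetwork <- function(net, path, format = c("sif", "graphml")) {
  stopifnot(is(net, "CorrelationNetwork"))
  format <- match.arg(format)
  if (format == "sif") {
    e <- net@edges
    lines <- sprintf("%s\t%s\t%s", e$m1,
                     ifelse(e$sign == "+", "pos", "neg"), e$m2)
    isolated <- setdiff(net@nodes$metabolite_id, c(e$m1, e$m2))
    writeLines(c(lines, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(
      net@edges[, c("m1", "m2", "r", "p", "sign"), drop = FALSE],
      directed = FALSE,
      vertices = net@nodes[, c("metabolite_id", "direction"), drop = FALSE])
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
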