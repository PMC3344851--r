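# Automatic network-component selection.
#
# For every ICA component, the mean time course of each of the 14 target and
# 6 anticorrelated ROIs is regressed on all component courses; a connectivity
# graph connects every pair of target ROIs whose regression T passes a
# Bonferroni-corrected threshold (clique rule), once for T > T_th (graphs
# 1..n) and once for T < -T_th (graphs n+1..2n) to absorb the ICA sign
# indeterminacy.  Each graph's edge count E is weighted by the fraction w of
# anti ROIs expressed with opposite sign (near 0 for the global component)
# and by the fingerprint weight w_F; the graph maximizing
# score = E * w * w_F selects the network component.

#' Mean ROI time courses
#'
#' @param run a preprocessed \code{\link{bold_run}}.
#' @param rois a \code{\link{derive_rois}} result.
#' @return t x 20 matrix; columns are the unweighted voxel means of the 14
#'   target ROIs followed by the 6 anti ROIs.
#' @export
roi_timecourses <- function(run, rois) {
  d <- dim(run$data)
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  one <- function(m, nm) {
    lin <- m[, 1] + (m[, 2] - 1) * d[1] + (m[, 3] - 1) * d[1] * d[2]
    .assert(all(run$mask[lin]), "ROI %s has voxels outside the mask", nm)
    colMeans(flat[lin, , drop = FALSE])
  }
  allr <- c(rois$targets, rois$anti)
  out <- vapply(names(allr), function(nm) one(allr[[nm]], nm), numeric(d[4]))
  colnames(out) <- names(allr)
  out
}

#' Regress ROI courses on all component time courses
#'
#' Ordinary least squares of each ROI mean course on an intercept plus the
#' component courses; per-coefficient t statistics with
#' dof = n_volumes - n_components - 1.
#'
#' @param roi_tc t x n_rois matrix from \code{\link{roi_timecourses}}.
#' @param courses t x n_components matrix of ICA time courses.
#' @return object of class \code{roi_regression}: \code{betas} and
#'   \code{tvalues} (n_rois x n_components), \code{dof}, \code{roi_order}.
#' @export
regress_components <- function(roi_tc, courses) {
  nt <- nrow(roi_tc)
  nc <- ncol(courses)
  .assert(nrow(courses) == nt, "roi_tc and courses disagree on the number of volumes")
  dof <- nt - nc - 1L
  .assert(dof > 0, "not enough volumes (%d) for %d regressors", nt, nc)
  X <- cbind(1, courses)
  qx <- qr(X)
  .assert(qx$rank == ncol(X), "rank-deficient design: collinear component courses (columns %s)",
          paste(setdiff(seq_len(ncol(X)), qx$pivot[seq_len(qx$rank)]) - 1L, collapse = ","))
  B <- qr.coef(qx, roi_tc)                    # (nc+1) x n_rois
  res <- roi_tc - X %*% B
  sigma2 <- colSums(res^2) / dof
  XtXinv <- chol2inv(qr.R(qx))
  se <- sqrt(outer(diag(XtXinv), sigma2))     # (nc+1) x n_rois
  tv <- B / se
  structure(list(betas = t(B[-1, , drop = FALSE]),
                 tvalues = t(tv[-1, , drop = FALSE]),
                 dof = as.integer(dof),
                 roi_order = colnames(roi_tc)), class = "roi_regression")
}

#' Number of possible edges among n nodes
#'
#' @param n node count (\eqn{\ge} 2).
#' @return n(n-1)/2; e.g. 91 for the 14 target ROIs.
#' @export
n_possible_edges <- function(n) {
  .assert(is.numeric(n) && n >= 2, "need at least 2 nodes")
  n * (n - 1) / 2
}

#' Bonferroni-corrected edge threshold on T
#'
#' Upper-tail t quantile at probability 1 - alpha / (n(n-1)/2) with the given
#' degrees of freedom: the per-edge threshold controlling the family of all
#' possible target-ROI edges at level alpha.
#'
#' @param alpha familywise error level (default 0.05).
#' @param n_nodes number of target ROIs (default 14, giving 91 comparisons).
#' @param dof regression degrees of freedom.
#' @return scalar T threshold.
#' @export
edge_threshold <- function(alpha = 0.05, n_nodes = 14, dof) {
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  .assert(dof > 0, "dof must be positive")
  stats::qt(1 - alpha / n_possible_edges(n_nodes), df = dof)
}

#' Build the per-component connectivity graphs
#'
#' For component c and sign s, the graph's nodes are the target ROIs whose
#' regression T satisfies T > T_th (s = +) or T < -T_th (s = -); edges join
#' every pair of such nodes.  Graphs are indexed 1..n (positive) and
#' n+1..2n (negative).
#'
#' @param reg a \code{\link{regress_components}} result.
#' @param T_th positive edge threshold from \code{\link{edge_threshold}}.
#' @param n_targets number of leading ROIs in \code{reg} that are targets.
#' @return list of \code{connectivity_graph} objects with fields
#'   \code{component}, \code{graph_index}, \code{sign}, \code{nodes},
#'   \code{edges} (2-column matrix), \code{E}.
#' @export
build_graphs <- function(reg, T_th, n_targets = 14) {
  .assert(T_th > 0, "T_th must be positive")
  tv <- reg$tvalues[seq_len(n_targets), , drop = FALSE]
  ncomp <- ncol(tv)
  nodes_all <- reg$roi_order[seq_len(n_targets)]
  one <- function(comp, sgn) {
    pass <- if (sgn > 0) tv[, comp] > T_th else tv[, comp] < -T_th
    nodes <- nodes_all[pass]
    k <- length(nodes)
    edges <- if (k >= 2) t(utils::combn(nodes, 2)) else matrix(character(0), 0, 2)
    structure(list(component = comp,
                   graph_index = if (sgn > 0) comp else ncomp + comp,
                   sign = if (sgn > 0) "positive" else "negative",
                   nodes = nodes, edges = edges, E = k * (k - 1) / 2),
              class = "connectivity_graph")
  }
  c(lapply(seq_len(ncomp), one, sgn = +1), lapply(seq_len(ncomp), one, sgn = -1))
}

#' Anticorrelation weight of one graph
#'
#' Fraction of the anti ROIs whose regression T has the sign opposite to the
#' graph's sign condition; near 0 for the global component (all ROIs
#' positively expressed), 1 for a fully anticorrelated set.
#'
#' @param reg a \code{\link{regress_components}} result.
#' @param component component index.
#' @param sign \code{"positive"} or \code{"negative"} graph condition.
#' @param n_targets number of leading target ROIs in \code{reg}.
#' @return scalar in \{0, 1/6, ..., 1\} (for 6 anti ROIs).
#' @export
anticorrelation_weight <- function(reg, component, sign = c("positive", "negative"),
                                   n_targets = 14) {
  sign <- match.arg(sign)
  .assert(component >= 1 && component <= ncol(reg$tvalues), "component out of range")
  anti_t <- reg$tvalues[-seq_len(n_targets), component]
  if (!length(anti_t)) return(0)
  opposite <- if (sign == "positive") anti_t < 0 else anti_t > 0
  mean(opposite)
}

#' Score all graphs and select the network component
#'
#' score = E x w x w_F per graph; the graph with the maximal score selects the
#' network component.  Ties break toward higher E, then lower graph index.
#' If every score is zero the result is flagged and no component is picked.
#'
#' @param reg a \code{\link{regress_components}} result.
#' @param graphs list from \code{\link{build_graphs}}.
#' @param fps list of \code{\link{fingerprint}} objects, one per component.
#' @param ref a \code{\link{reference_fingerprint}}.
#' @param n_targets number of leading target ROIs in \code{reg}.
#' @return object of class \code{selection_result}: \code{scores} data.frame
#'   (graph_index, component, sign, E, w, w_F, score, selected),
#'   \code{selected} (component index or NA), \code{selected_graph},
#'   \code{no_network_found}.
#' @export
score_and_select <- function(reg, graphs, fps, ref, n_targets = 14) {
  .assert(length(fps) == ncol(reg$tvalues),
          "need one fingerprint per component")
  wF <- vapply(fps, fingerprint_weight, 0, ref = ref)
  rows <- lapply(graphs, function(g) {
    w <- anticorrelation_weight(reg, g$component, g$sign, n_targets)
    data.frame(graph_index = g$graph_index, component = g$component,
               sign = g$sign, E = g$E, w = w, w_F = wF[g$component],
               score = g$E * w * wF[g$component], stringsAsFactors = FALSE)
  })
  sc <- do.call(rbind, rows)
  sc <- sc[order(sc$graph_index), ]
  no_network <- all(sc$score == 0)
  sel_graph <- if (no_network) NA_integer_ else {
    ord <- order(-sc$score, -sc$E, sc$graph_index)
    sc$graph_index[ord[1]]
  }
  sc$selected <- !is.na(sel_graph) & sc$graph_index == sel_graph
  structure(list(scores = sc,
                 selected = if (no_network) NA_integer_
                            else sc$component[sc$selected],
                 selected_graph = sel_graph,
                 no_network_found = no_network,
                 threshold = attr(graphs, "T_th")), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$no_network_found) {
    cat("<selection_result> no network found (all scores zero)\n")
  } else {
    s <- x$scores[x$scores$selected, ]
    cat(sprintf("<selection_result> component %d (%s graph %d): E=%g, w=%.3f, w_F=%.3f, score=%.2f\n",
                x$selected, s$sign, s$graph_index, s$E, s$w, s$w_F, s$score))
  }
  invisible(x)
}

#' Run the full selection chain on one decomposition
#'
#' Convenience wrapper: ROI time courses, component regression, edge
#' threshold, dual-sign graphs, fingerprints and the anticorrelation-corrected
#' score in one call.
#'
#' @param run the preprocessed \code{\link{bold_run}} used for the ICA.
#' @param dec its \code{\link{spatial_ica}} decomposition.
#' @param rois a \code{\link{derive_rois}} result.
#' @param ref a \code{\link{reference_fingerprint}}.
#' @param alpha familywise level for the edge threshold (default 0.05).
#' @return a \code{selection_result}; its \code{regression} and
#'   \code{fingerprints} attributes carry the intermediates.
#' @export
select_network_component <- function(run, dec, rois, ref, alpha = 0.05) {
  tc <- roi_timecourses(run, rois)
  reg <- regress_components(tc, dec$courses)
  T_th <- edge_threshold(alpha, n_nodes = length(rois$targets), dof = reg$dof)
  graphs <- build_graphs(reg, T_th, n_targets = length(rois$targets))
  attr(graphs, "T_th") <- T_th
  fps <- lapply(seq_len(dec$n_components), function(k)
    fingerprint(dec$maps[, , , k], dec$courses[, k], dec$tr_seconds, mask = dec$mask))
  res <- score_and_select(reg, graphs, fps, ref, n_targets = length(rois$targets))
  res$threshold <- T_th
  attr(res, "regression") <- reg
  attr(res, "fingerprints") <- fps
  res
}

#' Write a selection report TSV
#'
#' @param result a \code{selection_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_selection_tsv <- function(result, path) {
  utils::write.table(result$scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
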