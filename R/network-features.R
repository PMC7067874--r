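#' Drop low-confidence interactions
#'
#' Retains exactly the edges with confidence `>= min_score` (the method removes
#' scores strictly below 0.4 by default). The node list is unchanged, so nodes
#' isolated by the filter are kept.
#'
#' @param net An [interaction_network()].
#' @param min_score Minimum retained confidence, in \[0,1\] (default 0.4).
#' @return A filtered [interaction_network()].
#' @export
filter_edges <- function(net, min_score = 0.4) {
  stopifnot(inherits(net, "interaction_network"),
            min_score >= 0, min_score <= 1)
  edges <- filter(net$edges, .data$score >= min_score)
  if (nrow(edges) == 0) {
    abort(sprintf("no edge has score >= %s", format(min_score)))
  }
  interaction_network(edges, nodes = net$nodes)
}

# internal: igraph object over the full node set, lexicographic vertex order
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b", "score")],
    directed = FALSE,
    vertices = sort(net$nodes)
  )
}

#' All-pairs shortest-path (hop count) matrix
#'
#' Unweighted breadth-first hop distances between all node pairs of the
#' network; each entry is the minimum number of steps needed to traverse the
#' graph between two genes. Unreachable pairs (including isolated nodes) are
#' imputed with `max finite off-diagonal distance + 1` so the feature stays
#' finite and ordinally "farther than anything observed", unless an explicit
#' `sentinel` is supplied.
#'
#' @param net An [interaction_network()] with at least one edge.
#' @param sentinel Optional numeric override for the unreachable-pair value.
#' @return Numeric symmetric matrix with zero diagonal, rows/columns ordered by
#'   gene identifier; attribute `"imputed_value"` records the fill-in used (NA
#'   when all pairs were reachable).
#' @export
shortest_path_matrix <- function(net, sentinel = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$edges) == 0) abort("network has no edges")
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = NA)
  imputed <- NA_real_
  if (any(is.infinite(d))) {
    finite_off <- d[is.finite(d) & d > 0]
    imputed <- if (is.null(sentinel)) max(finite_off) + 1 else sentinel
    d[is.infinite(d)] <- imputed
  }
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  attr(d, "imputed_value") <- imputed
  d
}
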