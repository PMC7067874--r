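#' Size-constrained iterative greedy-modularity clustering
#'
#' Clusters the induced subgraph on a gene subset (typically the top score
#' decile) by greedy agglomerative modularity optimization (Clauset-Newman-
#' Moore), with edge confidences as weights by default and no confidence filter
#' applied. Clustering is iterative: any cluster larger than `max_size` is
#' re-clustered on its own induced subgraph (depth-first) until it splits no
#' further — an unsplittable oversized cluster is retained and logged. Clusters
#' smaller than `min_size` are discarded. Vertices are processed in
#' lexicographic gene order so results are deterministic.
#'
#' @param net An [interaction_network()] (unfiltered confidences).
#' @param genes Gene subset to cluster (must intersect the network's nodes).
#' @param max_size Clusters larger than this are re-clustered (default 200).
#' @param min_size Clusters smaller than this are discarded (default 30).
#' @param weighted Use edge confidences as modularity weights (default TRUE).
#' @return An object of class `cluster_set`: `membership` (tibble `gene`,
#'   `cluster`), `clusters` (tibble `cluster`, `size`, `unsplittable`),
#'   `discarded` (tibble `gene`, `reason`).
#' @export
iterative_modularity_clusters <- function(net, genes, max_size = 200,
                                          min_size = 30, weighted = TRUE) {
  stopifnot(inherits(net, "interaction_network"), max_size >= min_size)
  genes <- sort(unique(intersect(genes, net$nodes)))
  if (length(genes) == 0) abort("induced subgraph is empty")
  edges <- filter(net$edges, .data$gene_a %in% genes & .data$gene_b %in% genes)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)

  split_community <- function(vs) {
    # returns list of character vectors (leaf clusters) for the vertex set vs
    sub <- igraph::induced_subgraph(g, vs)
    w <- if (weighted) igraph::E(sub)$score else NULL
    memb <- if (igraph::ecount(sub) == 0) {
      rep(1L, igraph::vcount(sub))
    } else {
      igraph::membership(igraph::cluster_fast_greedy(sub, weights = w))
    }
    groups <- split(igraph::V(sub)$name, memb)
    if (length(groups) == 1) {
      # no split found: retain as-is (flagged unsplittable if oversized)
      attr(groups[[1]], "unsplittable") <- length(groups[[1]]) > max_size
      return(groups)
    }
    out <- list()
    for (grp in groups) {
      if (length(grp) > max_size) {
        out <- c(out, split_community(grp))
      } else {
        out <- c(out, list(grp))
      }
    }
    out
  }

  leaves <- split_community(genes)
  # deterministic ids: order clusters by lexicographically smallest member
  leaves <- leaves[order(vapply(leaves, min, character(1)))]
  keep <- vapply(leaves, length, integer(1)) >= min_size
  discarded <- bind_rows(purrr::map(leaves[!keep], function(grp) {
    tibble(gene = sort(grp), reason = sprintf("cluster of size %d < %d",
                                              length(grp), min_size))
  }))
  if (nrow(discarded) == 0) discarded <- tibble(gene = character(0), reason = character(0))
  leaves <- leaves[keep]
  unsplit <- vapply(leaves, function(grp) isTRUE(attr(grp, "unsplittable")),
                    logical(1))
  if (any(unsplit)) {
    warn(sprintf("%d oversized cluster(s) could not be split further and were retained",
                 sum(unsplit)))
  }
  membership <- bind_rows(purrr::imap(leaves, function(grp, i) {
    tibble(gene = sort(grp), cluster = as.integer(i))
  }))
  if (nrow(membership) == 0) membership <- tibble(gene = character(0), cluster = integer(0))
  clusters <- tibble(
    cluster = seq_along(leaves),
    size = unname(vapply(leaves, length, integer(1))),
    unsplittable = unname(unsplit)
  )
  structure(
    list(membership = membership, clusters = clusters, discarded = discarded,
         params = list(max_size = max_size, min_size = min_size,
                       weighted = weighted)),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters, %d genes retained, %d discarded\n",
              nrow(x$clusters), nrow(x$membership), nrow(x$discarded)))
  invisible(x)
}

#' @rdname iterative_modularity_clusters
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @export
tidy.cluster_set <- function(x, ...) x$membership

#' @rdname iterative_modularity_clusters
#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_clusters = nrow(x$clusters),
         n_genes = nrow(x$membership),
         n_discarded = nrow(x$discarded),
         largest = if (nrow(x$clusters)) max(x$clusters$size) else NA_integer_,
         smallest = if (nrow(x$clusters)) min(x$clusters$size) else NA_integer_)
}

#' Per-cluster hypergeometric overlap with a reference gene set
#'
#' For each cluster, the upper-tail hypergeometric probability of observing at
#' least the observed overlap with the reference set, given the cluster size,
#' the reference size, and a fixed background universe size (default 18,000,
#' the number of genes the method can score).
#'
#' @param clusters A [iterative_modularity_clusters()] result.
#' @param reference Character vector of reference genes (e.g. the
#'   high-confidence positives).
#' @param background_size Background universe size (default 18000).
#' @return Tibble: `cluster`, `size`, `overlap`, `p_value`.
#' @export
cluster_overlap_stats <- function(clusters, reference, background_size = 18000) {
  stopifnot(inherits(clusters, "cluster_set"))
  reference <- unique(reference)
  m <- length(reference)
  if (m > background_size) abort("reference larger than the background universe")
  clusters$membership %>%
    group_by(.data$cluster) %>%
    summarise(
      size = n(),
      overlap = sum(.data$gene %in% reference),
      .groups = "drop"
    ) %>%
    mutate(p_value = phyper(.data$overlap - 1, m, background_size - m,
                            .data$size, lower.tail = FALSE))
}

#' Per-cluster haploinsufficiency (pLI) enrichment
#'
#' For each cluster, Fisher's exact test of the 2x2 table (in cluster x
#' pLI > threshold) against all other clustered genes with a pLI value.
#'
#' @param clusters A [iterative_modularity_clusters()] result.
#' @param pli Tibble with columns `gene` and `pLI` (values in \[0,1\]).
#' @param threshold pLI cutoff marking haploinsufficiency-sensitive genes
#'   (default 0.5).
#' @return Tibble: `cluster`, `size`, `n_high_pli`, `odds_ratio`, `p_value`.
#' @export
cluster_pli_enrichment <- function(clusters, pli, threshold = 0.5) {
  stopifnot(inherits(clusters, "cluster_set"))
  pli <- as_tibble(pli)
  if (!all(c("gene", "pLI") %in% names(pli))) {
    abort("pli must have columns gene and pLI")
  }
  if (any(!is.na(pli$pLI) & (pli$pLI < 0 | pli$pLI > 1))) {
    abort("pLI values must lie in [0, 1]")
  }
  df <- left_join(clusters$membership, pli, by = "gene")
  df <- filter(df, !is.na(.data$pLI))
  if (nrow(df) == 0) abort("no clustered gene has a pLI value")
  df$high <- df$pLI > threshold
  purrr::map_dfr(sort(unique(df$cluster)), function(cl) {
    inside <- df$cluster == cl
    ft <- fisher_table(
      sum(inside & df$high), sum(inside & !df$high),
      sum(!inside & df$high), sum(!inside & !df$high)
    )
    tibble(cluster = cl, size = sum(inside), n_high_pli = sum(inside & df$high),
           odds_ratio = ft$odds_ratio, p_value = ft$p_value)
  })
}
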