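# igraph representation built on demand from the stored edge list
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE)
}

#' Degree of a gene in the functional network
#'
#' Count of distinct interaction partners. A gene absent from the network
#' has no measurement: the result is `NA`, not 0 (an isolated but listed
#' node would be 0, but edge lists cannot represent isolated nodes, so
#' absence means unobserved).
#'
#' @param network A [gene_network()].
#' @param genes Character vector of gene ids.
#' @return Named integer vector (NA for absent genes).
#' @export
node_degree <- function(network, genes) {
  g <- .as_igraph(network)
  present <- genes %in% igraph::V(g)$name
  out <- rep(NA_integer_, length(genes))
  out[present] <- as.integer(igraph::degree(g, genes[present]))
  stats::setNames(out, genes)
}

#' Proximity of genes to a seed set
#'
#' Two measures per gene: `hops`, the unweighted shortest-path distance to
#' the nearest seed, and `seed_weight`, the sum of log-likelihood weights
#' of the gene's direct edges to seed genes. With `exclude_self = TRUE`
#' (the default) a gene that is itself a seed is removed from the seed set
#' for its own computation (leave-one-out), preventing label leakage when
#' the measure is used as a predictor for training genes.
#'
#' Genes absent from the network get `NA` for both measures; a present
#' gene with no path to any seed gets `NA` hops and seed_weight 0.
#'
#' @param network A [gene_network()].
#' @param seeds Character vector of seed gene ids (non-empty).
#' @param genes Character vector of query gene ids (default: all network
#'   genes).
#' @param exclude_self Leave-one-out for genes that are seeds themselves.
#' @return data.frame with `gene_id`, `hops`, `seed_weight`.
#' @export
proximity_to_seeds <- function(network, seeds, genes = network_genes(network),
                               exclude_self = TRUE) {
  if (length(seeds) == 0L) stop("seed set must be non-empty")
  g <- .as_igraph(network)
  vnames <- igraph::V(g)$name
  seeds_in <- intersect(seeds, vnames)
  present <- genes %in% vnames

  hops <- rep(NA_real_, length(genes))
  wsum <- rep(NA_real_, length(genes))

  if (length(seeds_in) > 0L && any(present)) {
    # hop distances to all seeds at once (unweighted BFS)
    d <- igraph::distances(g, v = genes[present], to = seeds_in, weights = NA)
    ed <- network$edges
    for (k in which(present)) {
      gene <- genes[k]
      use <- seeds_in
      if (exclude_self) use <- setdiff(use, gene)
      if (length(use) == 0L) { hops[k] <- NA_real_; wsum[k] <- 0; next }
      dk <- d[match(gene, genes[present]), match(use, seeds_in)]
      m <- suppressWarnings(min(dk))
      hops[k] <- if (is.finite(m)) m else NA_real_
      direct <- (ed$gene_a == gene & ed$gene_b %in% use) |
                (ed$gene_b == gene & ed$gene_a %in% use)
      wsum[k] <- sum(ed$weight[direct])
    }
  } else if (any(present)) {
    wsum[present] <- 0
  }
  data.frame(gene_id = genes, hops = hops, seed_weight = wsum,
             stringsAsFactors = FALSE)
}
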