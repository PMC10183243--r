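as_weight_matrix <- function(net) {
  W <- if (inherits(net, "ggm_network")) net$W else as.matrix(net)
  if (is.null(colnames(W))) {
    dimnames(W) <- list(paste0("item", seq_len(ncol(W))),
                        paste0("item", seq_len(ncol(W))))
  }
  W
}

#' Strength centrality
#'
#' The sum of the absolute weights of all edges incident to each node: how
#' strongly a symptom is connected to the rest of the network.
#'
#' @param net a `ggm_network` or weight matrix.
#' @return Named numeric vector of per-node strengths.
#' @export
node_strength <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(abs(W))
}

#' Bridge strength
#'
#' Strength restricted to cross-community edges: the sum of absolute
#' weights of the edges joining a node to nodes in other communities.
#' High-bridge-strength symptoms are candidates for how one disorder's
#' symptoms activate another's.
#'
#' @param net a `ggm_network` or weight matrix.
#' @param cm a [community_map()] covering all nodes.
#' @return Named numeric vector of per-node bridge strengths.
#' @export
bridge_strength <- function(net, cm) {
  W <- as_weight_matrix(net)
  ids <- colnames(W)
  validate_communities(cm, ids)
  comm <- cm$assignment[ids]
  cross <- outer(comm, comm, `!=`)
  rowSums(abs(W) * cross)
}

#' Within-community strength
#'
#' The complement of [bridge_strength()]: per node,
#' `strength = bridge_strength + within_strength` exactly.
#'
#' @inheritParams bridge_strength
#' @return Named numeric vector.
#' @export
within_strength <- function(net, cm) {
  node_strength(net) - bridge_strength(net, cm)
}

#' Bridge betweenness
#'
#' For every unordered pair of nodes from different communities, each
#' intermediate node is credited with the fraction of shortest paths
#' between the pair that pass through it (fractional counting over tied
#' geodesics). Edge distances are `1 / |w|`, the standard conversion from
#' association to length; disconnected pairs contribute nothing.
#'
#' @inheritParams bridge_strength
#' @return Named numeric vector of per-node bridge betweenness scores.
#' @export
bridge_betweenness <- function(net, cm) {
  W <- as_weight_matrix(net)
  ids <- colnames(W)
  validate_communities(cm, ids)
  comm <- cm$assignment[ids]
  p <- ncol(W)
  score <- stats::setNames(numeric(p), ids)
  A <- abs(W)
  if (all(A == 0)) return(score)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  for (a in seq_len(p - 1)) {
    for (b in (a + 1):p) {
      if (comm[a] == comm[b]) next
      sp <- suppressWarnings(
        igraph::all_shortest_paths(g, from = a, to = b)$vpaths
      )
      if (length(sp) == 0) next
      share <- 1 / length(sp)
      for (pathv in sp) {
        inter <- as.integer(pathv)
        inter <- inter[-c(1, length(inter))]
        if (length(inter) > 0) score[inter] <- score[inter] + share
      }
    }
  }
  score
}

#' z-standardize a node-index vector
#'
#' Centers and scales with the sample standard deviation (n - 1
#' denominator), the form in which centrality indices are usually plotted.
#' A constant vector yields all zeros with a warning.
#'
#' @param values numeric vector, length >= 2.
#' @return Numeric vector of z-scores (mean 0, sample SD 1 when defined).
#' @export
zstandardize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  s <- sd(values)
  if (s == 0) {
    warning("constant vector; z-scores set to 0", call. = FALSE)
    return(values * 0)
  }
  (values - mean(values)) / s
}

#' Node metrics table
#'
#' Assembles strength, bridge strength, within-community strength, bridge
#' betweenness and (optionally) predictability per node, each raw and
#' z-standardized.
#'
#' @param net a `ggm_network`.
#' @param cm a [community_map()].
#' @param predictability optional result of [node_predictability()] to
#'   append as an `r2` column.
#' @return Data frame, one row per node.
#' @export
node_metrics <- function(net, cm, predictability = NULL) {
  W <- as_weight_matrix(net)
  ids <- colnames(W)
  validate_communities(cm, ids)
  s <- node_strength(W)
  b <- bridge_strength(W, cm)
  bb <- bridge_betweenness(W, cm)
  out <- data.frame(
    node = ids,
    community = unname(cm$assignment[ids]),
    strength = unname(s),
    strength_z = unname(zstandardize(s)),
    bridge_strength = unname(b),
    bridge_strength_z = unname(zstandardize(b)),
    within_strength = unname(s - b),
    bridge_betweenness = unname(bb),
    bridge_betweenness_z = unname(zstandardize(bb)),
    stringsAsFactors = FALSE
  )
  if (!is.null(predictability)) {
    r2 <- if (inherits(predictability, "predictability_table")) {
      predictability$r2
    } else {
      predictability
    }
    out$r2 <- unname(r2[ids])
  }
  out
}
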