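#' Reputation scores: the leading eigenvector of the adjacency matrix
#'
#' The reputation of a protein is its entry in the leading (Perron)
#' eigenvector of the network's adjacency matrix, rescaled so the maximum
#' entry is 1 — an eigenvector-centrality measure. The eigenvector is
#' computed by power iteration on the shifted matrix `A + I` (same
#' eigenvectors as `A`, but a strictly dominant leading eigenvalue even on
#' bipartite components, so the iteration always converges) starting from the
#' all-ones vector, to an infinity-norm tolerance of 1e-10 with at most
#' 10,000 iterations.
#'
#' On a disconnected network the leading eigenvector of the whole matrix
#' concentrates on one component and zeroes the others, so the eigenvector is
#' computed and max-rescaled per connected component: every component
#' contributes nonzero reputations. A singleton or edgeless component gets
#' reputation 1.
#'
#' @param network A [ppi_network] with at least one node.
#' @param tol Infinity-norm convergence tolerance of the power iteration.
#' @param max_iter Iteration cap.
#' @return A tibble with columns `node` and `gamma` (reputation in `[0, 1]`,
#'   maximum 1 attained in every connected component).
#' @export
reputation_scores <- function(network, tol = 1e-10, max_iter = 10000) {
  n <- igraph::vcount(network)
  if (n == 0) abort("network has no nodes.")
  comp <- igraph::components(network)
  gamma <- numeric(n)
  adj <- igraph::as_adj_list(network, mode = "all")
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) == 1) {
      gamma[members] <- 1
      next
    }
    pos <- integer(n)
    pos[members] <- seq_along(members)
    nbrs <- lapply(adj[members], function(v) pos[as.integer(v)])
    x <- rep(1, length(members))
    for (it in seq_len(max_iter)) {
      xn <- vapply(nbrs, function(j) sum(x[j]), numeric(1)) + x # (A + I) x
      xn <- xn / max(xn)
      if (max(abs(xn - x)) < tol) {
        x <- xn
        break
      }
      x <- xn
    }
    gamma[members] <- x / max(x)
  }
  tibble::tibble(node = network_nodes(network), gamma = gamma)
}

#' Nodes at distance exactly two
#'
#' @param network A [ppi_network].
#' @param v A protein id in the network.
#' @return Character vector of proteins at shortest-path distance exactly 2
#'   from `v` (never `v` itself or a direct neighbour).
#' @export
two_step_set <- function(network, v) {
  if (!v %in% network_nodes(network)) {
    abort(paste0("unknown node '", v, "'"))
  }
  nb <- names(igraph::neighbors(network, v))
  nb2 <- unique(unlist(lapply(nb, function(u) names(igraph::neighbors(network, u)))))
  setdiff(nb2, c(v, nb))
}

#' Number of length-two shortest paths between two nodes
#'
#' Defined only for nodes at distance exactly 2, where it equals the number
#' of common neighbours.
#'
#' @inheritParams two_step_set
#' @param x,v Protein ids with `dist(x, v) == 2`.
#' @return Integer count of shortest paths.
#' @export
shortest_path_count <- function(network, x, v) {
  d <- igraph::distances(network, v = x, to = v)[1, 1]
  if (!is.finite(d) || d != 2) {
    abort("shortest_path_count is defined only for nodes at distance 2.")
  }
  length(intersect(
    names(igraph::neighbors(network, x)),
    names(igraph::neighbors(network, v))
  ))
}

#' Raw 5-tuple topological feature vectors
#'
#' For every node `v` the feature vector `(gamma, sigma, tau, eta, theta)`
#' describes its local connectivity:
#' * `gamma` — reputation (leading-eigenvector entry, max-rescaled);
#' * `sigma` — degree, the number of direct neighbours;
#' * `tau` — sum of the reputations of the direct neighbours;
#' * `eta` — number of nodes at distance exactly 2;
#' * `theta` — half the sum, over the distance-2 nodes `x`, of
#'   `gamma(x)` times the number of length-2 shortest paths from `x` to `v`.
#'
#' @param network A [ppi_network].
#' @param reputations Optional reputation tibble (columns `node`, `gamma`);
#'   computed with [reputation_scores()] by default. Supplying rounded
#'   reputations reproduces hand calculations done at 2-decimal precision.
#' @return A tibble with columns `node`, `gamma`, `sigma`, `tau`, `eta`,
#'   `theta`, one row per node.
#' @examples
#' g1 <- example_networks()[[1]]
#' node_features(g1)
#' @export
node_features <- function(network, reputations = reputation_scores(network)) {
  nodes <- network_nodes(network)
  if (!all(nodes %in% reputations$node)) {
    abort("`reputations` must cover every node of the network.")
  }
  gamma <- setNames(reputations$gamma, reputations$node)[nodes]
  adj <- igraph::as_adj_list(network, mode = "all")
  nbr_names <- lapply(adj, function(v) nodes[as.integer(v)])
  names(nbr_names) <- nodes
  feat_one <- function(v) {
    nb <- nbr_names[[v]]
    nb2 <- setdiff(unique(unlist(nbr_names[nb], use.names = FALSE)), c(v, nb))
    theta <- if (length(nb2) == 0) {
      0
    } else {
      paths <- vapply(nb2, function(x) length(intersect(nbr_names[[x]], nb)), numeric(1))
      0.5 * sum(gamma[nb2] * paths)
    }
    c(
      sigma = length(nb),
      tau = sum(gamma[nb]),
      eta = length(nb2),
      theta = theta
    )
  }
  m <- t(vapply(nodes, feat_one, numeric(4)))
  tibble::tibble(
    node = nodes,
    gamma = unname(gamma),
    sigma = unname(m[, "sigma"]),
    tau = unname(m[, "tau"]),
    eta = unname(m[, "eta"]),
    theta = unname(m[, "theta"])
  )
}

#' Normalize feature vectors within one network
#'
#' Each of the five coordinates is divided by its maximum over the nodes of
#' the network, so every coordinate lies in `[0, 1]` and (for coordinates
#' with a nonzero maximum) some node attains 1. A coordinate whose maximum is
#' 0 maps to 0 for all nodes. Normalisation is per network: each network is
#' scaled by its own maxima.
#'
#' @param features A raw feature tibble from [node_features()].
#' @return A tibble with the same columns, coordinates rescaled to `[0, 1]`.
#' @export
normalize_features <- function(features) {
  dplyr::mutate(
    features,
    dplyr::across(
      dplyr::all_of(feature_cols()),
      function(x) if (max(x) > 0) x / max(x) else x * 0
    )
  )
}

#' Normalized feature table for a set of networks
#'
#' Convenience wrapper running [node_features()] and [normalize_features()]
#' on every network and binding the results with a `network` column.
#'
#' @param networks A list of [ppi_network] objects with unique ids.
#' @return A tibble with columns `network`, `node`, and the five normalized
#'   feature coordinates.
#' @export
network_features <- function(networks) {
  check_networks(networks)
  purrr::map_dfr(networks, function(g) {
    normalize_features(node_features(g)) |>
      dplyr::mutate(network = network_id(g), .before = 1)
  })
}

#' Gaussian topological similarity between two feature vectors
#'
#' `s_t = exp(-x^2 / 2)` where `x` is the Euclidean distance between the two
#' normalized 5-tuple feature vectors. Symmetric, equal to 1 exactly when the
#' vectors coincide, and strictly decreasing in the distance; the minimum
#' possible value over normalized vectors is `exp(-5/2)`.
#'
#' @param nfv_u,nfv_v Numeric vectors of length 5 (normalized features), or
#'   single rows of a normalized feature tibble.
#' @return Similarity in `(0, 1]`.
#' @export
topo_similarity <- function(nfv_u, nfv_v) {
  u <- feature_coords(nfv_u)
  v <- feature_coords(nfv_v)
  exp(-0.5 * sum((u - v)^2))
}

#' Topological similarity matrix between two networks
#'
#' @param features_u,features_v Normalized feature tibbles (with `node`
#'   column) for the two networks.
#' @return A numeric matrix of `s_t` values, rows named by `features_u$node`,
#'   columns by `features_v$node`.
#' @export
topo_similarity_matrix <- function(features_u, features_v) {
  mu <- as.matrix(features_u[feature_cols()])
  mv <- as.matrix(features_v[feature_cols()])
  d2 <- outer(rowSums(mu^2), rowSums(mv^2), "+") - 2 * mu %*% t(mv)
  d2[d2 < 0] <- 0
  s <- exp(-0.5 * d2)
  dimnames(s) <- list(features_u$node, features_v$node)
  s
}

feature_cols <- function() c("gamma", "sigma", "tau", "eta", "theta")

# internal: coerce a feature row / vector to the 5 numeric coordinates
feature_coords <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) abort("expected a single feature-vector row.")
    x <- unlist(x[feature_cols()])
  }
  x <- as.numeric(x)
  if (length(x) != 5) abort("a feature vector has exactly 5 coordinates.")
  x
}
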