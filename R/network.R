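#' Construct a PPI network
#'
#' A `ppi_network` is an undirected simple [igraph::igraph] graph whose
#' vertices are protein identifiers, tagged with a short network identifier
#' (typically a species label). Self-loops and duplicate edges are removed on
#' construction; isolated proteins are allowed.
#'
#' @param edges A two-column data frame (or matrix) of protein-identifier
#'   pairs, one interaction per row. May be empty.
#' @param id Short network label, e.g. `"SC"` for S. cerevisiae.
#' @param nodes Optional character vector of protein identifiers; the node set
#'   is the union of `nodes` and all edge endpoints, so proteins with no
#'   recorded interaction can be carried along.
#'
#' @return A `ppi_network` object (an igraph graph with graph attribute
#'   `network_id`).
#' @examples
#' g <- ppi_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3")), id = "toy")
#' network_id(g)
#' igraph::vcount(g)
#' @export
ppi_network <- function(edges, id, nodes = character()) {
  if (!rlang::is_string(id)) abort("`id` must be a single string.")
  em <- as.matrix(edges)
  if (length(em) > 0 && ncol(em) != 2) {
    abort("`edges` must have exactly two columns.")
  }
  storage.mode(em) <- "character"
  all_nodes <- unique(c(nodes, as.vector(t(em)))) # endpoints incl. self-loops
  if (nrow(em) > 0) em <- em[em[, 1] != em[, 2], , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(em, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = all_nodes
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  g <- igraph::set_graph_attr(g, "network_id", id)
  class(g) <- c("ppi_network", class(g))
  g
}

#' @rdname ppi_network
#' @param network A `ppi_network`.
#' @export
network_id <- function(network) {
  igraph::graph_attr(network, "network_id")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(
    "<ppi_network> ", network_id(x), ": ",
    igraph::vcount(x), " proteins, ", igraph::ecount(x), " interactions\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy the edge and node tables of a network
#'
#' @param x A `ppi_network`.
#' @param ... Unused.
#' @return A tibble with columns `network`, `from`, `to` (one row per
#'   undirected interaction).
#' @export
tidy.ppi_network <- function(x, ...) {
  el <- igraph::as_edgelist(x, names = TRUE)
  tibble::tibble(
    network = network_id(x),
    from = as.character(el[, 1]),
    to = as.character(el[, 2])
  )
}

#' @rdname tidy.ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  tibble::tibble(
    network = network_id(x),
    n_proteins = igraph::vcount(x),
    n_interactions = igraph::ecount(x)
  )
}

# internal: protein ids of one network
network_nodes <- function(network) igraph::V(network)$name

# internal: validate a list of ppi_network objects
check_networks <- function(networks) {
  if (!is.list(networks) || length(networks) == 0 ||
    !all(vapply(networks, inherits, logical(1), "ppi_network"))) {
    abort("`networks` must be a non-empty list of `ppi_network` objects.")
  }
  ids <- vapply(networks, network_id, character(1))
  if (anyDuplicated(ids)) abort("network ids must be unique.")
  invisible(ids)
}

# internal: map each protein id to its network id; error on cross-network
# duplicates (a protein belongs to exactly one species network)
node_network_map <- function(networks) {
  ids <- check_networks(networks)
  tbl <- purrr::map2_dfr(
    networks, ids,
    ~ tibble::tibble(node = network_nodes(.x), network = .y)
  )
  dup <- tbl$node[duplicated(tbl$node)]
  if (length(dup) > 0) {
    abort(paste0(
      "protein id(s) appear in more than one network: ",
      paste(utils::head(unique(dup), 5), collapse = ", ")
    ))
  }
  tbl
}
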