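#' The five-node worked-example networks
#'
#' Two isomorphic 5-node, 6-edge networks used throughout the documentation
#' and tests: `G1` has nodes `a1..a5` and edges a1-a2, a1-a4, a1-a5, a2-a3,
#' a2-a5, a4-a5; `G2` is the same graph with `b`-labelled nodes. Nodes `a1`
#' and `a5` are exchanged by an automorphism, so they carry identical feature
#' vectors.
#'
#' @return A named list of two [ppi_network] objects, `G1` and `G2`.
#' @examples
#' nets <- example_networks()
#' igraph::degree(nets$G1)
#' @export
example_networks <- function() {
  edges <- data.frame(
    from = c("a1", "a1", "a1", "a2", "a2", "a4"),
    to = c("a2", "a4", "a5", "a3", "a5", "a5")
  )
  g1 <- ppi_network(edges, id = "G1")
  g2 <- ppi_network(
    data.frame(
      from = sub("^a", "b", edges$from),
      to = sub("^a", "b", edges$to)
    ),
    id = "G2"
  )
  list(G1 = g1, G2 = g2)
}

#' Sample a seed interaction network
#'
#' Two generative models are available: an Erdős–Rényi graph with a given
#' mean degree, and a duplication–divergence process (start from a small
#' clique; each new node copies a random existing node's edges, retaining
#' each with probability `retention`) which yields the heavier-tailed degree
#' distributions typical of PPI networks.
#'
#' @param n Number of proteins.
#' @param mean_degree Target mean degree (Erdős–Rényi model).
#' @param model `"erdos_renyi"` (default) or `"duplication_divergence"`.
#' @param retention Edge-retention probability of the duplication model.
#' @param id Network label; node ids are `<id>_p1 .. <id>_pn`.
#' @return A [ppi_network]. Uses the current RNG state; call [set.seed()]
#'   first for reproducibility.
#' @export
sample_seed_network <- function(n, mean_degree = 6,
                                model = c("erdos_renyi", "duplication_divergence"),
                                retention = 0.4, id = "seed") {
  model <- rlang::arg_match(model)
  if (n < 2) abort("`n` must be at least 2.")
  nodes <- paste0(id, "_p", seq_len(n))
  if (model == "erdos_renyi") {
    g <- igraph::sample_gnp(n, min(1, mean_degree / (n - 1)))
  } else {
    g <- igraph::make_full_graph(min(4, n))
    while (igraph::vcount(g) < n) {
      anchor <- sample.int(igraph::vcount(g), 1)
      nb <- as.integer(igraph::neighbors(g, anchor))
      keep <- nb[runif(length(nb)) < retention]
      g <- igraph::add_vertices(g, 1)
      new <- igraph::vcount(g)
      targets <- unique(c(keep, anchor)) # always attach to the anchor
      g <- igraph::add_edges(g, rbind(targets, rep(new, length(targets))))
    }
  }
  igraph::V(g)$name <- nodes
  el <- igraph::as_edgelist(g, names = TRUE)
  ppi_network(el, id = id, nodes = nodes)
}

#' Noisy duplicate of a network with known correspondence
#'
#' Copies the seed network with relabelled nodes, deletes each edge
#' independently with probability `p_del`, and inserts
#' `round(p_add * |E|)` uniformly chosen non-edges. The returned truth map
#' records, for every derived node, its ancestor in the seed network.
#'
#' @param network Seed [ppi_network].
#' @param p_del Edge deletion probability in `[0, 1)`.
#' @param p_add Edge insertion rate in `[0, 1)`, as a fraction of the seed
#'   edge count.
#' @param new_id Label (and node-id prefix) of the derived network.
#' @return A list with `network` (the noisy copy) and `truth` (tibble
#'   `network`, `node`, `ancestor` covering every derived node).
#' @export
duplicate_with_noise <- function(network, p_del = 0.05, p_add = 0.05,
                                 new_id = "copy") {
  if (p_del < 0 || p_del >= 1 || p_add < 0 || p_add >= 1) {
    abort("`p_del` and `p_add` must lie in [0, 1).")
  }
  old_nodes <- network_nodes(network)
  new_nodes <- paste0(new_id, "_", old_nodes)
  relabel <- setNames(new_nodes, old_nodes)
  el <- igraph::as_edgelist(network, names = TRUE)
  edges <- tibble::tibble(
    from = unname(relabel[el[, 1]]),
    to = unname(relabel[el[, 2]])
  )
  keep <- runif(nrow(edges)) >= p_del
  edges <- edges[keep, , drop = FALSE]
  n_add <- round(p_add * nrow(el))
  if (n_add > 0) {
    existing <- c(pair_key(edges$from, edges$to))
    added <- 0
    while (added < n_add) {
      pick <- sample(new_nodes, 2)
      key <- pair_key(pick[1], pick[2])
      if (!key %in% existing) {
        edges <- dplyr::bind_rows(edges, tibble::tibble(from = pick[1], to = pick[2]))
        existing <- c(existing, key)
        added <- added + 1
      }
    }
  }
  list(
    network = ppi_network(edges, id = new_id, nodes = new_nodes),
    truth = tibble::tibble(
      network = new_id, node = new_nodes, ancestor = old_nodes
    )
  )
}

#' Synthetic all-against-all homology table
#'
#' Emulates tabular BLAST output for a set of derived networks with known
#' ancestry: every true-ortholog pair (two proteins of different networks
#' sharing an ancestor) receives a bit score drawn from the "true" normal
#' distribution, and `round(background_rate * n_true)` random non-ortholog
#' cross-network pairs receive scores from the lower "background"
#' distribution. Both distributions are truncated below at `min_bitscore`.
#' E-values are derived from the bit scores (`10^(-bitscore / 3)`), and both
#' hit directions are emitted.
#'
#' @param truths List of truth tibbles from [duplicate_with_noise()].
#' @param true_mean,true_sd Bit-score distribution of true-ortholog pairs
#'   (defaults 200 and 20 bits).
#' @param background_mean,background_sd Bit-score distribution of background
#'   pairs (defaults 60 and 15 bits).
#' @param background_rate Number of background pairs as a fraction of the
#'   number of true pairs.
#' @param min_bitscore Truncation floor in bits (default 30).
#' @return A tibble in 12-column BLAST tabular layout (`qseqid`, `sseqid`,
#'   ..., `evalue`, `bitscore`); write it with [write_blast_tab()].
#' @export
synthetic_homology <- function(truths, true_mean = 200, true_sd = 20,
                               background_mean = 60, background_sd = 15,
                               background_rate = 0.2, min_bitscore = 30) {
  truth <- dplyr::bind_rows(truths)
  true_pairs <- truth |>
    dplyr::inner_join(truth,
      by = "ancestor", suffix = c("_1", "_2"),
      relationship = "many-to-many"
    ) |>
    dplyr::filter(.data$network_1 < .data$network_2) |>
    dplyr::select(query = "node_1", subject = "node_2")
  n_true <- nrow(true_pairs)
  n_bg <- round(background_rate * n_true)
  bg_pairs <- tibble::tibble(query = character(), subject = character())
  if (n_bg > 0) {
    true_keys <- pair_key(true_pairs$query, true_pairs$subject)
    seen <- character()
    while (nrow(bg_pairs) < n_bg) {
      nets <- sample(unique(truth$network), 2)
      q <- sample(truth$node[truth$network == nets[1]], 1)
      s <- sample(truth$node[truth$network == nets[2]], 1)
      key <- pair_key(q, s)
      if (!key %in% true_keys && !key %in% seen) {
        bg_pairs <- dplyr::bind_rows(bg_pairs, tibble::tibble(query = q, subject = s))
        seen <- c(seen, key)
      }
    }
  }
  draw <- function(k, mu, sd) pmax(min_bitscore, rnorm(k, mu, sd))
  hits <- dplyr::bind_rows(
    dplyr::mutate(true_pairs, bitscore = draw(n_true, true_mean, true_sd)),
    dplyr::mutate(bg_pairs, bitscore = draw(n_bg, background_mean, background_sd))
  )
  hits <- dplyr::bind_rows(
    hits,
    dplyr::rename(hits, query = "subject", subject = "query")
  )
  tibble::tibble(
    qseqid = hits$query,
    sseqid = hits$subject,
    pident = 90,
    length = 300L,
    mismatch = 30L,
    gapopen = 0L,
    qstart = 1L,
    qend = 300L,
    sstart = 1L,
    send = 300L,
    evalue = 10^(-hits$bitscore / 3),
    bitscore = round(hits$bitscore, 1)
  )
}

#' @rdname synthetic_homology
#' @param records A 12-column homology tibble.
#' @param path Output path.
#' @export
write_blast_tab <- function(records, path) {
  readr::write_tsv(records, path, col_names = FALSE)
  invisible(path)
}

#' Synthetic GO annotations with controllable purity
#'
#' Every true-orthology group (proteins sharing an ancestor, the ancestor's
#' own protein included if its truth row is supplied) draws one "family term"
#' from a vocabulary of `vocabulary_size` terms; each member protein is
#' annotated with the family term with probability `purity`, and with a
#' uniformly random vocabulary term otherwise. At `purity = 1` every
#' ground-truth matchset is pure (entropy 0); at `purity = 0` terms are
#' uniform and the normalized entropy of large groups approaches 1.
#'
#' @param truths List of truth tibbles from [duplicate_with_noise()].
#' @param vocabulary_size Number of distinct GO-like term ids.
#' @param purity Probability in `[0, 1]` of drawing the family term.
#' @param aspect GO aspect assigned to the synthetic terms (default `"BP"`).
#' @return An annotation tibble (`protein`, `term`, `aspect`); write it with
#'   [write_gaf()].
#' @export
synthetic_annotations <- function(truths, vocabulary_size = 50, purity = 0.8,
                                  aspect = "BP") {
  if (purity < 0 || purity > 1) abort("`purity` must lie in [0, 1].")
  truth <- dplyr::bind_rows(truths)
  vocab <- sprintf("GO:%07d", seq_len(vocabulary_size))
  family <- setNames(
    sample(vocab, length(unique(truth$ancestor)), replace = TRUE),
    unique(truth$ancestor)
  )
  use_family <- runif(nrow(truth)) < purity
  random_term <- sample(vocab, nrow(truth), replace = TRUE)
  tibble::tibble(
    protein = truth$node,
    term = ifelse(use_family, unname(family[truth$ancestor]), random_term),
    aspect = aspect
  )
}

#' @rdname synthetic_annotations
#' @param annotations An annotation tibble (`protein`, `term`, `aspect`).
#' @param path Output path.
#' @export
write_gaf <- function(annotations, path) {
  aspect_map <- c(BP = "P", MF = "F", CC = "C")
  rows <- sprintf(
    "SYNTH\t%s\t%s\t\t%s\tSYNTH:0001\tIEA\t\t%s\t\t\tprotein\ttaxon:0\t20200101\tSYNTH\t\t",
    annotations$protein, annotations$protein, annotations$term,
    aspect_map[annotations$aspect]
  )
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Generate a complete synthetic alignment instance
#'
#' Draws an Erdős–Rényi (or duplication–divergence) seed network, derives
#' `k` noisy copies with known node correspondence, and builds a matching
#' homology table and annotation map, so the whole alignment pipeline can be
#' exercised with a known ground truth.
#'
#' @param n Seed network size (default 100 proteins).
#' @param mean_degree Seed mean degree (default 6).
#' @param k Number of derived networks (default 2).
#' @param p_del,p_add Edge noise rates of the copies (default 0.05 each).
#' @param background_rate Background homology rate (default 0.2).
#' @param purity Annotation purity (default 0.8).
#' @param model Seed-graph model, see [sample_seed_network()].
#' @param seed Integer RNG seed; the instance is bit-identical for a fixed
#'   seed.
#' @return A list with `networks` (list of `k` [ppi_network]s), `truth`
#'   (tibble `network`, `node`, `ancestor`), `homology` (BLAST-layout
#'   tibble), `annotations`, and `params`.
#' @export
synthetic_instance <- function(n = 100, mean_degree = 6, k = 2,
                               p_del = 0.05, p_add = 0.05,
                               background_rate = 0.2, purity = 0.8,
                               model = "erdos_renyi", seed = 1) {
  if (k < 2) abort("an alignment instance needs at least 2 networks.")
  if (!is.null(seed)) set.seed(seed)
  seed_net <- sample_seed_network(n, mean_degree, model = model, id = "seed")
  copies <- purrr::map(seq_len(k), function(i) {
    duplicate_with_noise(seed_net, p_del, p_add, new_id = paste0("net", i))
  })
  truths <- purrr::map(copies, "truth")
  list(
    networks = purrr::map(copies, "network"),
    truth = dplyr::bind_rows(truths),
    homology = synthetic_homology(truths, background_rate = background_rate),
    annotations = synthetic_annotations(truths, purity = purity),
    params = list(
      n = n, mean_degree = mean_degree, k = k, p_del = p_del, p_add = p_add,
      background_rate = background_rate, purity = purity, model = model,
      seed = seed
    )
  )
}

#' Fraction of selected candidate edges that are true-ortholog pairs
#'
#' The node-correctness proxy used to validate the optimizer on synthetic
#' instances with known ancestry.
#'
#' @param candidates Candidate tibble (columns `u`, `v`).
#' @param selected Integer indices of the selected candidate edges.
#' @param truth Truth tibble (`node`, `ancestor`).
#' @return A single number in `[0, 1]` (`NaN` for an empty selection).
#' @export
node_correctness <- function(candidates, selected, truth) {
  anc <- setNames(truth$ancestor, truth$node)
  sel <- candidates[selected, , drop = FALSE]
  mean(anc[sel$u] == anc[sel$v])
}
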