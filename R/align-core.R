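#' Build a pair scorer
#'
#' A scorer bundles everything needed to evaluate the combined similarity of
#' any two proteins: the normalized topological feature vectors, the
#' sequence-similarity map over the candidate set, and the blending weight
#' `alpha`. The combined pair score is
#' `alpha * s_h(u, v) + (1 - alpha) * s_t(u, v)`, where `s_h` defaults to 0
#' for pairs outside the candidate set and `s_t` is the Gaussian feature
#' similarity — so the score is defined for every pair of proteins with
#' computed features, including same-network pairs created transitively
#' inside a matchset.
#'
#' @param features Normalized feature table from [network_features()].
#' @param candidates Candidate tibble with `u`, `v`, `s_h` columns (from
#'   [normalize_sequence_scores()]); may be empty.
#' @param alpha Weight in `[0, 1]` given to sequence similarity (default
#'   0.5). Increase it to trust sequence more, decrease it to trust topology
#'   more.
#' @return A `ppi_scorer` object.
#' @export
make_scorer <- function(features, candidates = NULL, alpha = 0.5) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1].")
  }
  if (anyDuplicated(features$node)) {
    abort("`features` must have one row per protein (unique node ids).")
  }
  fm <- as.matrix(features[feature_cols()])
  rownames(fm) <- features$node
  sh <- numeric(0)
  if (!is.null(candidates) && nrow(candidates) > 0) {
    sh <- setNames(
      candidates$s_h %||% rep(0, nrow(candidates)),
      pair_key(candidates$u, candidates$v)
    )
  }
  structure(
    list(alpha = alpha, features = fm, sh = sh),
    class = "ppi_scorer"
  )
}

pair_key <- function(u, v) paste(pmin(u, v), pmax(u, v), sep = "\r")

#' Combined similarity of a protein pair
#'
#' @param u,v Protein ids with computed feature vectors.
#' @param scorer A [make_scorer()] object.
#' @return `alpha * s_h + (1 - alpha) * s_t`, a value in `[0, 1]`.
#' @export
pair_score <- function(u, v, scorer) {
  fm <- scorer$features
  if (!u %in% rownames(fm) || !v %in% rownames(fm)) {
    abort("both proteins must have computed feature vectors.")
  }
  s_h <- scorer$sh[pair_key(u, v)]
  if (is.na(s_h)) s_h <- 0
  s_t <- exp(-0.5 * sum((fm[u, ] - fm[v, ])^2))
  unname(scorer$alpha * s_h + (1 - scorer$alpha) * s_t)
}

#' Score of a single matchset
#'
#' The matchset score `s_m` is the sum of the combined pair score over all
#' unordered distinct pairs of proteins in the matchset.
#'
#' @param m Character vector of at least two protein ids.
#' @inheritParams pair_score
#' @export
matchset_score <- function(m, scorer) {
  if (length(m) < 2) abort("a matchset holds at least two proteins.")
  pairs <- utils::combn(m, 2)
  sum(vapply(
    seq_len(ncol(pairs)),
    function(i) pair_score(pairs[1, i], pairs[2, i], scorer),
    numeric(1)
  ))
}

#' Total alignment score
#'
#' `f(A)` is the sum of matchset scores over all matchsets of the alignment;
#' the empty alignment scores 0.
#'
#' @param alignment An alignment tibble (columns `matchset`, `protein`).
#' @inheritParams pair_score
#' @export
alignment_score <- function(alignment, scorer) {
  alignment <- check_alignment(alignment)
  if (nrow(alignment) == 0) {
    return(0)
  }
  sets <- split(alignment$protein, alignment$matchset)
  sum(vapply(sets, function(m) {
    if (length(m) < 2) 0 else matchset_score(m, scorer)
  }, numeric(1)))
}

#' Matchsets induced by a set of selected candidate edges
#'
#' The matchsets of an alignment are the connected components (of size at
#' least 2) of the graph whose vertices are proteins and whose edges are the
#' selected candidate edges; components are disjoint by construction.
#'
#' @param candidates Candidate tibble with `u`, `v` columns.
#' @param selected Integer row indices of the selected candidate edges
#'   (default: all rows).
#' @return An alignment tibble (columns `matchset`, `protein`), matchsets
#'   numbered by their lexicographically smallest protein.
#' @export
components_from_edges <- function(candidates, selected = seq_len(nrow(candidates))) {
  sel <- candidates[selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(tibble::tibble(matchset = integer(), protein = character()))
  }
  g <- igraph::graph_from_data_frame(sel[, c("u", "v")], directed = FALSE)
  comp <- igraph::components(g)
  tibble::tibble(
    protein = igraph::V(g)$name,
    member = comp$membership
  ) |>
    dplyr::group_by(.data$member) |>
    dplyr::mutate(key = min(.data$protein)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$key, .data$protein) |>
    dplyr::mutate(matchset = dplyr::dense_rank(.data$key)) |>
    dplyr::select("matchset", "protein")
}

#' Incremental score change of a move
#'
#' Computes the exact change `delta f` of the alignment score when applying a
#' move to the current edge selection, accounting for component merges and
#' splits: adding an edge between two components adds every cross-component
#' pair score; removing a bridge edge subtracts them; edges within an already
#' connected component change nothing.
#'
#' @param selected Integer indices of currently selected candidate edges.
#' @param move A list with `type` (`"add"`, `"remove"` or `"swap"`) and the
#'   candidate row indices `add` and/or `remove`.
#' @param candidates Candidate tibble with `u`, `v` columns.
#' @inheritParams pair_score
#' @return The score change; applying the move changes `f` by exactly this
#'   amount.
#' @export
delta_score <- function(selected, move, candidates, scorer) {
  check_move_idx <- function(i) {
    if (is.null(i) || !i %in% seq_len(nrow(candidates))) {
      abort("move references an index outside the candidate list.")
    }
    i
  }
  switch(move$type,
    add = delta_add(selected, check_move_idx(move$add), candidates, scorer),
    remove = delta_remove(selected, check_move_idx(move$remove), candidates, scorer),
    swap = {
      d1 <- delta_remove(selected, check_move_idx(move$remove), candidates, scorer)
      mid <- setdiff(selected, move$remove)
      d2 <- delta_add(mid, check_move_idx(move$add), candidates, scorer)
      d1 + d2
    },
    abort("unknown move type.")
  )
}

# membership of each involved protein in the selection graph
selection_membership <- function(candidates, selected) {
  sel <- candidates[selected, , drop = FALSE]
  if (nrow(sel) == 0) {
    return(setNames(integer(0), character(0)))
  }
  g <- igraph::graph_from_data_frame(sel[, c("u", "v")], directed = FALSE)
  setNames(igraph::components(g)$membership, igraph::V(g)$name)
}

cross_component_score <- function(comp_a, comp_b, scorer) {
  sum(vapply(
    comp_a,
    function(a) sum(vapply(comp_b, function(b) pair_score(a, b, scorer), numeric(1))),
    numeric(1)
  ))
}

delta_add <- function(selected, idx, candidates, scorer) {
  if (idx %in% selected) {
    return(0)
  }
  u <- candidates$u[idx]
  v <- candidates$v[idx]
  mem <- selection_membership(candidates, selected)
  cu <- if (u %in% names(mem)) names(mem)[mem == mem[u]] else u
  cv <- if (v %in% names(mem)) names(mem)[mem == mem[v]] else v
  if (v %in% cu) {
    return(0) # already connected: components unchanged
  }
  cross_component_score(cu, cv, scorer)
}

delta_remove <- function(selected, idx, candidates, scorer) {
  if (!idx %in% selected) {
    return(0)
  }
  u <- candidates$u[idx]
  v <- candidates$v[idx]
  rest <- setdiff(selected, idx)
  mem <- selection_membership(candidates, rest)
  cu <- if (u %in% names(mem)) names(mem)[mem == mem[u]] else u
  if (v %in% cu) {
    return(0) # a parallel path keeps the component intact
  }
  cv <- if (v %in% names(mem)) names(mem)[mem == mem[v]] else v
  -cross_component_score(cu, cv, scorer)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
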