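#' Build the candidate homolog set from BLAST records
#'
#' Keeps cross-network protein pairs only, merges the two BLAST directions of
#' a pair by taking the better hit (larger bit score / smaller e-value), and
#' assigns the raw sequence score `epsilon` according to `mode`:
#' * `"bitscore"` (default) — the bit score in bits;
#' * `"log_evalue"` — `-log10(evalue)`, with e-value 0 clamped to 1e-180
#'   before the logarithm so that larger `epsilon` always means more similar.
#'
#' Records naming a protein absent from every network are dropped with a
#' warning; records pairing two proteins of the same network are silently
#' discarded (candidate match edges are cross-network by definition).
#'
#' @param records A homology tibble from [read_blast_tab()] (columns `query`,
#'   `subject`, `evalue`, `bitscore`), already filtered by e-value cutoff.
#' @param networks List of [ppi_network] objects the pairs must span.
#' @param mode Raw-score mode, `"bitscore"` or `"log_evalue"`.
#' @return A tibble of candidate pairs with columns `u`, `v` (protein ids,
#'   `u < v` lexicographically), `network_u`, `network_v`, `epsilon`, and
#'   attributes `eps_min`, `eps_max`, `mode`.
#' @export
build_candidates <- function(records, networks, mode = c("bitscore", "log_evalue")) {
  mode <- rlang::arg_match(mode)
  node_map <- node_network_map(networks)
  lookup <- setNames(node_map$network, node_map$node)

  known <- records$query %in% node_map$node & records$subject %in% node_map$node
  if (any(!known)) {
    warn(paste0(
      sum(!known), " homology record(s) name proteins absent from every ",
      "network and were dropped."
    ))
    records <- records[known, , drop = FALSE]
  }
  records <- dplyr::filter(records, .data$query != .data$subject)
  if (nrow(records) == 0) {
    omega <- tibble::tibble(
      u = character(), v = character(),
      network_u = character(), network_v = character(), epsilon = double()
    )
    attr(omega, "mode") <- mode
    attr(omega, "eps_min") <- NA_real_
    attr(omega, "eps_max") <- NA_real_
    return(omega)
  }

  omega <- records |>
    dplyr::mutate(
      u = pmin(.data$query, .data$subject),
      v = pmax(.data$query, .data$subject),
      network_u = unname(lookup[.data$u]),
      network_v = unname(lookup[.data$v])
    ) |>
    dplyr::filter(.data$network_u != .data$network_v) |>
    dplyr::group_by(.data$u, .data$v, .data$network_u, .data$network_v) |>
    dplyr::summarise(
      bitscore = max(.data$bitscore),
      evalue = min(.data$evalue),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      epsilon = switch(mode,
        bitscore = .data$bitscore,
        log_evalue = -log10(pmax(.data$evalue, 1e-180))
      )
    ) |>
    dplyr::select("u", "v", "network_u", "network_v", "epsilon") |>
    dplyr::arrange(.data$u, .data$v)

  attr(omega, "mode") <- mode
  attr(omega, "eps_min") <- if (nrow(omega)) min(omega$epsilon) else NA_real_
  attr(omega, "eps_max") <- if (nrow(omega)) max(omega$epsilon) else NA_real_
  omega
}

#' Min-max normalized sequence similarity
#'
#' `s_h(u, v) = (epsilon(u, v) - epsilon_min) / (epsilon_max - epsilon_min)`,
#' normalised over the whole candidate set: the most similar pair scores 1,
#' the least similar 0. When all raw scores are equal (including a single
#' pair) every pair scores 1. Pairs outside the candidate set have `s_h = 0`
#' by convention.
#'
#' @param candidates Candidate tibble from [build_candidates()].
#' @return The same tibble with an `s_h` column added.
#' @export
normalize_sequence_scores <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, s_h = double(0)))
  }
  eps <- candidates$epsilon
  delta <- max(eps) - min(eps)
  out <- dplyr::mutate(
    candidates,
    s_h = if (delta > 0) (eps - min(eps)) / delta else rep(1, length(eps))
  )
  attr(out, "mode") <- attr(candidates, "mode")
  attr(out, "eps_min") <- min(eps)
  attr(out, "eps_max") <- max(eps)
  out
}
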