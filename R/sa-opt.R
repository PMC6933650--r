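#' Candidate match edges with precomputed scores
#'
#' Joins the sequence-similarity candidate set with the topological
#' similarity of each pair and caches the combined pair score
#' `alpha * s_h + (1 - alpha) * s_t`. The result is ordered lexicographically
#' by protein ids, so two runs on the same inputs yield identical candidate
#' lists.
#'
#' @param networks List of [ppi_network] objects.
#' @param seq_scores Candidate tibble with `s_h` from
#'   [normalize_sequence_scores()].
#' @param features Normalized feature table from [network_features()]
#'   (computed from `networks` by default).
#' @param alpha Sequence-vs-topology weight in `[0, 1]`.
#' @return A tibble with columns `u`, `v`, `network_u`, `network_v`, `s_h`,
#'   `s_t`, `score`, one row per candidate match edge.
#' @export
enumerate_candidates <- function(networks, seq_scores,
                                 features = network_features(networks),
                                 alpha = 0.5) {
  if (nrow(seq_scores) == 0) {
    abort("no candidate match edges; relax the e-value cutoff.")
  }
  fm <- as.matrix(features[feature_cols()])
  rownames(fm) <- features$node
  missing <- setdiff(unique(c(seq_scores$u, seq_scores$v)), rownames(fm))
  if (length(missing) > 0) {
    abort(paste0(
      "no feature vector for candidate protein(s): ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  d2 <- rowSums((fm[seq_scores$u, , drop = FALSE] - fm[seq_scores$v, , drop = FALSE])^2)
  seq_scores |>
    dplyr::mutate(
      s_t = exp(-0.5 * unname(d2)),
      score = alpha * .data$s_h + (1 - alpha) * .data$s_t
    ) |>
    dplyr::arrange(.data$u, .data$v)
}

#' Annealing schedule
#'
#' Geometric cooling: the temperature at level `i` (0-based) is
#' `t0 * cooling^i`. Each level runs `steps` proposed moves; the run stops
#' early when the best score has not improved for `patience` consecutive
#' levels (the practical reading of "anneal until the score converges").
#'
#' @param t0 Initial temperature (> 0).
#' @param cooling Cooling factor in (0, 1).
#' @param steps Proposed moves per temperature level.
#' @param levels Number of temperature levels.
#' @param patience Early-stop patience in levels.
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(t0 = 1.0, cooling = 0.9, steps = 1000,
                            levels = 100, patience = 10) {
  if (t0 <= 0) abort("`t0` must be positive.")
  if (cooling <= 0 || cooling >= 1) abort("`cooling` must be in (0, 1).")
  if (steps < 1 || levels < 1 || patience < 1) {
    abort("`steps`, `levels` and `patience` must be positive integers.")
  }
  structure(
    list(
      t0 = t0, cooling = cooling, steps = as.integer(steps),
      levels = as.integer(levels), patience = as.integer(patience)
    ),
    class = "anneal_schedule"
  )
}

#' Propose a random perturbation of the current edge selection
#'
#' With probability 0.45 an unselected candidate edge is added, with
#' probability 0.45 a selected edge is removed, and with probability 0.10 one
#' selected edge is swapped for one unselected edge atomically. When a drawn
#' move type is infeasible (nothing to add or nothing to remove) the feasible
#' type is used instead.
#'
#' @param selected Integer indices of currently selected candidates.
#' @param n_candidates Total number of candidate edges.
#' @return A move list with `type` and index fields `add` / `remove`.
#' @export
propose_move <- function(selected, n_candidates) {
  if (n_candidates < 1) abort("no candidate edges to perturb.")
  unselected <- setdiff(seq_len(n_candidates), selected)
  r <- runif(1)
  type <- if (r < 0.45) "add" else if (r < 0.90) "remove" else "swap"
  if (type == "add" && length(unselected) == 0) type <- "remove"
  if (type == "remove" && length(selected) == 0) type <- "add"
  if (type == "swap") {
    if (length(selected) == 0) type <- "add"
    if (length(unselected) == 0) type <- "remove"
  }
  pick <- function(x) x[[sample.int(length(x), 1)]]
  switch(type,
    add = list(type = "add", add = pick(unselected)),
    remove = list(type = "remove", remove = pick(selected)),
    swap = list(type = "swap", remove = pick(selected), add = pick(unselected))
  )
}

#' Metropolis acceptance rule
#'
#' Improving or neutral moves (`delta >= 0`) are always accepted; worsening
#' moves are accepted with probability `exp(delta / (temp * s))`, which
#' decays as the temperature falls.
#'
#' @param delta Score change of the proposed move (finite).
#' @param temp Current temperature (> 0).
#' @param s Score scaling constant (> 0) in the acceptance denominator.
#' @return `TRUE` to accept the move.
#' @export
metropolis_accept <- function(delta, temp, s) {
  if (!is.finite(delta)) abort("`delta` must be finite.")
  if (temp <= 0 || s <= 0) abort("`temp` and `s` must be positive.")
  delta >= 0 || runif(1) < exp(delta / (temp * s))
}

#' Maximize the alignment score by simulated annealing
#'
#' Starting from the empty alignment, repeatedly perturbs the set of selected
#' candidate edges ([propose_move()]) and accepts perturbations with the
#' Metropolis rule under a geometric cooling schedule, tracking the best
#' alignment ever visited. The inner loop runs in compiled code but draws all
#' randomness from R's RNG, so a fixed seed reproduces the trajectory
#' bit-for-bit.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param features Normalized feature table covering every candidate protein.
#' @param alpha Sequence-vs-topology weight in `[0, 1]` (default 0.5).
#' @param schedule An [anneal_schedule()].
#' @param seed Integer RNG seed (default 42); `NULL` keeps the current RNG
#'   state.
#' @param max_matchset_size Optional cap on matchset size: moves that would
#'   merge components into one larger than the cap are rejected outright.
#'   `NULL` (default) leaves matchset size unbounded. For ortholog recovery
#'   between `k` networks a cap of `k` is the natural choice.
#' @param s Score scaling constant in the Metropolis denominator; defaults to
#'   the mean combined candidate score, which makes acceptance rates
#'   insensitive to the overall score scale.
#' @return A `ppi_anneal` fit: use [tidy()] for the matchset table,
#'   [glance()] for a one-row summary, [autoplot()] for the score
#'   trajectory; `$best_score`, `$selected`, `$trajectory` give direct
#'   access.
#' @export
anneal <- function(candidates, features, alpha = 0.5,
                   schedule = anneal_schedule(), seed = 42,
                   max_matchset_size = NULL, s = NULL) {
  if (nrow(candidates) == 0) abort("at least one candidate edge is required.")
  if (!inherits(schedule, "anneal_schedule")) {
    abort("`schedule` must come from anneal_schedule().")
  }
  nodes <- sort(unique(c(candidates$u, candidates$v)))
  fm <- as.matrix(features[feature_cols()])
  rownames(fm) <- features$node
  if (!all(nodes %in% rownames(fm))) {
    abort("`features` must cover every candidate protein.")
  }
  fm <- fm[nodes, , drop = FALSE]
  s_h <- candidates$s_h %||% rep(0, nrow(candidates))
  if (is.null(candidates$score)) {
    abort("`candidates` must carry a precomputed `score` column.")
  }
  s_const <- s %||% mean(candidates$score)
  if (s_const <= 0) s_const <- 1
  if (!is.null(seed)) set.seed(seed)

  res <- anneal_cpp(
    match(candidates$u, nodes) - 1L,
    match(candidates$v, nodes) - 1L,
    s_h, fm, alpha,
    as.integer(max_matchset_size %||% 0L),
    schedule$t0, schedule$cooling, schedule$steps, schedule$levels,
    s_const, schedule$patience
  )

  selected <- res$best_selected
  structure(
    list(
      candidates = candidates,
      selected = selected,
      alignment = components_from_edges(candidates, selected),
      best_score = res$best_score,
      trajectory = tibble::tibble(
        level = seq_len(res$levels_run),
        temperature = schedule$t0 * schedule$cooling^(seq_len(res$levels_run) - 1),
        current_score = res$current_trace,
        best_score = res$best_trace,
        acceptance_rate = res$accept_trace
      ),
      schedule = schedule,
      alpha = alpha,
      s = s_const,
      max_matchset_size = max_matchset_size,
      seed = seed
    ),
    class = "ppi_anneal"
  )
}

#' Exhaustive optimum over candidate-edge subsets
#'
#' Enumerates all `2^n` subsets of at most 20 candidate edges and returns the
#' subset whose induced matchsets maximise the alignment score. Written as a
#' plain, from-scratch enumeration so it can serve as an independent check of
#' the annealing optimizer on small instances.
#'
#' @param candidates Candidate tibble (at most 20 rows) with `u`, `v`, `s_h`.
#' @param features Normalized feature table covering the candidate proteins.
#' @param alpha Sequence-vs-topology weight.
#' @param max_matchset_size Optional matchset-size cap; subsets inducing a
#'   larger component are infeasible.
#' @return A list with `score`, `selected` (row indices of one argmax) and
#'   `alignment`.
#' @export
brute_force_optimum <- function(candidates, features, alpha = 0.5,
                                max_matchset_size = NULL) {
  n <- nrow(candidates)
  if (n > 20) abort("exhaustive search is limited to 20 candidate edges.")
  if (n == 0) {
    return(list(
      score = 0, selected = integer(),
      alignment = tibble::tibble(matchset = integer(), protein = character())
    ))
  }
  nodes <- sort(unique(c(candidates$u, candidates$v)))
  k <- length(nodes)
  fm <- as.matrix(features[feature_cols()])
  rownames(fm) <- features$node
  fm <- fm[nodes, , drop = FALSE]
  d2 <- as.matrix(stats::dist(fm))^2
  p <- (1 - alpha) * exp(-0.5 * d2)
  s_h <- candidates$s_h %||% rep(0, n)
  iu <- match(candidates$u, nodes)
  iv <- match(candidates$v, nodes)
  for (e in seq_len(n)) {
    p[iu[e], iv[e]] <- p[iu[e], iv[e]] + alpha * s_h[e]
    p[iv[e], iu[e]] <- p[iv[e], iu[e]] + alpha * s_h[e]
  }
  cap <- max_matchset_size %||% Inf
  upper <- upper.tri(d2)

  best_score <- 0
  best_mask <- logical(n)
  for (mask_int in 0:(2^n - 1)) {
    mask <- bitwAnd(mask_int, 2^(seq_len(n) - 1)) > 0
    # union-find over the selected edges
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (e in which(mask)) {
      ru <- find(iu[e])
      rv <- find(iv[e])
      if (ru != rv) parent[ru] <- rv
    }
    root <- vapply(seq_len(k), find, integer(1))
    if (is.finite(cap) && max(tabulate(root, k)) > cap) next
    same <- outer(root, root, "==") & upper
    score <- sum(p[same])
    if (score > best_score + 1e-12) {
      best_score <- score
      best_mask <- mask
    }
  }
  selected <- which(best_mask)
  list(
    score = best_score,
    selected = selected,
    alignment = components_from_edges(candidates, selected)
  )
}
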