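#' Coverage of an alignment
#'
#' Coverage is the percentage of all input proteins that appear in some
#' matchset — a sensitivity proxy: how much of the data the alignment
#' explains.
#'
#' @param alignment Alignment tibble (columns `matchset`, `protein`).
#' @param networks List of [ppi_network] objects the alignment was computed
#'   on.
#' @return A one-row tibble with `n_aligned`, `n_total`, `coverage`
#'   (percent).
#' @export
alignment_coverage <- function(alignment, networks) {
  alignment <- check_alignment(alignment)
  node_map <- node_network_map(networks)
  unknown <- setdiff(alignment$protein, node_map$node)
  if (length(unknown) > 0) {
    abort(paste0(
      "alignment references protein(s) absent from every network: ",
      paste(utils::head(unknown, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    n_aligned = length(unique(alignment$protein)),
    n_total = nrow(node_map),
    coverage = 100 * .data$n_aligned / .data$n_total
  )
}

#' GO-term entropy of one matchset
#'
#' Pools all term occurrences (with multiplicity across proteins) of the
#' chosen aspect over the proteins of the matchset. With `d` distinct terms
#' and `p_i` the proportion of the i-th term among all pooled occurrences,
#' the entropy is `E = -sum(p_i * ln p_i)` and the normalized entropy is
#' `NE = E / ln(d)`. A functionally coherent matchset has low entropy; a pure
#' matchset (one term) has `E = 0` and `NE` undefined (`d = 1`), and a
#' matchset with no annotated protein has neither defined.
#'
#' @param m Character vector of protein ids (one matchset).
#' @param annotations Annotation tibble from [read_gaf()] (columns `protein`,
#'   `term`, `aspect`).
#' @param aspect One of `"all"` (default: pool BP, MF and CC), `"BP"`,
#'   `"MF"`, `"CC"`.
#' @return A one-row tibble with `n_annotated`, `d`, `entropy`,
#'   `norm_entropy` (`NA` where undefined).
#' @export
matchset_entropy <- function(m, annotations, aspect = c("all", "BP", "MF", "CC")) {
  aspect <- rlang::arg_match(aspect)
  ann <- dplyr::filter(annotations, .data$protein %in% m)
  if (aspect != "all") ann <- dplyr::filter(ann, .data$aspect == .env$aspect)
  n_annotated <- length(unique(ann$protein))
  if (nrow(ann) == 0) {
    return(tibble::tibble(
      n_annotated = 0L, d = 0L, entropy = NA_real_, norm_entropy = NA_real_
    ))
  }
  p <- as.numeric(table(ann$term))
  p <- p / sum(p)
  d <- length(p)
  e <- -sum(p * log(p))
  tibble::tibble(
    n_annotated = n_annotated,
    d = d,
    entropy = e,
    norm_entropy = if (d > 1) e / log(d) else NA_real_
  )
}

#' Mean entropy and mean normalized entropy of an alignment
#'
#' The mean entropy (ME) is the arithmetic mean of `E` over matchsets with at
#' least one annotated protein; the mean normalized entropy (MNE) averages
#' `NE` over matchsets where it is defined (`d >= 2`). Lower values indicate
#' more functionally coherent matchsets. Skipped matchsets are counted and
#' reported.
#'
#' @param alignment Alignment tibble (columns `matchset`, `protein`).
#' @inheritParams matchset_entropy
#' @return A list of class `entropy_report` with `$matchsets` (per-matchset
#'   tibble) and `$summary` (one-row tibble with `me`, `mne`, counts).
#' @export
mean_entropies <- function(alignment, annotations, aspect = c("all", "BP", "MF", "CC")) {
  aspect <- rlang::arg_match(aspect)
  alignment <- check_alignment(alignment)
  sets <- split(alignment$protein, alignment$matchset)
  per <- purrr::imap_dfr(sets, function(m, id) {
    dplyr::mutate(
      matchset_entropy(m, annotations, aspect),
      matchset = as.integer(id), size = length(m), .before = 1
    )
  })
  scored <- per[!is.na(per$entropy), , drop = FALSE]
  ne_ok <- per[!is.na(per$norm_entropy), , drop = FALSE]
  summary <- tibble::tibble(
    aspect = aspect,
    n_matchsets = length(sets),
    n_scored = nrow(scored),
    n_skipped_entropy = length(sets) - nrow(scored),
    n_scored_ne = nrow(ne_ok),
    me = if (nrow(scored) > 0) mean(scored$entropy) else NA_real_,
    mne = if (nrow(ne_ok) > 0) mean(ne_ok$norm_entropy) else NA_real_
  )
  structure(list(matchsets = per, summary = summary), class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  s <- x$summary
  cat("<entropy_report> aspect=", s$aspect, ": ",
    s$n_scored, "/", s$n_matchsets, " matchsets scored; ME=",
    format(s$me, digits = 4), ", MNE=", format(s$mne, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.entropy_report <- function(x, ...) x$matchsets

#' @export
glance.entropy_report <- function(x, ...) x$summary
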