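#' Read a PPI network from a tab-separated edge list
#'
#' The expected dialect is the usual IntAct-derived export: one interaction
#' per line, the first two tab-separated columns holding protein identifiers,
#' any further columns ignored, lines starting with `#` skipped. Self-loops
#' are dropped and duplicate edges (in either orientation) are collapsed.
#'
#' @param path Path to the edge-list file.
#' @param network_id Short label for the network (e.g. a species tag).
#' @return A [ppi_network].
#' @seealso [write_ppi_network()]
#' @export
read_ppi_network <- function(path, network_id) {
  lines <- read_nonempty_lines(path)
  keep <- !startsWith(lines$text, "#")
  lines <- lines[keep, , drop = FALSE]
  if (nrow(lines) == 0) {
    abort(paste0("no interaction lines in '", path, "'"))
  }
  fields <- stringr::str_split(lines$text, "\t")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed edge list '", path, "': line ", lines$lineno[bad[1]],
      " has fewer than 2 tab-separated fields"
    ))
  }
  edges <- tibble::tibble(
    from = purrr::map_chr(fields, 1),
    to = purrr::map_chr(fields, 2)
  )
  ppi_network(edges, id = network_id)
}

#' @rdname read_ppi_network
#' @param network A `ppi_network` to serialise.
#' @export
write_ppi_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  readr::write_tsv(
    tibble::tibble(from = as.character(el[, 1]), to = as.character(el[, 2])),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Read tabular BLAST output
#'
#' Parses the standard 12-column tabular format (`-outfmt 6`: qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore)
#' and drops hits whose e-value exceeds the cutoff. Both directions of a
#' reciprocal hit are retained as separate records; direction merging happens
#' later in [build_candidates()].
#'
#' @param path Path to the BLAST tabular file.
#' @param evalue_cutoff Keep only records with e-value `<=` this cutoff.
#'   The cutoff controls how many candidate pairs enter the alignment; the
#'   default `1e-7` is a common stringency for cross-species protein BLAST.
#' @return A tibble with columns `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path, evalue_cutoff = 1e-7) {
  lines <- read_nonempty_lines(path)
  if (nrow(lines) == 0) {
    return(tibble::tibble(
      query = character(), subject = character(),
      evalue = double(), bitscore = double()
    ))
  }
  fields <- stringr::str_split(lines$text, "\t")
  bad <- which(lengths(fields) != 12)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed BLAST tabular file '", path, "': line ",
      lines$lineno[bad[1]], " has ", lengths(fields)[bad[1]],
      " fields (expected 12)"
    ))
  }
  evalue <- suppressWarnings(as.numeric(purrr::map_chr(fields, 11)))
  bitscore <- suppressWarnings(as.numeric(purrr::map_chr(fields, 12)))
  bad <- which(is.na(evalue) | is.na(bitscore))
  if (length(bad) > 0) {
    abort(paste0(
      "non-numeric e-value or bit score in '", path, "' at line ",
      lines$lineno[bad[1]]
    ))
  }
  tibble::tibble(
    query = purrr::map_chr(fields, 1),
    subject = purrr::map_chr(fields, 2),
    evalue = evalue,
    bitscore = bitscore
  ) |>
    dplyr::filter(.data$evalue <= evalue_cutoff)
}

#' Read a GAF 2.x annotation file
#'
#' Comment lines start with `!`. The aspect column (P/F/C) is mapped to
#' BP/MF/CC, rows whose qualifier contains `NOT` are excluded, and the
#' DB object id (column 2) is used as the protein identifier. Terms are kept
#' as flat identifiers; no propagation through the ontology graph is done.
#'
#' @param path Path to a GAF file.
#' @return A tibble with columns `protein`, `term`, `aspect` (one row per
#'   annotation occurrence; duplicated rows are collapsed).
#' @export
read_gaf <- function(path) {
  lines <- read_nonempty_lines(path)
  keep <- !startsWith(lines$text, "!")
  lines <- lines[keep, , drop = FALSE]
  empty <- tibble::tibble(
    protein = character(), term = character(), aspect = character()
  )
  if (nrow(lines) == 0) {
    return(empty)
  }
  fields <- stringr::str_split(lines$text, "\t")
  bad <- which(lengths(fields) < 15)
  if (length(bad) > 0) {
    abort(paste0(
      "malformed GAF file '", path, "': line ", lines$lineno[bad[1]],
      " has ", lengths(fields)[bad[1]], " columns (expected >= 15)"
    ))
  }
  aspect_map <- c(P = "BP", F = "MF", C = "CC")
  aspect_raw <- purrr::map_chr(fields, 9)
  bad <- which(!aspect_raw %in% names(aspect_map))
  if (length(bad) > 0) {
    abort(paste0(
      "unknown GO aspect '", aspect_raw[bad[1]], "' in '", path,
      "' at line ", lines$lineno[bad[1]]
    ))
  }
  tibble::tibble(
    protein = purrr::map_chr(fields, 2),
    qualifier = purrr::map_chr(fields, 4),
    term = purrr::map_chr(fields, 5),
    aspect = unname(aspect_map[aspect_raw])
  ) |>
    dplyr::filter(!stringr::str_detect(.data$qualifier, "\\bNOT\\b")) |>
    dplyr::select("protein", "term", "aspect") |>
    dplyr::distinct()
}

#' Read and write matchset alignment files
#'
#' One matchset per line, tab-separated protein identifiers (the format used
#' by several multiple-network aligners). Matchsets in one alignment are
#' mutually disjoint: a protein may appear on at most one line.
#'
#' @param path File path.
#' @return `read_alignment()` returns an alignment tibble with columns
#'   `matchset` (integer) and `protein`; `write_alignment()` returns `path`
#'   invisibly.
#' @export
read_alignment <- function(path) {
  lines <- read_nonempty_lines(path)
  if (nrow(lines) == 0) {
    return(tibble::tibble(matchset = integer(), protein = character()))
  }
  fields <- stringr::str_split(lines$text, "\t")
  out <- tibble::tibble(
    matchset = rep(seq_along(fields), lengths(fields)),
    protein = unlist(fields)
  )
  dup <- out$protein[duplicated(out$protein)]
  if (length(dup) > 0) {
    abort(paste0(
      "invalid alignment '", path, "': protein '", dup[1],
      "' appears in more than one matchset"
    ))
  }
  out
}

#' @rdname read_alignment
#' @param alignment An alignment tibble (columns `matchset`, `protein`), as
#'   returned by [components_from_edges()] or [tidy()] on an annealing fit.
#' @export
write_alignment <- function(alignment, path) {
  alignment <- check_alignment(alignment)
  sets <- split(alignment$protein, alignment$matchset)
  writeLines(vapply(sets, paste, character(1), collapse = "\t"), path)
  invisible(path)
}

# internal: alignment tibble contract (disjoint matchsets)
check_alignment <- function(alignment) {
  if (!all(c("matchset", "protein") %in% names(alignment))) {
    abort("an alignment needs `matchset` and `protein` columns.")
  }
  if (anyDuplicated(alignment$protein)) {
    abort("matchsets must be mutually disjoint: duplicated protein id.")
  }
  tibble::as_tibble(alignment)
}

# internal: non-empty lines with original line numbers
read_nonempty_lines <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: '", path, "'"))
  text <- readr::read_lines(path)
  tibble::tibble(lineno = seq_along(text), text = text) |>
    dplyr::filter(.data$text != "")
}
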