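# Shared fixtures: everything is generated in code at test time.

# homology table in BLAST 12-column layout -> reader-style records
as_records <- function(blast_tbl) {
  tibble::tibble(
    query = blast_tbl$qseqid,
    subject = blast_tbl$sseqid,
    evalue = blast_tbl$evalue,
    bitscore = blast_tbl$bitscore
  )
}

# small two-network instance with exactly `m` candidate edges (true orthologs
# plus an equal helping of background pairs), for optimizer tests
small_instance <- function(m = 10, seed = 1, alpha = 0.5) {
  inst <- synthetic_instance(
    n = 8, mean_degree = 3, k = 2, p_del = 0.1, p_add = 0.1,
    background_rate = 1, seed = seed
  )
  omega <- normalize_sequence_scores(
    build_candidates(as_records(inst$homology), inst$networks)
  )
  feats <- network_features(inst$networks)
  cand <- enumerate_candidates(inst$networks, omega, feats, alpha = alpha)
  if (nrow(cand) > m) {
    cand <- cand[sort(sample.int(nrow(cand), m)), , drop = FALSE]
  }
  list(candidates = cand, features = feats, networks = inst$networks)
}

# independent alignment-score recomputation: builds the full pair-score
# matrix directly from the definitions, no shared code with the scorer
oracle_alignment_score <- function(alignment, candidates, features, alpha = 0.5) {
  if (nrow(alignment) == 0) return(0)
  fm <- as.matrix(features[c("gamma", "sigma", "tau", "eta", "theta")])
  rownames(fm) <- features$node
  sh_key <- paste(pmin(candidates$u, candidates$v), pmax(candidates$u, candidates$v))
  total <- 0
  for (ms in split(alignment$protein, alignment$matchset)) {
    if (length(ms) < 2) next
    for (i in seq_len(length(ms) - 1)) {
      for (j in seq(i + 1, length(ms))) {
        a <- ms[i]; b <- ms[j]
        hit <- match(paste(min(a, b), max(a, b)), sh_key)
        sh <- if (is.na(hit)) 0 else candidates$s_h[hit]
        st <- exp(-0.5 * sum((fm[a, ] - fm[b, ])^2))
        total <- total + alpha * sh + (1 - alpha) * st
      }
    }
  }
  total
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
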