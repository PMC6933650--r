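toy_networks <- function() {
  list(
    ppi_network(rbind(c("a1", "a2"), c("a2", "a3"), c("a3", "a4"), c("a4", "a5")), id = "A"),
    ppi_network(rbind(c("b1", "b2"), c("b2", "b3"), c("b3", "b4"), c("b4", "b5")), id = "B")
  )
}

test_that("coverage is the percentage of proteins in any matchset", {
  nets <- toy_networks()
  full <- tibble::tibble(
    matchset = rep(1:5, each = 2),
    protein = c(rbind(paste0("a", 1:5), paste0("b", 1:5)))
  )
  expect_equal(alignment_coverage(full, nets)$coverage, 100)
  empty <- tibble::tibble(matchset = integer(), protein = character())
  expect_equal(alignment_coverage(empty, nets)$coverage, 0)
  partial <- tibble::tibble(
    matchset = c(1L, 1L, 1L, 1L),
    protein = c("a1", "a2", "b1", "b2")
  )
  cov <- alignment_coverage(partial, nets)
  expect_equal(cov$n_aligned, 4)
  expect_equal(cov$coverage, 40)
  bad <- tibble::tibble(matchset = 1L, protein = "ghost")
  expect_error(alignment_coverage(bad, nets), "absent from every network")
})

ann_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    protein = vapply(rows, `[[`, character(1), 1),
    term = vapply(rows, `[[`, character(1), 2),
    aspect = vapply(rows, function(r) if (length(r) > 2) r[[3]] else "BP", character(1))
  )
}

test_that("matchset entropy follows the Shannon formulas", {
  pure <- ann_tbl(c("p1", "GO:1"), c("p2", "GO:1"), c("p3", "GO:1"))
  e <- matchset_entropy(c("p1", "p2", "p3"), pure)
  expect_equal(e$d, 1)
  expect_equal(e$entropy, 0)
  expect_true(is.na(e$norm_entropy)) # NE undefined at d = 1

  half <- ann_tbl(c("p1", "GO:1"), c("p2", "GO:2"))
  e <- matchset_entropy(c("p1", "p2"), half)
  expect_equal(e$entropy, log(2), tolerance = 1e-12)
  expect_equal(e$norm_entropy, 1, tolerance = 1e-12)

  # proportions (1/2, 1/4, 1/4): E = 1.5 ln 2, NE = 1.5 ln 2 / ln 3
  skewed <- ann_tbl(
    c("p1", "GO:1"), c("p2", "GO:1"), c("p3", "GO:2"), c("p4", "GO:3")
  )
  e <- matchset_entropy(paste0("p", 1:4), skewed)
  expect_equal(e$entropy, 1.5 * log(2), tolerance = 1e-12)
  expect_equal(e$norm_entropy, 1.5 * log(2) / log(3), tolerance = 1e-12)

  none <- matchset_entropy(c("q1", "q2"), pure)
  expect_equal(none$d, 0)
  expect_true(is.na(none$entropy))
})

test_that("term multiplicity across proteins drives the proportions", {
  # GO:1 annotates 3 of 4 proteins -> p = (3/4, 1/4)
  ann <- ann_tbl(c("p1", "GO:1"), c("p2", "GO:1"), c("p3", "GO:1"), c("p4", "GO:2"))
  e <- matchset_entropy(paste0("p", 1:4), ann)
  expect_equal(e$entropy, -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-12)
  # duplicating every protein's annotation multiset changes nothing
  doubled <- dplyr::bind_rows(
    ann,
    dplyr::mutate(ann, protein = paste0(protein, "_copy"))
  )
  e2 <- matchset_entropy(c(paste0("p", 1:4), paste0("p", 1:4, "_copy")), doubled)
  expect_equal(e2$d, e$d)
  expect_equal(e2$entropy, e$entropy, tolerance = 1e-12)
  expect_equal(e2$norm_entropy, e$norm_entropy, tolerance = 1e-12)
})

test_that("aspects filter the pooled terms", {
  ann <- ann_tbl(
    c("p1", "GO:1", "BP"), c("p2", "GO:2", "MF"), c("p1", "GO:3", "MF")
  )
  all_terms <- matchset_entropy(c("p1", "p2"), ann, aspect = "all")
  expect_equal(all_terms$d, 3)
  bp <- matchset_entropy(c("p1", "p2"), ann, aspect = "BP")
  expect_equal(bp$d, 1)
  cc <- matchset_entropy(c("p1", "p2"), ann, aspect = "CC")
  expect_equal(cc$d, 0)
})

test_that("mean entropies average over scored matchsets and count skips", {
  ann <- ann_tbl(
    c("p1", "GO:1"), c("p2", "GO:1"), # matchset 1: pure, E = 0
    c("p3", "GO:1"), c("p4", "GO:2") # matchset 2: E = ln 2
  )
  aln <- tibble::tibble(
    matchset = c(1L, 1L, 2L, 2L, 3L, 3L),
    protein = c("p1", "p2", "p3", "p4", "q1", "q2") # matchset 3 unannotated
  )
  rep <- mean_entropies(aln, ann)
  expect_equal(rep$summary$me, log(2) / 2, tolerance = 1e-12)
  expect_equal(rep$summary$mne, 1) # only matchset 2 has NE defined
  expect_equal(rep$summary$n_scored, 2)
  expect_equal(rep$summary$n_skipped_entropy, 1)
  expect_equal(rep$summary$n_scored_ne, 1)
})

test_that("report means match a direct recomputation on a random fixture", {
  set.seed(77)
  inst <- synthetic_instance(n = 30, k = 2, purity = 0.6, seed = 77)
  truth_groups <- split(inst$truth$node, inst$truth$ancestor)
  aln <- tibble::tibble(
    matchset = rep(seq_along(truth_groups), lengths(truth_groups)),
    protein = unlist(truth_groups)
  )
  rep <- mean_entropies(aln, inst$annotations)
  # independent recomputation straight from the definitions
  es <- nes <- c()
  for (ms in truth_groups) {
    terms <- inst$annotations$term[inst$annotations$protein %in% ms]
    if (length(terms) == 0) next
    p <- as.numeric(table(terms)) / length(terms)
    e <- -sum(p * log(p))
    es <- c(es, e)
    if (length(p) > 1) nes <- c(nes, e / log(length(p)))
  }
  expect_equal(rep$summary$me, mean(es), tolerance = 1e-12)
  expect_equal(rep$summary$mne, mean(nes), tolerance = 1e-12)
  expect_true(all(rep$matchsets$norm_entropy >= 0 | is.na(rep$matchsets$norm_entropy)))
  expect_true(all(rep$matchsets$norm_entropy <= 1 | is.na(rep$matchsets$norm_entropy)))
})
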