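test_that("candidate enumeration is complete, scored and deterministic", {
  inst <- small_instance(m = Inf, seed = 2)
  cand <- inst$candidates
  expect_true(all(c("u", "v", "s_h", "s_t", "score") %in% names(cand)))
  expect_equal(cand$score, 0.5 * cand$s_h + 0.5 * cand$s_t)
  expect_false(is.unsorted(cand$u))
  inst2 <- small_instance(m = Inf, seed = 2)
  expect_identical(cand, inst2$candidates)
})

test_that("the worked-example all-vs-all candidate set has a unit diagonal", {
  nets <- example_networks()
  a <- paste0("a", 1:5)
  b <- paste0("b", 1:5)
  rec <- tidyr::expand_grid(query = a, subject = b) |>
    dplyr::mutate(evalue = 1e-20, bitscore = 100)
  omega <- normalize_sequence_scores(build_candidates(rec, nets))
  cand <- enumerate_candidates(nets, omega, alpha = 0)
  expect_equal(nrow(cand), 25)
  diag_rows <- cand[sub("a", "", cand$u) == sub("b", "", cand$v), ]
  expect_equal(diag_rows$s_t, rep(1, 5))
  expect_error(
    enumerate_candidates(nets, omega[0, ]),
    "relax the e-value cutoff"
  )
})

test_that("move proposals hit the 0.45/0.45/0.10 mixture and fall back safely", {
  withr::with_seed(8, {
    types <- replicate(10000, propose_move(1:5, 10)$type)
  })
  freq <- table(types) / 10000
  expect_equal(unname(freq[["add"]]), 0.45, tolerance = 0.05)
  expect_equal(unname(freq[["remove"]]), 0.45, tolerance = 0.05)
  expect_equal(unname(freq[["swap"]]), 0.10, tolerance = 0.25)
  withr::with_seed(1, {
    expect_true(all(replicate(50, propose_move(integer(), 4)$type) == "add"))
    expect_true(all(replicate(50, propose_move(1:4, 4)$type) == "remove"))
  })
})

test_that("the Metropolis rule accepts improvements surely, losses exponentially", {
  withr::with_seed(10, {
    expect_true(metropolis_accept(0, temp = 0.5, s = 1))
    expect_true(all(replicate(20, metropolis_accept(2, temp = 1e-6, s = 1))))
    rate <- mean(replicate(20000, metropolis_accept(-0.5, temp = 1, s = 0.5)))
  })
  expect_equal(rate, exp(-1), tolerance = 0.02)
  expect_error(metropolis_accept(NaN, 1, 1), "finite")
  # acceptance probability increases with temperature
  probs <- exp(-0.3 / (c(0.01, 0.1, 1, 10) * 1))
  expect_true(all(diff(probs) > 0))
})

test_that("annealing finds the unique optimum of trivial instances", {
  inst <- small_instance(m = 1, seed = 6)
  fit <- anneal(inst$candidates, inst$features,
    schedule = anneal_schedule(steps = 50, levels = 20), seed = 1
  )
  expect_equal(fit$selected, 1L)
  expect_equal(fit$best_score, inst$candidates$score[1], tolerance = 1e-9)
})

test_that("a fixed seed reproduces the trajectory exactly", {
  inst <- small_instance(m = 10, seed = 15)
  sched <- anneal_schedule(steps = 100, levels = 20)
  f1 <- anneal(inst$candidates, inst$features, schedule = sched, seed = 99)
  f2 <- anneal(inst$candidates, inst$features, schedule = sched, seed = 99)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$trajectory, f2$trajectory)
  expect_identical(f1$best_score, f2$best_score)
})

test_that("the best-so-far score never decreases and matches a recompute", {
  inst <- small_instance(m = 12, seed = 23)
  fit <- anneal(inst$candidates, inst$features,
    schedule = anneal_schedule(steps = 200, levels = 30), seed = 5,
    max_matchset_size = 3
  )
  expect_true(all(diff(fit$trajectory$best_score) >= 0))
  sc <- make_scorer(inst$features, inst$candidates)
  expect_equal(
    alignment_score(fit$alignment, sc), fit$best_score,
    tolerance = 1e-9
  )
  expect_true(all(table(fit$alignment$matchset) <= 3)) # cap respected
})

test_that("a matchset-size cap forces the higher-scoring of two conflicting edges", {
  # two candidates share a protein; under cap 2 only one can be selected
  nets <- list(
    ppi_network(rbind(c("u", "u2")), id = "A"),
    ppi_network(rbind(c("x", "y")), id = "B")
  )
  feats <- network_features(nets)
  cand <- tibble::tibble(
    u = c("u", "u"), v = c("x", "y"),
    s_h = c(1, 0.1)
  ) |>
    dplyr::mutate(
      s_t = 1, # alpha = 1 makes topology irrelevant
      score = s_h
    )
  bf <- brute_force_optimum(cand, feats, alpha = 1, max_matchset_size = 2)
  expect_equal(bf$selected, 1L)
  fit <- anneal(cand, feats,
    alpha = 1, max_matchset_size = 2,
    schedule = anneal_schedule(steps = 100, levels = 20), seed = 3
  )
  expect_equal(fit$selected, 1L)
  # unconstrained, both edges merge into one triple
  bf2 <- brute_force_optimum(cand, feats, alpha = 1)
  expect_setequal(bf2$selected, 1:2)
})

test_that("exhaustive search selects all disjoint positive edges and bounds anneal", {
  inst <- small_instance(m = 4, seed = 30)
  feats <- inst$features
  bf <- brute_force_optimum(inst$candidates, feats)
  expect_true(bf$score >= 0)
  expect_error(
    brute_force_optimum(inst$candidates[rep(1, 21), ], feats),
    "20 candidate"
  )
  empty <- brute_force_optimum(inst$candidates[0, ], feats)
  expect_equal(empty$score, 0)
  # annealing can never beat the exhaustive optimum
  for (seed in 1:5) {
    inst <- small_instance(m = 9, seed = seed + 50)
    bf <- brute_force_optimum(inst$candidates, inst$features, max_matchset_size = 3)
    fit <- anneal(inst$candidates, inst$features,
      schedule = anneal_schedule(cooling = 0.95, steps = 100, levels = 40),
      seed = seed, max_matchset_size = 3
    )
    expect_lte(fit$best_score, bf$score + 1e-9)
    expect_gte(fit$best_score, 0.95 * bf$score)
  }
})
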