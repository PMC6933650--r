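test_that("reputation scores match closed forms on symmetric graphs", {
  k3 <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")), id = "k3")
  expect_equal(reputation_scores(k3)$gamma, c(1, 1, 1))

  star <- ppi_network(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")), id = "star")
  rep <- reputation_scores(star)
  g <- setNames(rep$gamma, rep$node)
  expect_equal(unname(g["c"]), 1)
  expect_equal(unname(g[c("l1", "l2", "l3")]), rep(1 / sqrt(3), 3), tolerance = 1e-8)
})

test_that("power iteration agrees with a dense eigen-decomposition oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- sample_seed_network(40, mean_degree = 4, id = "rnd")
    rep <- reputation_scores(g)
    a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    comp <- igraph::components(g)
    oracle <- numeric(igraph::vcount(g))
    for (ci in seq_len(comp$no)) {
      idx <- which(comp$membership == ci)
      if (length(idx) == 1) {
        oracle[idx] <- 1
      } else {
        v <- abs(eigen(a[idx, idx, drop = FALSE], symmetric = TRUE)$vectors[, 1])
        oracle[idx] <- v / max(v)
      }
    }
    expect_equal(rep$gamma, oracle, tolerance = 1e-6)
  }
})

test_that("degenerate networks get total reputations", {
  edgeless <- ppi_network(matrix(character(), 0, 2), id = "e", nodes = c("p1", "p2"))
  expect_equal(reputation_scores(edgeless)$gamma, c(1, 1))
  expect_error(
    reputation_scores(ppi_network(matrix(character(), 0, 2), id = "void")),
    "no nodes"
  )
})

test_that("two-step sets exclude the node and its direct neighbours", {
  g1 <- example_networks()$G1
  expect_setequal(two_step_set(g1, "a3"), c("a1", "a5"))
  k3 <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")), id = "k3")
  expect_length(two_step_set(k3, "a"), 0)
  path4 <- ppi_network(rbind(c("p1", "p2"), c("p2", "p3"), c("p3", "p4")), id = "p")
  expect_identical(two_step_set(path4, "p1"), "p3")
  expect_error(two_step_set(g1, "zz"), "unknown node")
})

test_that("shortest-path counts equal common-neighbour counts at distance 2", {
  g1 <- example_networks()$G1
  expect_equal(shortest_path_count(g1, "a4", "a2"), 2) # via a1 and via a5
  path3 <- ppi_network(rbind(c("p1", "p2"), c("p2", "p3")), id = "p")
  expect_equal(shortest_path_count(path3, "p1", "p3"), 1)
  c4 <- ppi_network(rbind(c("x1", "x2"), c("x2", "x3"), c("x3", "x4"), c("x4", "x1")), id = "c")
  expect_equal(shortest_path_count(c4, "x1", "x3"), 2)
  expect_error(shortest_path_count(g1, "a1", "a2"), "distance 2")
})

test_that("feature identities hold by recomputation on random graphs", {
  for (seed in c(2, 9)) {
    set.seed(seed)
    g <- sample_seed_network(25, mean_degree = 4, id = "rnd")
    feats <- node_features(g)
    gamma <- setNames(feats$gamma, feats$node)
    for (v in feats$node) {
      nb <- names(igraph::neighbors(g, v))
      expect_equal(feats$tau[feats$node == v], sum(gamma[nb]))
      n2 <- two_step_set(g, v)
      expect_equal(feats$eta[feats$node == v], length(n2))
      theta <- if (length(n2)) {
        0.5 * sum(gamma[n2] * vapply(n2, function(x) shortest_path_count(g, x, v), numeric(1)))
      } else {
        0
      }
      expect_equal(feats$theta[feats$node == v], unname(theta))
    }
  }
})

test_that("automorphic nodes of the worked example get identical tuples", {
  feats <- node_features(example_networks()$G1)
  expect_equal(
    unlist(feats[feats$node == "a1", -1]),
    unlist(feats[feats$node == "a5", -1])
  )
})

test_that("an isolated node has only its reputation", {
  g <- ppi_network(rbind(c("a", "b")), id = "iso", nodes = c("a", "b", "z"))
  feats <- node_features(g)
  z <- feats[feats$node == "z", ]
  expect_equal(unname(unlist(z[c("sigma", "tau", "eta", "theta")])), c(0, 0, 0, 0))
  expect_equal(z$gamma, 1) # its own singleton component
})

test_that("feature vectors are invariant under node relabelling", {
  set.seed(7)
  g <- sample_seed_network(20, mean_degree = 4, id = "orig")
  perm <- sample(igraph::V(g)$name)
  relabel <- setNames(perm, igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  g2 <- ppi_network(
    cbind(relabel[el[, 1]], relabel[el[, 2]]),
    id = "perm", nodes = unname(relabel)
  )
  key <- function(f) {
    m <- round(as.matrix(f[c("gamma", "sigma", "tau", "eta", "theta")]), 8)
    m[order(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5]), , drop = FALSE]
  }
  expect_equal(unname(key(node_features(g))), unname(key(node_features(g2))))
  expect_equal(
    unname(key(normalize_features(node_features(g)))),
    unname(key(normalize_features(node_features(g2))))
  )
})

test_that("normalization rescales each coordinate to its per-network maximum", {
  feats <- node_features(example_networks()$G1)
  norm <- normalize_features(feats)
  expect_equal(
    norm$sigma[match(paste0("a", 1:5), norm$node)],
    c(1, 1, 1 / 3, 2 / 3, 1)
  )
  for (col in c("gamma", "sigma", "tau", "eta", "theta")) {
    expect_true(all(norm[[col]] >= 0 & norm[[col]] <= 1))
    expect_equal(max(norm[[col]]), 1) # every coordinate has a nonzero max here
  }
  single <- ppi_network(matrix(character(), 0, 2), id = "s", nodes = "p")
  nf <- normalize_features(node_features(single))
  expect_equal(unname(unlist(nf[-1])), c(1, 0, 0, 0, 0))
})

test_that("Gaussian similarity follows the closed form and its properties", {
  expect_equal(topo_similarity(rep(0.3, 5), rep(0.3, 5)), 1)
  expect_equal(topo_similarity(c(0, 0, 0, 0, 0), c(1, 1, 0, 0, 0)), exp(-1))
  expect_equal(topo_similarity(rep(0, 5), rep(1, 5)), exp(-2.5))
  set.seed(3)
  u <- runif(5); v <- runif(5); w <- runif(5)
  expect_equal(topo_similarity(u, v), topo_similarity(v, u))
  # strictly decreasing in Euclidean distance
  d <- sort(c(
    sqrt(sum((u - v)^2)), sqrt(sum((u - w)^2)), sqrt(sum((v - w)^2))
  ))
  s <- exp(-0.5 * d^2)
  expect_true(all(diff(s) < 0))
})
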