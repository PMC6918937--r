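test_that("threshold binarization keeps ties and reports isolates", {
  set.seed(1)
  m <- matrix(runif(361, 0.1, 0.9), 19)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  g0 <- binarize_by_threshold(m, 0)
  expect_equal(n_edges(g0), 171)                 # complete graph
  ghigh <- binarize_by_threshold(m, max(m) + 0.01)
  expect_equal(n_edges(ghigh), 0)
  expect_length(attr(ghigh, "isolated"), 19)

  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  w <- w + t(w)
  expect_equal(n_edges(binarize_by_threshold(w, 0.35)), 3)
  expect_equal(n_edges(binarize_by_threshold(w, 0.3)), 4)  # tie survives
})

test_that("fixed-degree binarization fixes the edge count with half-up rounding", {
  set.seed(2)
  m <- matrix(runif(361), 19)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  expect_equal(n_edges(binarize_by_degree(m, 6)), 57)   # 19 * 6 / 2
  expect_equal(n_edges(binarize_by_degree(m, 5)), 48)   # round(47.5) half-up
  expect_error(binarize_by_degree(m, 19), "exceeds")

  # all-equal weights: ties resolve to the lexicographically first pairs
  eq <- matrix(1, 5, 5)
  diag(eq) <- 0
  g <- binarize_by_degree(eq, 2)                        # m = 5 edges
  el <- graph_edges(g)
  el <- el[order(el[, 1], el[, 2]), ]
  expect_equal(el, cbind(c(1, 1, 1, 1, 2), c(2, 3, 4, 5, 3)))
})

test_that("clustering coefficient matches closed forms and brute force", {
  tri <- binary_graph(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_equal(clustering_coefficient(tri), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(binary_graph(star)), 0)

  for (s in 1:25) {
    n <- sample(4:8, 1)
    a <- with_seed(s, {
      a <- matrix(0L, n, n)
      a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
      a + t(a)
    })
    g <- binary_graph(a)
    expect_equal(clustering_coefficient(g), oracle_clustering(a),
                 tolerance = 1e-14)
    expect_equal(clustering_coefficient(g),
                 igraph::transitivity(as_igraph(g), type = "localaverage",
                                      isolates = "zero"),
                 tolerance = 1e-12)
  }
})

test_that("characteristic path length matches closed forms and oracles", {
  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(as.numeric(characteristic_path_length(binary_graph(k5))), 1)

  p4 <- matrix(0, 4, 4)
  p4[cbind(1:3, 2:4)] <- 1
  p4 <- p4 + t(p4)
  expect_equal(as.numeric(characteristic_path_length(binary_graph(p4))),
               5 / 3, tolerance = 1e-14)

  for (s in 1:25) {
    n <- sample(4:8, 1)
    a <- random_gnm_graph(n, min(n + 1, n * (n - 1) / 2), seed = 400 + s)
    g <- binary_graph(a)
    expect_equal(as.numeric(characteristic_path_length(g)),
                 oracle_path_length(a), tolerance = 1e-14)
    expect_equal(as.numeric(characteristic_path_length(g)),
                 igraph::mean_distance(as_igraph(g)), tolerance = 1e-12)
  }

  # disconnected: average over reachable pairs, flagged
  two <- matrix(0, 4, 4)
  two[1, 2] <- two[2, 1] <- two[3, 4] <- two[4, 3] <- 1
  L <- characteristic_path_length(binary_graph(two))
  expect_equal(as.numeric(L), 1)
  expect_true(attr(L, "disconnected"))
  expect_error(characteristic_path_length(binary_graph(matrix(0, 3, 3))),
               "no edges")
})

test_that("rewiring preserves the degree sequence and edge count exactly", {
  for (s in 1:10) {
    g <- generate_ws_graph(19, 6, 0.3, seed = s)
    r <- maslov_sneppen_rewire(g, seed = s + 100)
    expect_identical(degrees(r), degrees(g))
    expect_identical(n_edges(r), n_edges(g))
    expect_true(all(diag(r$adj) == 0))
  }
  tri <- binary_graph(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
  expect_identical(maslov_sneppen_rewire(tri, seed = 1)$adj, tri$adj)
  r1 <- maslov_sneppen_rewire(generate_ws_graph(12, 4, 0.2, seed = 3), seed = 8)
  r2 <- maslov_sneppen_rewire(generate_ws_graph(12, 4, 0.2, seed = 3), seed = 8)
  expect_identical(r1$adj, r2$adj)   # deterministic given the seed
})

test_that("small-world index behaves on reference graphs", {
  kn <- binary_graph(matrix(1, 19, 19) - diag(19))
  sw <- small_world(kn, n_nulls = 10, seed = 1)
  expect_identical(sw$sigma, 1)      # rewiring cannot change a complete graph

  ws <- generate_ws_graph(19, 4, 0.1, seed = 1)
  sww <- small_world(ws, n_nulls = 50, seed = 2)
  expect_gt(sww$sigma, 1)

  # triangle-free graph: C_rand can be zero -> sigma undefined
  c4 <- matrix(0, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  c4 <- c4 + t(c4)
  sw4 <- small_world(binary_graph(c4), n_nulls = 5, seed = 1)
  expect_true(is.na(sw4$sigma))
})

test_that("nested graphs keep monotone edge counts and path lengths", {
  set.seed(6)
  m <- matrix(runif(361, 0, 1), 19)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  g_small <- binarize_by_degree(m, 4)
  g_big <- binarize_by_degree(m, 8)
  # top-m selection nests: every edge of the sparser graph is in the denser
  expect_true(all(g_big$adj[g_small$adj == 1] == 1))
  expect_gte(as.numeric(characteristic_path_length(g_small)),
             as.numeric(characteristic_path_length(g_big)))
})

test_that("threshold sweeps flag isolation and track edge monotonicity", {
  set.seed(7)
  m <- matrix(runif(361, 0.05, 0.6), 19)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  sw <- threshold_sweep(m, thresholds = seq(0.1, 0.6, 0.05), n_nulls = 5,
                        seed = 1)
  expect_true(all(diff(sw$n_edges) <= 0))
  # first invalid threshold is the first one exceeding some node's strongest tie
  weakest_hub <- min(apply(m, 1, max))
  expect_equal(min(sw$threshold[!sw$valid & sw$n_isolated > 0]),
               min(sw$threshold[sw$threshold > weakest_hub]))
  expect_true(all(is.na(sw$C[!sw$valid])))

  flat <- matrix(0.5, 19, 19)
  diag(flat) <- 0
  swf <- threshold_sweep(flat, thresholds = c(0.4, 0.5, 0.6), n_nulls = 2,
                         seed = 1)
  expect_equal(swf$n_edges, c(171, 171, 0))   # single transition above 0.5
  expect_error(threshold_sweep(m, thresholds = c(0.3, 0.2)), "increasing")
})

test_that("graph exports are readable by igraph", {
  g <- generate_ws_graph(10, 4, 0.2, seed = 5)
  fp <- tempfile(fileext = ".net")
  fg <- tempfile(fileext = ".graphml")
  write_pajek(g, fp)
  write_graphml(g, fg)
  gp <- igraph::read_graph(fp, format = "pajek")
  gg <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::gsize(gp), n_edges(g))
  expect_equal(igraph::gsize(gg), n_edges(g))
  unlink(c(fp, fg))
})
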