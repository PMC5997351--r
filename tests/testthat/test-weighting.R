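test_that("edge clustering matches hand values on canonical graphs", {
  k3 <- graph_from_pairs(c("A", "B"), c("B", "C"), c("A", "C"))
  expect_equal(edge_clustering(k3), rep(1, 3))

  c4 <- graph_from_pairs(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A"))
  expect_equal(edge_clustering(c4), rep(0.5, 4))

  path <- graph_from_pairs(c("A", "B"), c("B", "C"))
  expect_equal(edge_clustering(path, c("A", "B")), 1)

  expect_error(edge_clustering(path, c("A", "C")), "not present")
  expect_error(edge_clustering(path, c("A", "Z")), "not in network")
})

test_that("edge clustering agrees with the brute-force count and stays in (0,1]", {
  for (s in 1:5) {
    fx <- simulate_ppi_data(n_proteins = 30, edge_prob = 0.12, seed = s)
    g <- fx$network
    el <- oracle_edges(g)
    got <- edge_clustering(g)
    want <- vapply(seq_len(nrow(el)),
                   function(k) oracle_ecc(el, el[k, 1], el[k, 2]),
                   numeric(1))
    expect_equal(got, want)
    expect_true(all(got > 0 & got <= 1))
  }
})

test_that("co-expression similarity rescales Pearson correlation", {
  expect_equal(coexpression_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(coexpression_similarity(c(1, 2, 3), c(3, 2, 1)), 0)
  # zero variance: no evidence either way -> neutral 0.5
  expect_equal(coexpression_similarity(c(1, 2, 3), c(5, 5, 5)), 0.5)
  expect_error(coexpression_similarity(1:3, 1:4), "length")
  set.seed(8)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  expect_equal(coexpression_similarity(x, y), oracle_pcc_rescaled(x, y))
})

test_that("network weights equal ECC x rescaled PCC, bounded in [0,1]", {
  fx <- simulate_ppi_data(n_proteins = 25, seed = 4)
  w <- weight_network(fx$network, fx$expression)
  el <- oracle_edges(fx$network)
  want <- vapply(seq_len(nrow(el)), function(k) {
    oracle_weight(el, fx$expression, el[k, 1], el[k, 2])
  }, numeric(1))
  expect_equal(igraph::E(w)$weight, want)
  expect_true(all(igraph::E(w)$weight >= 0 & igraph::E(w)$weight <= 1))
})

test_that("perfect anticorrelation zeroes a weight regardless of topology", {
  g <- graph_from_pairs(c("A", "B"), c("B", "C"), c("A", "C"))
  expr <- rbind(A = c(1, 2, 3), B = c(3, 2, 1), C = c(1, 2, 3))
  w <- weight_network(g, expr)
  el <- igraph::as_edgelist(w)
  ab <- which((el[, 1] == "A" & el[, 2] == "B") |
                (el[, 1] == "B" & el[, 2] == "A"))
  expect_equal(igraph::E(w)$weight[ab], 0)
  ac <- which((el[, 1] == "A" & el[, 2] == "C") |
                (el[, 1] == "C" & el[, 2] == "A"))
  expect_equal(igraph::E(w)$weight[ac], 1)  # ECC 1 on a triangle, PCC 1
})

test_that("weighted degree sums incident weights and obeys the handshake identity", {
  fx <- simulate_ppi_data(n_proteins = 25, seed = 6)
  w <- weight_network(fx$network, fx$expression)
  sw <- weighted_degree(w)
  expect_equal(sum(sw), 2 * sum(igraph::E(w)$weight))

  g <- igraph::add_vertices(graph_from_pairs(c("A", "B")), 1,
                            name = "LONE")
  igraph::E(g)$weight <- 0.7
  expect_equal(unname(weighted_degree(g, "LONE")), 0)
  expect_equal(unname(weighted_degree(g, "A")), 0.7)
  expect_error(weighted_degree(g, "NOPE"), "unknown")
})

test_that("complex participation follows the direct/indirect definition", {
  # star v-(a,b,c): fix weights by hand via the edge attribute
  g <- graph_from_pairs(c("v", "a"), c("v", "b"), c("v", "c"))
  set_w <- function(g, wab) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- wab[paste(el[, 1], el[, 2])]
    g
  }
  g <- set_w(g, c("v a" = 0.4, "v b" = 0.6, "v c" = 0.9))

  # direct: v in one complex with a and b -> 0.4 + 0.6
  cat1 <- as_complex_catalogue(list(C1 = c("v", "a", "b")))
  expect_equal(unname(complex_participation(g, cat1, "v")), 1.0)

  # multiplicity: two complexes sharing neighbor a count the edge twice
  cat2 <- as_complex_catalogue(list(C1 = c("v", "a"), C2 = c("v", "a", "x")))
  expect_equal(unname(complex_participation(g, cat2, "v")), 0.8)

  # indirect: v in no complex, only complexed neighbors contribute
  cat3 <- as_complex_catalogue(list(C1 = c("a", "z")))
  expect_equal(unname(complex_participation(g, cat3, "v")), 0.4)

  # no participation at all
  cat4 <- as_complex_catalogue(list(C1 = c("y", "z")))
  expect_equal(unname(complex_participation(g, cat4, "v")), 0)

  expect_error(complex_participation(g, cat1, "NOPE"), "unknown")
})

test_that("complex participation matches nested-loop enumeration on fixtures", {
  for (s in 1:3) {
    fx <- simulate_ppi_data(n_proteins = 30, n_complexes = 5, seed = s)
    w <- weight_network(fx$network, fx$expression)
    got <- complex_participation(w, fx$complexes)
    el <- oracle_edges(fx$network)
    want <- vapply(igraph::V(w)$name, function(v) {
      oracle_pc(el, fx$expression, fx$complexes, v)
    }, numeric(1))
    expect_equal(got, want)
    expect_true(all(got >= 0))
    # direct participants are bounded by (#complexes) x weighted degree
    memb <- complex_membership(fx$complexes)
    sw <- weighted_degree(w)
    for (v in names(memb)[names(memb) %in% names(got)]) {
      expect_lte(got[[v]], length(memb[[v]]) * sw[[v]] + 1e-12)
    }
  }
})
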