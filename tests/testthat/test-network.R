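test_that("STRING edge parsing thresholds inclusively and collapses duplicates", {
  edges <- data.frame(a = c("A", "B", "A", "C"), b = c("B", "A", "C", "D"),
                      s = c(400L, 400L, 399L, 850L))
  net <- make_network(edges, min_score = 0.400)
  g <- net$graph
  expect_equal(igraph::ecount(g), 2)             # A-B collapsed, A-C below cut
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_false(igraph::are_adjacent(g, "A", "C"))

  # empty file -> empty network
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), path)
  empty <- load_string_edges(path)
  expect_equal(igraph::vcount(empty$graph), 0)

  # malformed rows are reported with their line number
  writeLines(c("protein1 protein2 combined_score", "A B 500", "A B"), path)
  expect_error(load_string_edges(path), "line 3")
  writeLines(c("A B x"), path)
  expect_error(load_string_edges(path), "non-integer")
})

test_that("taxon prefixes are stripped from protein identifiers", {
  edges <- data.frame(a = "4896.SPAC1", b = "4896.SPAC2", s = 700L)
  net <- make_network(edges, id_prefix_strip = "4896.")
  expect_setequal(igraph::V(net$graph)$name, c("SPAC1", "SPAC2"))
})

test_that("worked small graphs match the closed-form centralities", {
  path <- make_network(data.frame(a = c("A", "B"), b = c("B", "C"),
                                  s = c(500L, 500L)))
  expect_equal(compute_centrality(path, "degree")[["B"]], 2)
  expect_equal(compute_centrality(path, "closeness")[["B"]], 1.0)
  expect_equal(compute_centrality(path, "closeness")[["A"]], 2 / 3)
  expect_equal(compute_centrality(path, "betweenness")[["B"]], 1)
  expect_equal(compute_centrality(path, "betweenness")[["A"]], 0)
  ev <- compute_centrality(path, "eigenvector")
  expect_equal(ev[["B"]], 1)
  expect_equal(ev[["A"]], 1 / sqrt(2), tolerance = 1e-9)
  expect_equal(ev[["C"]], 1 / sqrt(2), tolerance = 1e-9)

  star <- make_network(data.frame(a = "C", b = paste0("L", 1:4),
                                  s = rep(500L, 4)))
  expect_equal(compute_centrality(star, "degree")[["C"]], 4)
  expect_equal(compute_centrality(star, "betweenness")[["C"]], 6)  # (n-1)(n-2)/2

  tri <- make_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A"),
                                 s = rep(500L, 3)))
  expect_equal(unname(compute_centrality(tri, "betweenness")), rep(0, 3))
  expect_equal(unname(compute_centrality(tri, "eigenvector")), rep(1, 3),
               tolerance = 1e-9)
  expect_error(compute_centrality(tri, "pagerank"), "unknown")
})

test_that("all four metrics match brute-force oracles on random small graphs", {
  set.seed(202)
  for (rep in 1:30) {
    k <- sample(3:7, 1)
    el <- random_connected_edges(k)
    nodes <- paste0("N", 1:k)
    edges <- data.frame(a = nodes[el[, 1]], b = nodes[el[, 2]],
                        s = rep(500L, nrow(el)))
    net <- make_network(edges)
    oracle <- oracle_centralities(nodes, cbind(nodes[el[, 1]], nodes[el[, 2]]))
    for (m in c("degree", "closeness", "betweenness", "eigenvector")) {
      got <- compute_centrality(net, m)
      expect_equal(got[nodes], oracle[[m]][nodes], tolerance = 1e-9,
                   label = sprintf("%s on replicate %d", m, rep))
    }
  }
})

test_that("degree bookkeeping invariants hold on random graphs", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(4:7, 1)
    el <- random_connected_edges(k)
    nodes <- paste0("N", 1:k)
    net <- make_network(data.frame(a = nodes[el[, 1]], b = nodes[el[, 2]],
                                   s = rep(500L, nrow(el))))
    deg <- compute_centrality(net, "degree")
    expect_equal(sum(deg), 2 * igraph::ecount(net$graph))
  }
})

test_that("eigenvector centrality is invariant to node relabelling", {
  set.seed(31)
  el <- random_connected_edges(6)
  nodes <- paste0("N", 1:6)
  perm <- sample(6)
  net1 <- make_network(data.frame(a = nodes[el[, 1]], b = nodes[el[, 2]],
                                  s = rep(500L, nrow(el))))
  net2 <- make_network(data.frame(a = nodes[perm[el[, 1]]],
                                  b = nodes[perm[el[, 2]]],
                                  s = rep(500L, nrow(el))))
  ev1 <- compute_centrality(net1, "eigenvector")
  ev2 <- compute_centrality(net2, "eigenvector")
  expect_equal(unname(ev2[nodes[perm]]), unname(ev1[nodes]), tolerance = 1e-8)
})

test_that("centrality features align with genes and flag absences", {
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"), s = c(500L, 500L))
  fun <- make_network(edges)
  phys <- make_network(data.frame(a = "X", b = "Y", s = 800L))
  prof <- centrality_profile(fun, phys, c("A", "B", "C"))
  expect_equal(prof$functional_degree, c(1, 2, 1))
  expect_equal(prof$physical_degree, c(0, 0, 0))
  expect_true(all(prof$functional_present))
  expect_false(any(prof$physical_present))

  expect_error(centrality_profile(phys, phys, c("A", "B", "C")),
               "no genes match")

  tab <- feature_table(data.frame(v = c(1, 2, 3)), c("A", "B", "C"),
                       c(v = "other"), c(v = "continuous"))
  merged <- add_centrality_features(tab, fun, phys)
  expect_equal(sum(merged$group == "network_centrality"), 8)
  expect_equal(merged$data$functional_degree, c(1, 2, 1))
})
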