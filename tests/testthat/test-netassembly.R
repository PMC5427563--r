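test_that("count_pairs matches the closed forms", {
  expect_equal(count_pairs(10), 45)
  expect_equal(count_pairs(10, include_self = TRUE), 55)
  expect_equal(count_pairs(2), 1)
  expect_equal(count_pairs(0), 0)
})

test_that("build_network deduplicates, drops self-pairs and keeps isolated nodes", {
  pairs <- data.frame(protein_a = c("A", "B", "A"),
                      protein_b = c("B", "A", "A"))
  expect_warning(g <- build_network(pairs), "self-pair")
  expect_equal(igraph::ecount(g), 1)
  tri <- data.frame(protein_a = c("A", "B", "C"), protein_b = c("B", "C", "A"))
  g3 <- build_network(tri)
  expect_equal(igraph::ecount(g3), 3)
  expect_equal(igraph::vcount(g3), 3)
  g4 <- build_network(tri, nodes = c("A", "B", "C", "D"))
  expect_equal(igraph::vcount(g4), 4)
  expect_equal(unname(igraph::degree(g4)["D"]), 0)
})

test_that("network_metrics matches closed forms on K3, path and K10", {
  tri <- build_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  m <- network_metrics(tri)
  expect_equal(m$mean_degree, 2)
  expect_equal(m$diameter, 1)
  expect_equal(m$mean_clustering_coefficient, 1)

  path <- build_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  mp <- network_metrics(path)
  expect_equal(mp$mean_degree, 4 / 3)
  expect_equal(mp$diameter, 2)
  expect_equal(mp$mean_clustering_coefficient, 0)

  k10 <- as.data.frame(t(combn(LETTERS[1:10], 2)))
  mk <- network_metrics(build_network(k10))
  expect_equal(mk$mean_degree, 9)
  expect_equal(mk$diameter, 1)
  expect_equal(mk$mean_clustering_coefficient, 1)
  expect_error(network_metrics(igraph::make_empty_graph(0)), "empty")
})

test_that("network metrics agree with the brute-force BFS/triangle oracle", {
  set.seed(71)
  for (case in 1:3) {
    n <- sample(30:120, 1)
    g <- random_network(n, sample(n:(3 * n), 1), seed = case)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    want <- oracle_graph_metrics(adj)
    got <- network_metrics(g)
    expect_equal(got$mean_degree, want$mean_degree)
    expect_equal(got$diameter, want$diameter)
    expect_equal(got$mean_clustering_coefficient, want$mean_clustering,
                 tolerance = 1e-12)
  }
})

test_that("random_network honors exact node/edge counts and simplicity", {
  for (seed in 1:5) {
    g <- random_network(30, 80, seed = seed)
    expect_equal(igraph::vcount(g), 30)
    expect_equal(igraph::ecount(g), 80)
    expect_true(igraph::is_simple(g))
  }
  # forced complete graph
  gk <- random_network(10, 45, seed = 1)
  expect_equal(network_metrics(gk)$mean_clustering_coefficient, 1)
  # edgeless
  g0 <- random_network(5, 0, seed = 1)
  expect_equal(network_metrics(g0)$mean_degree, 0)
  expect_error(random_network(5, 11), "maximum")
  # seeded determinism
  expect_identical(igraph::as_edgelist(random_network(20, 30, seed = 9)),
                   igraph::as_edgelist(random_network(20, 30, seed = 9)))
})

test_that("G(n,m) mean clustering approaches the density over many seeds", {
  n <- 100; m <- 500
  density <- 2 * m / (n * (n - 1))
  ccs <- vapply(1:200, function(s) {
    network_metrics(random_network(n, m, seed = s))$mean_clustering_coefficient
  }, numeric(1))
  expect_equal(mean(ccs), density, tolerance = 0.05)
})

test_that("overlay_reference partitions predicted and reference edge sets", {
  pred <- data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"))
  net <- build_network(pred)
  # identical sets: all true positives
  all_tp <- overlay_reference(net, pred)
  expect_equal(unname(all_tp$summary), c(3, 0, 0))
  # disjoint sets
  other <- data.frame(a = "D", b = "E")
  disj <- overlay_reference(net, other)
  expect_equal(unname(disj$summary["true_positive"]), 0)
  expect_equal(unname(disj$summary["positive_prediction"]), 3)
  expect_equal(unname(disj$summary["false_negative"]), 1)
  # hand-built mixed case; order within a pair must not matter
  ref <- data.frame(a = c("B", "C", "D"), b = c("A", "B", "E"))
  mix <- overlay_reference(net, ref)
  expect_equal(unname(mix$summary), c(2, 1, 1))
  # |TP| + |FN| = |reference|
  expect_equal(mix$summary[["true_positive"]] + mix$summary[["false_negative"]],
               nrow(ref))
  # labels partition the union
  expect_equal(nrow(mix$labels), 4)
  expect_false(anyDuplicated(paste(mix$labels$protein_a, mix$labels$protein_b)) > 0)
})

test_that("hive_groups bins by degree with inclusive boundaries and sorts by clustering", {
  # star-ish construction with controlled degrees via thresholds scaled down
  g <- random_network(40, 120, seed = 2)
  hv <- hive_groups(g, low_max = 5, high_min = 8)
  expect_setequal(unique(hv$axis), intersect(c("low", "medium", "high"), hv$axis))
  deg <- igraph::degree(g)
  for (i in seq_len(nrow(hv))) {
    d <- deg[[hv$node[i]]]
    expected_axis <- if (d < 5) "low" else if (d <= 8) "medium" else "high"
    expect_equal(hv$axis[i], expected_axis)
  }
  # within-axis order ascends in clustering coefficient
  for (ax in unique(hv$axis)) {
    sub <- hv[hv$axis == ax, ]
    expect_true(all(diff(sub$clustering[order(sub$order)]) >= 0))
  }
  # boundary degrees: exactly low_max goes to the medium axis
  star <- build_network(data.frame(a = rep("hub", 5), b = paste0("x", 1:5)))
  hv2 <- hive_groups(star, low_max = 5, high_min = 8)
  expect_equal(hv2$axis[hv2$node == "hub"], "medium")
  expect_true(all(hv2$axis[hv2$node != "hub"] == "low"))
})

test_that("edge list TSV round trips with and without headers", {
  edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(edges, tmp)
  expect_equal(read_edge_list(tmp), edges)
  writeLines(c("X\tY", "Y\tZ"), tmp)
  headless <- read_edge_list(tmp)
  expect_equal(names(headless)[1:2], c("protein_a", "protein_b"))
  expect_equal(nrow(headless), 2)
})
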