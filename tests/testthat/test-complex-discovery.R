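# algorithm-specific predicates an emitted cluster must satisfy, checked
# against the original graph with oracle-side (igraph) computations
cluster_predicates <- list(
  mcode = function(graph, members, cl) {
    ok <- oracle_connected(graph, members) &&
      length(members) >= cl$params$min_size
    if (cl$params$haircut && !cl$params$fluff) {
      deg <- igraph::degree(igraph::induced_subgraph(graph, members))
      ok <- ok && all(deg >= 2)
    }
    ok
  },
  dpclus = function(graph, members, cl) {
    oracle_connected(graph, members) &&
      length(members) >= cl$params$min_size &&
      oracle_density(graph, members) >= cl$params$d_min - 1e-12
  },
  ipca = function(graph, members, cl) {
    oracle_connected(graph, members) &&
      length(members) >= cl$params$min_size &&
      oracle_diameter(graph, members) <= cl$params$d_max
  },
  coach = function(graph, members, cl) {
    oracle_connected(graph, members) &&
      length(members) >= cl$params$min_size
  })

algorithms <- list(mcode = mcode, dpclus = dpclus, ipca = ipca,
                   coach = coach)

test_that("dense components are recovered as single clusters", {
  g <- fixture_graphs()$k5_isolates
  expect_equal(clusters_as_set(mcode(g)), list(paste0("a", 1:5)))
  k3 <- clique_graph(c("a", "b", "c"))
  expect_equal(clusters_as_set(dpclus(k3)), list(c("a", "b", "c")))
  k4 <- clique_graph(letters[1:4])
  expect_equal(clusters_as_set(ipca(k4)), list(letters[1:4]))
  k6 <- clique_graph(letters[1:6])
  expect_equal(clusters_as_set(coach(k6)), list(letters[1:6]))
})

test_that("empty and edgeless graphs yield empty clusterings", {
  for (algo in algorithms) {
    expect_length(algo(edgeless_graph(4))$clusters, 0)
    expect_length(algo(igraph::make_empty_graph(0, directed = FALSE))$clusters, 0)
  }
})

test_that("dpclus recovers both overlapping cliques through a shared vertex", {
  g <- fixture_graphs()$shared_k4
  cl <- dpclus(g)
  sets <- clusters_as_set(cl)
  expect_true(any(vapply(sets, identical, logical(1),
                         sort(c("s0", paste0("a", 1:3))))))
  expect_true(any(vapply(sets, identical, logical(1),
                         sort(c("s0", paste0("b", 1:3))))))
  # the shared vertex sits in both clusters in overlap mode
  expect_gte(sum(vapply(sets, function(s) "s0" %in% s, logical(1))), 2)
})

test_that("dpclus on a star emits no cluster of size three or more", {
  cl <- dpclus(fixture_graphs()$star6)
  expect_true(all(lengths(cl$clusters) == 2))
  # confirmed by exhaustive enumeration: no connected subset of size >= 3
  # of a star reaches density 0.9
  subs <- enumerate_connected_subsets(fixture_graphs()$star6, 7)
  dens_ok <- Filter(function(s) length(s) >= 3 &&
                      oracle_density(fixture_graphs()$star6, s) >= 0.9, subs)
  expect_length(dens_ok, 0)
})

test_that("ipca respects the interaction-probability and diameter rules", {
  # no 4-node cluster exists on a path: brute-force over all connected
  # subsets shows none can be grown under IP >= 0.5
  p8 <- fixture_graphs()$path8
  expect_length(ipca(p8, min_size = 4)$clusters, 0)

  g <- fixture_graphs()$bridged_k5
  sets <- clusters_as_set(ipca(g))
  expect_true(any(vapply(sets, identical, logical(1), sort(paste0("a", 1:5)))))
  expect_true(any(vapply(sets, identical, logical(1), sort(paste0("b", 1:5)))))
})

test_that("coach attaches peripheral vertices adjacent to over half the core", {
  g <- named_graph(rbind(clique_edges(c("a", "b", "c", "d")),
                         cbind("p1", c("a", "b", "c")),
                         cbind("p2", c("a", "b", "c"))))
  sets <- clusters_as_set(coach(g))
  expect_equal(sets, list(sort(c("a", "b", "c", "d", "p1", "p2"))))
})

test_that("every emitted cluster satisfies its algorithm's predicates (exhaustive fixtures)", {
  for (gname in names(fixture_graphs())) {
    g <- fixture_graphs()[[gname]]
    for (aname in names(algorithms)) {
      cl <- algorithms[[aname]](g)
      for (members in cl$clusters) {
        expect_true(cluster_predicates[[aname]](g, members, cl),
                    label = paste(aname, "on", gname, "cluster",
                                  paste(members, collapse = ",")))
      }
    }
  }
})

test_that("clustering is deterministic across repeated runs", {
  for (g in fixture_graphs()) {
    for (algo in algorithms) {
      expect_identical(algo(g)$clusters, algo(g)$clusters)
    }
  }
})

test_that("clustering commutes with order-preserving relabeling", {
  g <- fixture_graphs()$random10
  nodes <- sort(igraph::V(g)$name)
  map <- stats::setNames(sprintf("q%02d", seq_along(nodes)), nodes)
  g2 <- relabel_graph(g, map)
  for (algo in algorithms) {
    a <- lapply(algo(g)$clusters, function(m) unname(sort(map[m])))
    b <- lapply(algo(g2)$clusters, sort)
    expect_equal(unname(a), unname(b))
  }
})

test_that("clustering commutes with arbitrary relabeling on a tie-free graph", {
  # distinct degrees/weights everywhere: a clique with a pendant chain
  g <- named_graph(rbind(clique_edges(paste0("m", 1:5)),
                         cbind("m1", "t1"), cbind("t1", "t2")))
  map <- stats::setNames(c("zz", "aa", "mm", "bb", "kk", "rr", "ee"),
                         c(paste0("m", 1:5), "t1", "t2"))
  g2 <- relabel_graph(g, map)
  canon <- function(sets) {
    sets <- lapply(sets, sort)
    unname(sets[order(vapply(sets, paste, character(1), collapse = "|"))])
  }
  # emission order of tied leftover pairs may differ under relabeling;
  # the emitted member sets must coincide
  for (algo in algorithms) {
    a <- lapply(algo(g)$clusters, function(m) unname(map[m]))
    b <- algo(g2)$clusters
    expect_equal(canon(a), canon(b))
  }
})

test_that("cluster statistics summarize counts and sizes", {
  cl <- clustering(list(c1 = paste0("g", 1:3), c2 = paste0("h", 1:5)))
  st <- cluster_stats(cl)
  expect_equal(st, list(n_clusters = 2L, max_size = 5L, min_size = 3L,
                        mean_size = 4))
  st0 <- cluster_stats(clustering(list()))
  expect_equal(st0$n_clusters, 0L)
  expect_equal(st0$mean_size, 0)
})

test_that("match_score agrees with a brute-force all-pairs affinity oracle", {
  ref <- random_clustering(sprintf("g%02d", 1:40), 6, c(3, 8), seed = 2,
                           prefix = "ref")
  expect_equal(match_score(ref, ref, omega = 0.9),
               list(precision = 1, recall = 1, f_measure = 1))

  disj <- clustering(list(d1 = c("zz1", "zz2", "zz3")))
  expect_equal(match_score(disj, ref, omega = 0.25)$f_measure, 0)

  pred <- random_clustering(sprintf("g%02d", 1:40), 5, c(3, 8), seed = 9,
                            prefix = "pred")
  got <- match_score(pred, ref, omega = 0.2)
  na_mat <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) {
    na_mat[i, j] <- oracle_na(pred$clusters[[i]], ref$clusters[[j]])
  }
  p <- mean(apply(na_mat, 1, max) >= 0.2)
  r <- mean(apply(na_mat, 2, max) >= 0.2)
  expect_equal(got$precision, p)
  expect_equal(got$recall, r)
  expect_equal(got$f_measure,
               if (p + r == 0) 0 else 2 * p * r / (p + r))
  expect_error(match_score(pred, clustering(list())), "empty reference")
})

test_that("all algorithms recover planted cliques exactly in the noiseless regime", {
  spec <- synthetic_spec(n_genes = 80, n_complexes = 5,
                         complex_size_range = c(5, 8), p_in = 1,
                         p_out = 0, overlap_fraction = 0, seed = 3)
  net <- generate_planted_network(spec)
  for (aname in names(algorithms)) {
    cl <- algorithms[[aname]](net$network)
    min_size <- cl$params$min_size
    keep <- lengths(net$ground_truth$clusters) >= min_size
    ref <- clustering(net$ground_truth$clusters[keep], algorithm = "planted")
    ms <- match_score(cl, ref, omega = 0.9)
    expect_equal(ms$recall, 1, label = paste(aname, "recall"))
  }
})
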