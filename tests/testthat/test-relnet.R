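test_that("correlation matrix matches the direct formula and flags degeneracy", {
  set.seed(71)
  m <- matrix(rnorm(25), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:5)))
  S <- correlation_matrix(m)
  for (i in 1:5) {
    for (j in 1:5) {
      xi <- m[i, ]; xj <- m[j, ]
      ref <- sum((xi - mean(xi)) * (xj - mean(xj))) /
        sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
      expect_equal(S[i, j], ref, tolerance = 1e-12)
    }
  }
  dup <- rbind(m, g6 = m[1, ], g7 = -m[1, ])
  S2 <- correlation_matrix(dup)
  expect_equal(S2["g1", "g6"], 1)
  expect_equal(S2["g1", "g7"], -1)

  flat <- rbind(m, g8 = rep(3, 5))
  expect_warning(S3 <- correlation_matrix(flat), "zero-variance")
  expect_false("g8" %in% rownames(S3))
  expect_error(correlation_matrix(m[, 1:2]), "3 samples")
})

test_that("hard thresholding uses strict absolute-value semantics", {
  S <- matrix(c(1, -0.99, 0.98, -0.99, 1, 0.5, 0.98, 0.5, 1), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  A <- threshold_adjacency(S, 0.98)
  expect_equal(A["g1", "g2"], 1L)  # |r| = 0.99 > 0.98, negative correlation
  expect_equal(A["g1", "g3"], 0L)  # r = 0.98 exactly: no edge
  expect_true(all(diag(A) == 0))
  expect_error(threshold_adjacency(S, 1.2), "in \\(0, 1\\)")
  expect_error(threshold_adjacency(S, 0), "in \\(0, 1\\)")
})

test_that("edge count is monotone non-increasing in the threshold", {
  set.seed(72)
  m <- matrix(rnorm(30 * 10), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  S <- correlation_matrix(m)
  thresholds <- seq(0.1, 0.95, by = 0.05)
  counts <- vapply(thresholds, function(r0) sum(threshold_adjacency(S, r0)) / 2,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # near-unity threshold on random data: near-empty graph
  expect_lte(sum(threshold_adjacency(S, 0.999)) / 2, 1)
})

test_that("largest connected component follows size then lexicographic tie rule", {
  A <- matrix(0L, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  # two triangles {a,b,c}, {e,f,g} and isolated d
  for (tri in list(c("a", "b", "c"), c("e", "f", "g"))) {
    A[tri[1], tri[2]] <- A[tri[2], tri[1]] <- 1L
    A[tri[2], tri[3]] <- A[tri[3], tri[2]] <- 1L
    A[tri[1], tri[3]] <- A[tri[3], tri[1]] <- 1L
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c"))

  # path of 5 beats a pair
  B <- matrix(0L, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  for (i in 1:4) B[i, i + 1] <- B[i + 1, i] <- 1L
  B[6, 7] <- B[7, 6] <- 1L
  g2 <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  expect_setequal(igraph::V(largest_connected_component(g2))$name,
                  letters[1:5])
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(73)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    g <- random_graph(n, runif(1, 0.1, 0.5))
    lcc <- largest_connected_component(g)
    memb <- components_unionfind(igraph::as_adjacency_matrix(g, sparse = FALSE))
    sizes <- table(memb)
    expect_equal(igraph::vcount(lcc), max(as.integer(sizes)))
    # the returned node set is exactly one union-find class
    cls <- memb[match(igraph::V(lcc)$name, igraph::V(g)$name)]
    expect_equal(length(unique(cls)), 1)
  }
})

test_that("fast-greedy recovers planted cliques and degenerate graphs", {
  # single clique: one community, Q = 0
  A <- matrix(1L, 5, 5, dimnames = list(paste0("g", 1:5), paste0("g", 1:5)))
  diag(A) <- 0L
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  cl <- fastgreedy_communities(g)
  expect_equal(cl$n_communities, 1)
  expect_equal(cl$modularity, 0, tolerance = 1e-12)

  # two 5-cliques joined by one edge: cliques recovered, Q = exhaustive max
  B <- matrix(0L, 10, 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10)))
  B[1:5, 1:5] <- 1L
  B[6:10, 6:10] <- 1L
  diag(B) <- 0L
  B[5, 6] <- B[6, 5] <- 1L
  g2 <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
  cl2 <- fastgreedy_communities(g2)
  expect_equal(cl2$n_communities, 2)
  expect_equal(length(unique(cl2$membership[1:5])), 1)
  expect_equal(length(unique(cl2$membership[6:10])), 1)
  expect_equal(cl2$modularity, exhaustive_max_modularity(g2), tolerance = 1e-12)

  # edgeless graph: singletons with Q = 0
  g3 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g3)$name <- paste0("g", 1:4)
  cl3 <- fastgreedy_communities(g3)
  expect_equal(cl3$n_communities, 4)
  expect_equal(cl3$modularity, 0)
})

test_that("centralities match hand values on canonical graphs", {
  path <- igraph::make_graph(~ a - b, b - c)
  ct <- centralities(path)
  expect_equal(ct$degree[ct$gene == "b"], 2L)
  expect_equal(ct$betweenness[ct$gene == "b"], 1)

  star <- igraph::make_graph(~ hub - l1, hub - l2, hub - l3)
  cs <- centralities(star)
  expect_equal(cs$betweenness[cs$gene == "hub"], 3)  # C(3,2) bridged pairs
  expect_equal(sort(cs$degree, decreasing = TRUE), c(3L, 1L, 1L, 1L))
})

test_that("hub report ranks deterministically and covers all nodes", {
  A <- matrix(1L, 4, 4, dimnames = list(c("d", "b", "a", "c"),
                                        c("d", "b", "a", "c")))
  diag(A) <- 0L
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  hr <- hub_report(g)
  expect_equal(nrow(hr), 4)
  expect_equal(hr$gene, c("a", "b", "c", "d"))  # equal degrees: id order
  expect_equal(hr$rank_degree, 1:4)
})

test_that("a latent-factor parent gene tops the degree ranking", {
  # children share the factor plus independent noise: parent-child
  # correlation (~0.86) clears a threshold that child-child pairs (~0.74)
  # mostly miss, so the noise-free parent accumulates the most edges
  set.seed(74)
  hits <- replicate(20, {
    n <- 80
    f <- rnorm(n)
    block <- rbind(
      parent = f,
      t(sapply(1:11, function(i) f + rnorm(n, 0, 0.6)))
    )
    rownames(block) <- c("parent", sprintf("child%02d", 1:11))
    colnames(block) <- paste0("s", 1:n)
    net <- relevance_network(block, r0 = 0.8)
    hub_report(net$graph)$gene[1] == "parent"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("gene collapse for networks keeps the highest-variance probe", {
  set.seed(75)
  m <- matrix(rnorm(4 * 8), nrow = 4,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:8)))
  m[2, ] <- m[2, ] * 5  # p2 has the largest variance
  ann <- tibble::tibble(
    probe_id = paste0("p", 1:4),
    gene_symbol = c("GA", "GA", "GB", "unannotated")
  )
  rep <- maturnet:::representative_probes(m, ann)
  expect_setequal(rownames(rep), c("GA", "GB", "p4"))
  expect_equal(rep["GA", ], m[2, ], ignore_attr = TRUE)
})
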