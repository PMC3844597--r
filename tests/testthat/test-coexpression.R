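test_that("Spearman distance matches hand-computed rank correlations", {
  u <- c(1, 2, 3, 4)
  prof <- rbind(u = u, expu = exp(u), rev = rev(u), perm = c(1, 3, 2, 4))
  d <- spearmanDistance(prof)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["u", "expu"], 0)               # monotone transform: rho = 1
  expect_equal(d["u", "rev"], 2)                # reversed ranks: rho = -1
  expect_equal(d["u", "perm"], 0.2)             # rho = 0.8 by hand
  expect_equal(d, t(d))

  # constant profile: sentinel distance 1 with a warning
  prof2 <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(3, 1, 2))
  expect_warning(d2 <- spearmanDistance(prof2), "constant")
  expect_equal(unname(d2["b", c("a", "c")]), c(1, 1))
  expect_error(spearmanDistance(prof[, 1:2]), ">= 3")
})

test_that("the MST matches exhaustive enumeration on small instances", {
  # 3 nodes, distances 1, 2, 3: the two cheapest edges, total weight 3
  d3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree3 <- buildMST(d3)
  expect_equal(sum(igraph::E(treeGraph(tree3))$weight), 3)

  # random instances, n <= 7, against the Pruefer enumeration oracle
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(4:7, 1)
      d <- matrix(0, n, n)
      d[upper.tri(d)] <- round(runif(n * (n - 1) / 2, 0.1, 2), 2)
      d <- d + t(d)
      dimnames(d) <- list(paste0("n", 1:n), paste0("n", 1:n))
    })
    tree <- buildMST(d)
    g <- treeGraph(tree)
    expect_equal(igraph::ecount(g), n - 1L)
    expect_true(igraph::is_connected(g))
    expect_equal(sum(igraph::E(g)$weight), bruteForceMSTWeight(d),
                 tolerance = 1e-12)
    # independent cross-check against igraph's MST total weight
    gi <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(sum(igraph::E(g)$weight),
                 sum(igraph::E(igraph::mst(gi))$weight), tolerance = 1e-12)
  }
  expect_error(buildMST(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(buildMST(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("equal-weight ties resolve to the lexicographically smallest edges", {
  nodes <- c("a", "b", "c")
  d <- matrix(1, 3, 3, dimnames = list(nodes, nodes)); diag(d) <- 0
  g <- treeGraph(buildMST(d))
  el <- igraph::as_edgelist(g)
  pairs <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  expect_equal(pairs, c("a b", "a c"))
})

test_that("walk length equals breadth-first-search distance", {
  # a path graph: endpoints are n - 1 apart, neighbours 1 apart
  n <- 6
  nodes <- sprintf("t%03d", 1:n)
  d <- abs(outer(1:n, 1:n, "-")) / 10
  dimnames(d) <- list(nodes, nodes)
  path_tree <- buildMST(d)   # MST of collinear points is the path
  wl <- walkLength(path_tree)
  expect_equal(wl[1, n], n - 1L)
  expect_equal(wl[2, 3], 1L)

  for (seed in 1:10) {
    tree <- randomTree(25, seed)
    wl <- walkLength(tree)
    bfs <- igraph::distances(treeGraph(tree), weights = NA)
    expect_equal(unname(wl), unname(bfs[treeNodes(tree), treeNodes(tree)]))
  }
  expect_error(walkLength(path_tree, "ghost"), "unknown node")
})

test_that("network extraction follows the walk-length cutoff", {
  # 12-node path; selected nodes spaced <= 4 edges apart form one network
  n <- 12
  nodes <- sprintf("t%03d", 1:n)
  d <- abs(outer(1:n, 1:n, "-")) / 10
  dimnames(d) <- list(nodes, nodes)
  tree <- buildMST(d)
  close_set <- nodes[c(1, 4, 8, 12)]            # gaps 3, 4, 4
  one <- extractNetworks(tree, close_set, cutoff = 4, minNetworkSize = 2)
  expect_equal(length(attr(one, "sizes")), 1)
  expect_true(all(one$network == "net_1"))

  # two groups separated by a 5-edge gap split into two networks
  split_set <- nodes[c(1, 2, 3, 8, 9, 10)]
  two <- extractNetworks(tree, split_set, cutoff = 4, minNetworkSize = 2)
  expect_equal(unname(attr(two, "sizes")), c(3L, 3L))
  expect_equal(length(unique(two$network)), 2)

  # clusters below minNetworkSize become unassigned
  small <- extractNetworks(tree, split_set, cutoff = 4, minNetworkSize = 4)
  expect_true(all(small$network == "unassigned"))
  expect_error(extractNetworks(tree, split_set, cutoff = 0), ">= 1")
  expect_error(extractNetworks(tree, "ghost"), "not in tree")
})

test_that("extraction is order-invariant and refines monotonically with the
           cutoff", {
  for (seed in 1:5) {
    tree <- randomTree(40, seed)
    withr::with_seed(seed + 100, sel <- sample(treeNodes(tree), 18))
    a <- extractNetworks(tree, sel, cutoff = 4, minNetworkSize = 1)
    b <- extractNetworks(tree, rev(sel), cutoff = 4, minNetworkSize = 1)
    expect_identical(a, b)

    # decreasing the cutoff never merges clusters
    fine <- extractNetworks(tree, sel, cutoff = 2, minNetworkSize = 1)
    coarse_part <- a$network[match(fine$probe_id, a$probe_id)]
    split_tab <- table(fine$network, coarse_part)
    expect_true(all(rowSums(split_tab > 0) == 1))
  }
})

test_that("single-linkage cut equals thresholded-graph components", {
  for (seed in 1:10) {
    tree <- randomTree(30, seed)
    withr::with_seed(seed, sel <- sort(sample(treeNodes(tree), 12)))
    nets <- extractNetworks(tree, sel, cutoff = 3, minNetworkSize = 1)
    wl <- walkLength(tree, sel, sel)
    hc <- hclust(as.dist(wl), method = "single")
    sl <- cutree(hc, h = 3.5)
    expect_equal(adjustedRandIndex(nets$network, sl[nets$probe_id]), 1)
  }
})

test_that("trees export as edge lists and GraphML", {
  tree <- randomTree(8, 1)
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  writeTree(tree, ep, gp)
  el <- read.delim(ep)
  expect_equal(nrow(el), 7)
  expect_true(file.size(gp) > 0)
})
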