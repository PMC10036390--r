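path3 <- as_trait_network(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
                          trait_names = c("A", "B", "C"))
triangle <- as_trait_network(matrix(1, 3, 3) - diag(3),
                             trait_names = c("A", "B", "C"))
star4 <- local({
  adj <- matrix(0, 5, 5)
  adj[1, 2:5] <- 1; adj[2:5, 1] <- 1
  as_trait_network(adj, trait_names = c("X", paste0("L", 1:4)))
})
k5 <- as_trait_network(matrix(1, 5, 5) - diag(5))
two_triangles <- local({
  adj <- matrix(0, 6, 6)
  adj[1:3, 1:3] <- 1; adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  as_trait_network(adj)
})

test_that("node metrics on hand-computed fixtures", {
  nm <- node_metrics(path3)
  expect_equal(nm$degree, c(1L, 2L, 1L))
  expect_equal(nm$closeness[nm$trait == "B"], 1)            # 1/mean(1,1)
  expect_equal(nm$closeness[nm$trait == "A"], 1 / 1.5)      # 1/mean(1,2)
  expect_equal(nm$betweenness, c(0, 1, 0))

  nm_star <- node_metrics(star4)
  expect_equal(nm_star$degree[nm_star$trait == "X"], 4L)
  expect_equal(nm_star$betweenness[nm_star$trait == "X"], 6)  # C(4,2) pairs
  expect_equal(nm_star$betweenness[nm_star$trait == "L1"], 0)

  nm_k5 <- node_metrics(k5)
  expect_equal(nm_k5$degree, rep(4L, 5))
  expect_equal(nm_k5$closeness, rep(1, 5))
  expect_equal(nm_k5$betweenness, rep(0, 5))
})

test_that("isolated nodes get closeness 0 and disconnected pairs drop from AL", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1      # one edge + two isolates
  net <- as_trait_network(adj)
  nm <- node_metrics(net)
  expect_equal(nm$closeness, c(1, 1, 0, 0))
  topo <- topology_metrics(net)
  expect_equal(topo$avg_path_length, 1)   # only the connected pair counts
  expect_equal(topo$edge_density, 1 / 6)
})

test_that("topology metrics on hand-computed fixtures", {
  t_tri <- topology_metrics(triangle)
  expect_equal(t_tri$edge_density, 1)
  expect_equal(t_tri$avg_path_length, 1)
  expect_equal(t_tri$avg_clustering, 1)
  expect_equal(modularity_q(triangle, c(1, 1, 1)), 0)  # single-module Q = 0

  t_p3 <- topology_metrics(path3)
  expect_equal(t_p3$edge_density, 2 / 3)
  expect_equal(t_p3$avg_path_length, 4 / 3)
  expect_equal(t_p3$avg_clustering, 0)

  # Newman Q of the planted two-module partition: 2 * (1/2 - 1/4)
  expect_equal(modularity_q(two_triangles, rep(1:2, each = 3)), 0.5)
  t_2t <- topology_metrics(two_triangles)
  expect_equal(t_2t$modularity, 0.5)
  expect_equal(t_2t$n_modules, 2L)
  expect_true(same_partition(attr(t_2t, "modules"), rep(1:2, each = 3)))
})

test_that("degenerate networks are handled explicitly", {
  expect_error(topology_metrics(as_trait_network(matrix(0, 1, 1))),
               class = "traitnet_degenerate_network")
  empty <- as_trait_network(matrix(0, 4, 4))
  topo <- topology_metrics(empty)
  expect_equal(topo$edge_density, 0)
  expect_true(is.na(topo$avg_path_length))
  expect_equal(topo$avg_clustering, 0)
  expect_equal(topo$modularity, 0)
  expect_equal(topo$n_modules, 4L)   # one module per node
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    net <- as_trait_network(adj)
    nm <- node_metrics(net)
    expect_equal(nm$degree, as.integer(rowSums(adj)))
    expect_equal(nm$betweenness, oracle_betweenness(adj), tolerance = 1e-9)
    expect_equal(nm$closeness, oracle_closeness_recip_mean(adj),
                 tolerance = 1e-9)
    topo <- topology_metrics(net)
    expect_equal(topo$avg_path_length, oracle_avg_path_length(adj),
                 tolerance = 1e-9)
    expect_equal(topo$avg_clustering, oracle_avg_clustering(adj),
                 tolerance = 1e-9)
    expect_equal(topo$edge_density, sum(adj) / (n * (n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("metrics cross-check against igraph conventions", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    adj <- random_adjacency(n, 0.5)
    net <- as_trait_network(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    nm <- node_metrics(net)
    expect_equal(nm$betweenness, unname(igraph::betweenness(g)),
                 tolerance = 1e-9)
    if (igraph::is_connected(g)) {
      # igraph closeness = 1/sum; ours = 1/mean = (n-1)/sum
      expect_equal(nm$closeness,
                   unname(igraph::closeness(g)) * (n - 1), tolerance = 1e-9)
      expect_equal(topology_metrics(net)$avg_path_length,
                   igraph::mean_distance(g), tolerance = 1e-9)
    }
    expect_equal(topology_metrics(net)$avg_clustering,
                 igraph::transitivity(g, type = "localaverage", isolates = "zero"),
                 tolerance = 1e-9)
    mem <- network_modules(net)
    expect_equal(modularity_q(net, mem),
                 igraph::modularity(g, mem), tolerance = 1e-9)
  }
})

test_that("all metrics are invariant under node relabeling", {
  set.seed(55)
  adj <- random_adjacency(8, 0.4)
  net <- as_trait_network(adj)
  perm <- sample(8)
  net_p <- as_trait_network(adj[perm, perm])
  nm <- node_metrics(net)
  nm_p <- node_metrics(net_p)
  reord <- match(nm_p$trait, nm$trait)
  expect_equal(nm_p$degree, nm$degree[reord])
  expect_equal(nm_p$betweenness, nm$betweenness[reord], tolerance = 1e-9)
  expect_equal(nm_p$closeness, nm$closeness[reord], tolerance = 1e-9)
  t1 <- topology_metrics(net); t2 <- topology_metrics(net_p)
  expect_equal(t2$edge_density, t1$edge_density)
  expect_equal(t2$avg_path_length, t1$avg_path_length, tolerance = 1e-9)
  expect_equal(t2$avg_clustering, t1$avg_clustering, tolerance = 1e-9)
})

test_that("adding an edge never decreases ED nor increases distances", {
  set.seed(31)
  adj <- random_adjacency(7, 0.3)
  missing <- which(upper.tri(adj) & adj == 0, arr.ind = TRUE)
  skip_if(nrow(missing) == 0)
  pick <- missing[sample(nrow(missing), 1), ]
  adj2 <- adj
  adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
  t1 <- topology_metrics(as_trait_network(adj))
  t2 <- topology_metrics(as_trait_network(adj2))
  expect_gt(t2$edge_density, t1$edge_density)
  d1 <- oracle_distances(adj); d2 <- oracle_distances(adj2)
  expect_true(all(d2 <= d1))
})

test_that("hub and mediator identification ranks and breaks ties as documented", {
  h_star <- identify_hubs(node_metrics(star4), top_n = 1)
  expect_equal(h_star$trait[h_star$role == "hub"], "X")
  expect_equal(h_star$trait[h_star$role == "mediator"], "X")

  # degrees (3, 2, 2, 1): hub list starts with the degree-3 node
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[1, 3] <- adj[1, 4] <- adj[2, 3] <- 1
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  nm <- node_metrics(as_trait_network(adj, trait_names = c("hub", "b", "c", "leaf")))
  h <- identify_hubs(nm, top_n = 2)
  expect_equal(h$trait[h$role == "hub"][1], "hub")

  # K4: everything tied, ranking falls back to name order, flagged
  nm_k4 <- node_metrics(as_trait_network(matrix(1, 4, 4) - diag(4),
                                         trait_names = c("d", "c", "b", "a")))
  h_k4 <- identify_hubs(nm_k4, top_n = 4)
  expect_true(all(h_k4$tied))
  expect_equal(h_k4$trait[h_k4$role == "hub"], c("a", "b", "c", "d"))
  expect_warning(identify_hubs(nm_k4, top_n = 9), "top_n")
})

test_that("greedy community detection recovers well-separated modules", {
  mem <- network_modules(two_triangles)
  expect_true(same_partition(mem, rep(1:2, each = 3)))
  # and is deterministic
  expect_identical(mem, network_modules(two_triangles))
  skip_if_not_installed("igraph")
  mem_l <- network_modules(two_triangles, method = "louvain", seed = 3)
  expect_true(same_partition(mem_l, rep(1:2, each = 3)))
})
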