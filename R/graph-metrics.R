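# Node- and network-level topology metrics on binary undirected graphs,
# computed from first principles (BFS shortest paths, Brandes betweenness,
# Newman modularity with greedy agglomerative community detection).

adjacency_of <- function(net) {
  if (inherits(net, "trait_network")) net$adjacency else as.matrix(net)
}

# all-pairs shortest path lengths by breadth-first search; Inf = unreachable
shortest_path_lengths <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- dist[frontier[1]] + 1
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

# Brandes (2001) betweenness for unweighted undirected graphs: fractional
# credit across tied shortest paths, endpoints excluded, each unordered
# pair counted once.
betweenness_centrality <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1L))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, rownames(adj))
}

# per-node clustering coefficient: 2 * triangles / (k (k - 1)), 0 for k < 2
local_clustering <- function(adj) {
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj) / 2
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  stats::setNames(as.numeric(cc), rownames(adj))
}

#' Node metrics of a trait network
#'
#' Degree (number of neighbours), closeness and betweenness for every trait.
#' Closeness is the reciprocal of the *mean* shortest-path length from the
#' focal trait to the traits it can reach -- not the reciprocal of the sum,
#' which many graph libraries use; the two differ by a factor of (n - 1) on
#' a connected graph.  Isolated traits get closeness 0.  Betweenness counts
#' shortest paths through the focal trait with fractional credit when
#' several shortest paths tie, endpoints excluded.
#'
#' @param net A `trait_network` (or a binary symmetric adjacency matrix).
#' @return Tibble with columns `trait`, `degree`, `closeness`,
#'   `betweenness`, and `group` when the network carries a label.
#' @examples
#' path3 <- as_trait_network(rbind(c(0,1,0), c(1,0,1), c(0,1,0)),
#'                           trait_names = c("A", "B", "C"))
#' node_metrics(path3)
#' @export
node_metrics <- function(net) {
  adj <- adjacency_of(net)
  n <- nrow(adj)
  d <- shortest_path_lengths(adj)
  closeness <- vapply(seq_len(n), function(i) {
    reach <- d[i, ]
    reach <- reach[is.finite(reach) & seq_len(n) != i]
    if (length(reach) == 0L || mean(reach) == 0) 0 else 1 / mean(reach)
  }, numeric(1))
  out <- tibble::tibble(trait = rownames(adj),
                        degree = as.integer(rowSums(adj)),
                        closeness = closeness,
                        betweenness = as.numeric(betweenness_centrality(adj)))
  if (inherits(net, "trait_network") && !is.na(net$group)) out$group <- net$group
  out
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over modules of (e_c / m - (d_c / 2m)^2), where e_c is the number
#' of edges inside module c, d_c its total degree and m the total edge
#' count.  Q of the single-module partition is exactly 0; an empty graph
#' has Q = 0 by convention.
#'
#' @param net A `trait_network` or adjacency matrix.
#' @param membership Integer (or factor) module id per node.
#' @return A single number in \[-0.5, 1\].
#' @export
modularity_q <- function(net, membership) {
  adj <- adjacency_of(net)
  membership <- as.integer(as.factor(membership))
  m <- sum(adj) / 2
  if (m == 0) return(0)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(adj[idx, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# greedy agglomerative modularity maximisation (Clauset-Newman-Moore style):
# start from singletons, repeatedly merge the connected pair of communities
# with the largest modularity gain (ties broken by smallest community index
# pair), and return the partition with the highest Q along the merge path.
greedy_membership <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj) / 2
  if (m == 0 || n == 0) return(seq_len(max(n, 0L)))
  membership <- seq_len(n)
  best_membership <- membership
  best_q <- modularity_q(adj, membership)
  # community-level edge-weight and degree bookkeeping
  e <- adj / (2 * m)            # fraction of edge ends between communities
  a <- rowSums(adj) / (2 * m)   # fraction of edge ends in each community
  alive <- rep(TRUE, n)
  comm_of <- seq_len(n)
  repeat {
    ids <- which(alive)
    if (length(ids) < 2L) break
    best_gain <- -Inf; best_pair <- NULL
    for (ii in seq_along(ids)) {
      i <- ids[ii]
      for (jj in seq_along(ids)) {
        if (jj <= ii) next
        j <- ids[jj]
        if (e[i, j] == 0) next   # merging disconnected communities never helps
        gain <- 2 * (e[i, j] - a[i] * a[j])
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best_pair <- c(i, j)
        }
      }
    }
    if (is.null(best_pair)) break  # remaining communities mutually disconnected
    i <- best_pair[1]; j <- best_pair[2]
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[, i] + e[, j]
    e[i, i] <- e[i, i]           # diagonal already accumulated via both adds
    a[i] <- a[i] + a[j]
    alive[j] <- FALSE
    e[j, ] <- 0; e[, j] <- 0; a[j] <- 0
    comm_of[comm_of == j] <- i
    q <- modularity_q(adj, comm_of)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_membership <- comm_of
    }
  }
  as.integer(as.factor(best_membership))
}

#' Detect trait modules
#'
#' Partitions the network into modules (sets of traits more densely
#' connected among themselves than with the rest).  The default `"greedy"`
#' method is a deterministic agglomerative modularity maximisation
#' implemented in this package; `"leading_eigenvector"` and `"louvain"`
#' delegate to igraph (Louvain under a fixed RNG seed).
#'
#' @param net A `trait_network`.
#' @param method `"greedy"`, `"leading_eigenvector"` or `"louvain"`.
#' @param seed RNG seed used for `"louvain"` (default 1).
#' @return Named integer vector: module id (1-based) per trait.
#' @export
network_modules <- function(net, method = c("greedy", "leading_eigenvector",
                                            "louvain"), seed = 1L) {
  method <- match.arg(method)
  adj <- adjacency_of(net)
  if (method == "greedy") {
    mem <- greedy_membership(adj)
  } else {
    if (!requireNamespace("igraph", quietly = TRUE)) {
      rlang::abort("this community method needs the igraph package",
                   class = "traitnet_config_error")
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comm <- if (method == "leading_eigenvector") {
      igraph::cluster_leading_eigen(g)
    } else {
      old <- .Random.seed_safe()
      on.exit(.restore_seed(old), add = TRUE)
      set.seed(seed)
      igraph::cluster_louvain(g)
    }
    mem <- as.integer(igraph::membership(comm))
  }
  stats::setNames(mem, rownames(adj))
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Global topology metrics of a trait network
#'
#' Edge density ED = 2|E| / (n(n-1)); average path length AL = mean
#' shortest-path length over connected unordered pairs (disconnected pairs
#' excluded; `NA` when the network has no edges); average clustering
#' coefficient AC = mean of per-node clustering coefficients (0 for nodes
#' of degree < 2); modularity Q of the detected module partition, together
#' with the number of modules.
#'
#' @param net A `trait_network` with at least 2 nodes.
#' @param method Community-detection method passed to [network_modules()].
#' @param seed Seed for stochastic community methods.
#' @return A one-row tibble: `group`, `n_nodes`, `n_edges`, `edge_density`,
#'   `avg_path_length`, `avg_clustering`, `modularity`, `n_modules`.  The
#'   module assignment is attached as attribute `"modules"`.
#' @examples
#' tri <- as_trait_network(matrix(1, 3, 3) - diag(3))
#' topology_metrics(tri)
#' @export
topology_metrics <- function(net, method = "greedy", seed = 1L) {
  adj <- adjacency_of(net)
  n <- nrow(adj)
  if (n < 2L) {
    rlang::abort("topology metrics need at least 2 nodes",
                 class = "traitnet_degenerate_network")
  }
  ne <- sum(adj) / 2
  ed <- 2 * ne / (n * (n - 1))
  d <- shortest_path_lengths(adj)
  finite <- d[upper.tri(d)]
  finite <- finite[is.finite(finite) & finite > 0]
  al <- if (length(finite)) mean(finite) else NA_real_
  ac <- mean(local_clustering(adj))
  if (ne == 0) {
    mem <- stats::setNames(seq_len(n), rownames(adj))
    q <- 0
  } else {
    mem <- network_modules(net, method = method, seed = seed)
    q <- modularity_q(adj, mem)
  }
  out <- tibble::tibble(
    group = if (inherits(net, "trait_network")) net$group else NA_character_,
    n_nodes = n, n_edges = as.integer(ne),
    edge_density = ed, avg_path_length = al, avg_clustering = ac,
    modularity = q, n_modules = length(unique(mem)))
  attr(out, "modules") <- mem
  out
}

#' Node and topology metrics for a list of per-group networks
#'
#' @param nets Named list of `trait_network`, e.g. from
#'   [networks_by_group()].
#' @param method,seed Passed to [topology_metrics()].
#' @return `topology_by_group()`: one tibble row per network.
#'   `node_metrics_by_group()`: stacked node-metric rows with a `group`
#'   column and the module id of each trait.
#' @export
topology_by_group <- function(nets, method = "greedy", seed = 1L) {
  dplyr::bind_rows(purrr::imap(nets, function(net, g) {
    row <- topology_metrics(net, method = method, seed = seed)
    row$group <- g
    row
  }))
}

#' @rdname topology_by_group
#' @export
node_metrics_by_group <- function(nets, method = "greedy", seed = 1L) {
  dplyr::bind_rows(purrr::imap(nets, function(net, g) {
    nm <- node_metrics(net)
    nm$group <- g
    mem <- attr(topology_metrics(net, method = method, seed = seed), "modules")
    nm$module <- as.integer(mem[nm$trait])
    nm
  }))
}

#' Identify hub and mediator traits
#'
#' Hub traits are the most connected: ranked by degree, then closeness,
#' both descending.  Mediator traits bridge modules: ranked by betweenness
#' descending.  Ties are broken by trait name (alphabetical) and flagged in
#' the `tied` column.
#'
#' @param nm Node-metrics tibble from [node_metrics()].
#' @param top_n How many traits to return per role (default 3); values
#'   larger than the number of traits return all, with a warning.
#' @return Tibble with columns `role` ("hub" or "mediator"), `rank`,
#'   `trait`, `degree`, `closeness`, `betweenness`, `tied`.
#' @export
identify_hubs <- function(nm, top_n = 3L) {
  if (nrow(nm) == 0L) {
    rlang::abort("empty node metrics", class = "traitnet_insufficient_data")
  }
  if (top_n > nrow(nm)) {
    rlang::warn("top_n exceeds the number of traits; returning all")
    top_n <- nrow(nm)
  }
  rank_role <- function(df, role) {
    df$rank <- seq_len(nrow(df))
    df$role <- role
    df[seq_len(top_n), c("role", "rank", "trait", "degree", "closeness",
                         "betweenness", "tied")]
  }
  hubs <- dplyr::arrange(nm, dplyr::desc(.data$degree),
                         dplyr::desc(.data$closeness), .data$trait)
  hub_key <- paste(hubs$degree, signif(hubs$closeness, 12))
  hubs$tied <- duplicated(hub_key) | duplicated(hub_key, fromLast = TRUE)
  meds <- dplyr::arrange(nm, dplyr::desc(.data$betweenness), .data$trait)
  med_key <- signif(meds$betweenness, 12)
  meds$tied <- duplicated(med_key) | duplicated(med_key, fromLast = TRUE)
  dplyr::bind_rows(rank_role(hubs, "hub"), rank_role(meds, "mediator"))
}
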