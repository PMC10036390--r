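# Brute-force graph oracles, deliberately independent of the package's
# BFS/Brandes implementations: Floyd-Warshall distances, exhaustive
# simple-path enumeration for betweenness, and triple loops for triangles.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# all simple paths from s to t as a list of vertex vectors
oracle_all_paths <- function(adj, s, t) {
  n <- nrow(adj)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) {
      if (!(w %in% path)) walk(c(path, w))
    }
  }
  walk(s)
  out
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq((s + 1), n)) {
      paths <- oracle_all_paths(adj, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + through / length(shortest)
      }
    }
  }
  b
}

oracle_closeness_recip_mean <- function(adj) {
  d <- oracle_distances(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    r <- d[i, -i]
    r <- r[is.finite(r)]
    if (length(r) == 0L) 0 else 1 / mean(r)
  }, numeric(1))
}

oracle_avg_path_length <- function(adj) {
  d <- oracle_distances(adj)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v) & v > 0]
  if (length(v)) mean(v) else NA_real_
}

oracle_avg_clustering <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { cc[i] <- 0; next }
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        links <- links + adj[nb[a], nb[b]]
      }
    }
    cc[i] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- stats::rbinom(length(up), 1, p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  dimnames(adj) <- list(paste0("T", seq_len(n)), paste0("T", seq_len(n)))
  adj
}

# do two module assignments describe the same partition?
same_partition <- function(a, b) {
  identical(as.integer(as.factor(a))[order(as.integer(as.factor(a)))],
            as.integer(as.factor(b))[order(as.integer(as.factor(b)))]) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

make_trait_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
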