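#' Pairwise Pearson correlations with two-sided p-values
#'
#' Computes the trait-by-trait product-moment correlation matrix with
#' pairwise-complete observations, the per-pair complete sample counts, and
#' two-sided p-values from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom.  Pairs involving a zero-variance (constant) trait are
#' flagged `NA` rather than silently set to 0 or 1; p-values are defined
#' only where at least 3 complete observations exist.
#'
#' @param data Tibble of individuals with numeric trait columns.
#' @param group Optional group column name; when given together with
#'   `which_group`, only that water body's rows are used.
#' @param which_group Group label to subset to (requires `group`).
#' @param traits Optional trait column names; default all numeric non-group
#'   columns.
#' @return An object of class `correlation_result`: a list with symmetric
#'   matrices `r`, `p`, `n_pairs`, plus `trait_names` and `group`.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(a = rnorm(20), b = rnorm(20))
#' d$c <- d$a + rnorm(20, sd = 0.1)
#' cr <- pearson_with_pvalues(d)
#' cr$r["a", "c"]
#' @export
pearson_with_pvalues <- function(data, group = NULL, which_group = NULL,
                                 traits = NULL) {
  if (!is.null(which_group)) {
    if (is.null(group)) {
      rlang::abort("`which_group` requires `group`",
                   class = "traitnet_config_error")
    }
    data <- data[as.character(data[[group]]) == which_group, , drop = FALSE]
  }
  if (is.null(traits)) {
    traits <- if (is.null(group)) {
      names(data)[vapply(data, is.numeric, logical(1))]
    } else {
      trait_columns(data, group)
    }
  }
  if (length(traits) < 2L) {
    rlang::abort("need at least 2 trait columns",
                 class = "traitnet_format_error")
  }
  x <- as.matrix(data[, traits, drop = FALSE])
  storage.mode(x) <- "double"
  obs <- !is.na(x)
  n_pairs <- crossprod(obs)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  # constant columns over the pairwise-complete rows give sd = 0 -> NA in r
  p <- matrix(NA_real_, nrow = length(traits), ncol = length(traits),
              dimnames = dimnames(r))
  ok <- n_pairs >= 3 & !is.na(r)
  if (any(ok)) {
    rr <- pmin(pmax(r[ok], -1), 1)
    df <- n_pairs[ok] - 2
    tstat <- ifelse(abs(rr) >= 1, Inf, abs(rr) * sqrt(df / (1 - rr^2)))
    p[ok] <- 2 * stats::pt(tstat, df = df, lower.tail = FALSE)
  }
  diag(r)[!is.na(diag(r))] <- 1
  diag(p) <- ifelse(is.na(diag(r)), NA_real_, 0)
  structure(list(r = r, p = p, n_pairs = n_pairs,
                 trait_names = traits,
                 group = if (is.null(which_group)) NA_character_ else which_group),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", length(x$trait_names), " traits",
      if (!is.na(x$group)) paste0(", group '", x$group, "'"), "\n", sep = "")
  invisible(x)
}

#' Tidy a correlation result into an edge-candidate table
#'
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return Tibble with one row per unordered trait pair: `trait_i`,
#'   `trait_j`, `r`, `p`, `n`.
#' @export
tidy.correlation_result <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(trait_i = x$trait_names[idx[, 1]],
                 trait_j = x$trait_names[idx[, 2]],
                 r = x$r[idx], p = x$p[idx], n = as.integer(x$n_pairs[idx]))
}

#' Build a binary trait network by significance thresholding
#'
#' An undirected edge joins two traits whenever the two-sided p-value of
#' their Pearson correlation is strictly below `alpha`; the sign and
#' magnitude of r are discarded, so the network records only the presence
#' or absence of a significant correlation.  Pairs whose correlation is
#' undefined (constant trait, too few observations) get no edge.  No
#' multiple-testing correction is applied by default; `adjust` switches on
#' standard [stats::p.adjust()] corrections over the distinct pairs.
#'
#' @param cr A `correlation_result` from [pearson_with_pvalues()].
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param adjust P-value adjustment method over trait pairs (default
#'   `"none"`).
#' @return An object of class `trait_network`: list with binary symmetric
#'   `adjacency` (zero diagonal), `trait_names`, `alpha`, `group`, and the
#'   `r` and `p` matrices the edges came from.
#' @examples
#' set.seed(1)
#' d <- as.data.frame(matrix(rnorm(120), 30, 4))
#' net <- build_network(pearson_with_pvalues(d), alpha = 0.05)
#' n_edges(net)
#' @export
build_network <- function(cr, alpha = 0.05, adjust = "none") {
  if (!inherits(cr, "correlation_result")) {
    rlang::abort("`cr` must be a correlation_result",
                 class = "traitnet_config_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    rlang::abort("`alpha` must be a single number in (0, 1)",
                 class = "traitnet_config_error")
  }
  p <- cr$p
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  adj <- ifelse(!is.na(p) & p < alpha, 1L, 0L)
  diag(adj) <- 0L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  dimnames(adj) <- list(cr$trait_names, cr$trait_names)
  structure(list(adjacency = adj, trait_names = cr$trait_names,
                 alpha = alpha, group = cr$group, r = cr$r, p = cr$p),
            class = "trait_network")
}

#' Construct a trait network directly from an adjacency matrix
#'
#' Mostly useful for tests and worked examples; checks symmetry, zero
#' diagonal and 0/1 entries.
#'
#' @param adjacency Square 0/1 matrix; row/col names become trait names.
#' @param trait_names Optional names overriding dimnames.
#' @param group Optional water-body label.
#' @param alpha Significance level recorded on the object (default `NA`).
#' @return A `trait_network`.
#' @export
as_trait_network <- function(adjacency, trait_names = NULL, group = NA_character_,
                             alpha = NA_real_) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (ncol(adjacency) != n) {
    rlang::abort("adjacency must be square", class = "traitnet_format_error")
  }
  if (!all(adjacency %in% c(0, 1))) {
    rlang::abort("adjacency must be binary", class = "traitnet_format_error")
  }
  if (any(diag(adjacency) != 0)) {
    rlang::abort("adjacency must have zero diagonal (no self-loops)",
                 class = "traitnet_format_error")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    rlang::abort("adjacency must be symmetric", class = "traitnet_format_error")
  }
  if (is.null(trait_names)) {
    trait_names <- rownames(adjacency)
    if (is.null(trait_names)) trait_names <- paste0("T", seq_len(n))
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(trait_names, trait_names)
  structure(list(adjacency = adjacency, trait_names = trait_names,
                 alpha = alpha, group = group, r = NULL, p = NULL),
            class = "trait_network")
}

#' Number of edges in a trait network
#' @param net A `trait_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  as.integer(sum(net$adjacency[upper.tri(net$adjacency)]))
}

#' @export
print.trait_network <- function(x, ...) {
  n <- length(x$trait_names)
  cat("<trait_network> ", n, " traits, ", n_edges(x), " edges",
      if (!is.na(x$alpha)) paste0(", alpha = ", x$alpha),
      if (!is.na(x$group)) paste0(", group '", x$group, "'"), "\n", sep = "")
  invisible(x)
}

#' Tidy a trait network into its edge list
#'
#' @param x A `trait_network`.
#' @param ... Unused.
#' @return Tibble with columns `trait_i`, `trait_j` and, when the network
#'   was built from correlations, `r` and `p`.
#' @export
tidy.trait_network <- function(x, ...) {
  idx <- which(upper.tri(x$adjacency) & x$adjacency == 1L, arr.ind = TRUE)
  out <- tibble::tibble(trait_i = x$trait_names[idx[, 1]],
                        trait_j = x$trait_names[idx[, 2]])
  if (!is.null(x$r)) {
    out$r <- x$r[idx]
    out$p <- x$p[idx]
  }
  out
}

#' Build one trait network per water body
#'
#' @inheritParams pearson_with_pvalues
#' @inheritParams build_network
#' @return Named list of `trait_network`, one per group level (in order of
#'   first appearance).
#' @export
networks_by_group <- function(data, group, alpha = 0.05, traits = NULL,
                              adjust = "none") {
  levels <- unique(as.character(data[[group]]))
  nets <- lapply(levels, function(g) {
    build_network(pearson_with_pvalues(data, group = group, which_group = g,
                                       traits = traits),
                  alpha = alpha, adjust = adjust)
  })
  stats::setNames(nets, levels)
}

#' Write a network as an edge-list CSV
#'
#' @param net A `trait_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_csv(tidy(net), path)
  invisible(path)
}

#' Write a network's adjacency matrix as CSV
#'
#' @param net A `trait_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  df <- as.data.frame(net$adjacency)
  df <- cbind(trait = rownames(net$adjacency), df)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' Trait names become node ids.  Requires the igraph package.
#'
#' @param net A `trait_network`.
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    rlang::abort("GraphML export needs the igraph package",
                 class = "traitnet_config_error")
  }
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
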