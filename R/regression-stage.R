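#' Screen environmental drivers of network topology by Pearson correlation
#'
#' Correlates each topology metric with each environmental variable across
#' water bodies and flags the variables significant at `alpha` as
#' candidates for multiple regression.  Constant variables are excluded
#' with a warning rather than reported as spurious r = 0.
#'
#' @param topo Tibble of per-group topology metrics (from
#'   [topology_by_group()]), with a `group` column.
#' @param env Tibble of environmental variables, one row per group, with a
#'   `group` column.
#' @param metrics Topology metric columns to screen; default the four
#'   global metrics.
#' @param variables Environmental columns to screen; default all numeric
#'   columns of `env`.
#' @param alpha Selection level (default 0.05).
#' @return Tibble with columns `metric`, `variable`, `r`, `p`, `n`,
#'   `selected`.
#' @export
screen_environment <- function(topo, env,
                               metrics = c("edge_density", "avg_path_length",
                                           "avg_clustering", "modularity"),
                               variables = NULL, alpha = 0.05) {
  joined <- dplyr::inner_join(topo, env, by = "group",
                              suffix = c("", ".env"))
  if (nrow(joined) < 3L) {
    rlang::abort("need at least 3 groups with both topology and environment",
                 class = "traitnet_insufficient_data")
  }
  if (is.null(variables)) {
    variables <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                         "group")
  }
  grid <- tidyr::expand_grid(metric = metrics, variable = variables)
  res <- purrr::pmap_dfr(grid, function(metric, variable) {
    x <- joined[[metric]]
    v <- joined[[if (variable %in% names(joined)) variable
                 else paste0(variable, ".env")]]
    keep <- !is.na(x) & !is.na(v)
    if (sum(keep) < 3L || stats::sd(v[keep]) == 0 || stats::sd(x[keep]) == 0) {
      rlang::warn(paste0("skipping ", metric, " ~ ", variable,
                         ": constant or insufficient data"))
      return(tibble::tibble(metric = metric, variable = variable,
                            r = NA_real_, p = NA_real_,
                            n = sum(keep), selected = FALSE))
    }
    ct <- stats::cor.test(x[keep], v[keep], method = "pearson")
    tibble::tibble(metric = metric, variable = variable,
                   r = unname(ct$estimate), p = ct$p.value,
                   n = sum(keep), selected = ct$p.value < alpha)
  })
  res
}

#' Backward multiple regression by p-value elimination
#'
#' Fits an ordinary least-squares model of `response` on all `predictors`,
#' then repeatedly drops the predictor with the largest p-value above
#' `p_remove` and refits, until every remaining predictor has p <=
#' `p_remove` or only one predictor is left.  With a single candidate this
#' is a simple linear regression.  A warning (not an error) is issued when
#' observations per predictor fall below 5, as is common with few sites.
#'
#' @param data Data frame holding the response and candidate predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of candidate predictor columns.
#' @param p_remove Elimination threshold on individual coefficient p-values
#'   (default 0.10).
#' @return An object of class `backward_fit`: list with the final [lm] fit
#'   (`fit`), `response`, `predictors` retained, and `eliminated` -- a
#'   tibble tracing each removal (`step`, `predictor`, `p_value`).
#'   [tidy()] and [glance()] methods summarise it.
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(TP = runif(20), DO = runif(20), junk = runif(20))
#' d$AL <- 1.2 - 2 * d$TP + 0.5 * d$DO + rnorm(20, sd = 0.05)
#' fit <- backward_regression(d, "AL", c("TP", "DO", "junk"))
#' glance(fit)
#' @export
backward_regression <- function(data, response, predictors, p_remove = 0.10) {
  stopifnot(is.character(response), length(response) == 1L)
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("columns not found: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "traitnet_config_error")
  }
  data <- data[stats::complete.cases(data[, c(response, predictors)]), ,
               drop = FALSE]
  n <- nrow(data)
  if (n <= length(predictors) + 1L) {
    rlang::abort("need more observations than predictors + 1",
                 class = "traitnet_insufficient_data")
  }
  if (n / length(predictors) < 5) {
    rlang::warn("fewer than 5 observations per candidate predictor; estimates will be unstable")
  }
  eliminated <- tibble::tibble(step = integer(), predictor = character(),
                               p_value = double())
  current <- predictors
  step <- 0L
  repeat {
    fml <- stats::reformulate(current, response = response)
    fit <- stats::lm(fml, data = data)
    if (anyNA(stats::coef(fit))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      rlang::abort(paste0("rank-deficient design; collinear columns: ",
                          paste(bad, collapse = ", ")),
                   class = "traitnet_collinearity_error")
    }
    if (length(current) == 1L) break
    coefs <- summary(fit)$coefficients
    slopes <- coefs[setdiff(rownames(coefs), "(Intercept)"), , drop = FALSE]
    worst <- which.max(slopes[, "Pr(>|t|)"])
    if (slopes[worst, "Pr(>|t|)"] <= p_remove) break
    step <- step + 1L
    eliminated <- dplyr::bind_rows(eliminated, tibble::tibble(
      step = step, predictor = rownames(slopes)[worst],
      p_value = slopes[worst, "Pr(>|t|)"]))
    current <- setdiff(current, rownames(slopes)[worst])
  }
  structure(list(fit = fit, response = response, predictors = current,
                 eliminated = eliminated, p_remove = p_remove, n_obs = n),
            class = "backward_fit")
}

#' @export
print.backward_fit <- function(x, ...) {
  cat("<backward_fit> ", equation_text(x), "\n", sep = "")
  if (nrow(x$eliminated)) {
    cat("eliminated: ", paste(x$eliminated$predictor, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy the coefficients of a backward regression
#'
#' @param x A `backward_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
tidy.backward_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1]),
                 std_error = unname(co[, 2]), statistic = unname(co[, 3]),
                 p_value = unname(co[, 4]))
}

#' One-row summary of a backward regression
#'
#' @param x A `backward_fit`.
#' @param ... Unused.
#' @return Tibble with `response`, `predictors`, `r_squared`,
#'   `f_statistic`, `p_value`, `n_obs`, `n_eliminated`.  A perfect fit
#'   (residual variance 0) reports `f_statistic = Inf` and `p_value = 0`.
#' @export
glance.backward_fit <- function(x, ...) {
  s <- summary(x$fit)
  if (is.null(s$fstatistic)) {
    f <- NA_real_; p <- NA_real_
  } else {
    f <- unname(s$fstatistic[1])
    p <- stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                   lower.tail = FALSE)
    if (!is.finite(f)) { f <- Inf; p <- 0 }
  }
  tibble::tibble(response = x$response,
                 predictors = paste(x$predictors, collapse = " + "),
                 r_squared = s$r.squared, f_statistic = f, p_value = unname(p),
                 n_obs = x$n_obs, n_eliminated = nrow(x$eliminated))
}

#' Format a fitted model as a readable equation
#'
#' Mirrors the conventional report format, e.g.
#' `"AL = 1.22 - 24.30 TP + 0.15 DO (R2 = 0.91; F = 19.37; P < 0.01)"`.
#'
#' @param x A `backward_fit`.
#' @param digits Significant digits for coefficients.
#' @return A single string.
#' @export
equation_text <- function(x, digits = 3) {
  co <- stats::coef(x$fit)
  terms <- names(co)[-1]
  rhs <- format(signif(co[1], digits))
  for (i in seq_along(terms)) {
    b <- co[i + 1]
    rhs <- paste0(rhs, if (b >= 0) " + " else " - ",
                  format(signif(abs(b), digits)), " ", terms[i])
  }
  g <- glance.backward_fit(x)
  paste0(x$response, " = ", rhs,
         " (R2 = ", format(signif(g$r_squared, 2)),
         "; F = ", format(signif(g$f_statistic, 4)),
         "; P = ", format(signif(g$p_value, 2)), ")")
}

#' Regress node metrics on trait variability, and topology on mean CV
#'
#' `cv_vs_node_metrics()` fits simple linear regressions of each node
#' metric (degree, closeness, betweenness) on trait CV, pairing each
#' trait's CV with its node metrics within the same water body.
#' `cv_vs_topology()` regresses each global topology metric on the
#' group-level mean CV across water bodies.  Slopes with p >= `alpha` are
#' flagged nonsignificant (the dashed-line convention of regression
#' figures).
#'
#' @param cvt CV table from [cv_table()].
#' @param nm Per-group node metrics from [node_metrics_by_group()].
#' @param alpha Significance flag level (default 0.05).
#' @return Tibble with one row per response: `response`, `intercept`,
#'   `slope`, `r_squared`, `p_value`, `n`, `significant`.
#' @export
cv_vs_node_metrics <- function(cvt, nm, alpha = 0.05) {
  joined <- dplyr::inner_join(cvt, nm, by = c("trait", "group"))
  if (nrow(joined) == 0L) {
    unmatched <- dplyr::anti_join(cvt, nm, by = c("trait", "group"))
    rlang::abort(paste0("no matching trait/group keys; unmatched: ",
                        paste(utils::head(paste(unmatched$trait,
                                                unmatched$group, sep = "@"), 5),
                              collapse = ", ")),
                 class = "traitnet_join_error")
  }
  if (nrow(joined) < 3L) {
    rlang::abort("need at least 3 matched trait/group rows",
                 class = "traitnet_insufficient_data")
  }
  purrr::map_dfr(c("degree", "closeness", "betweenness"), function(metric) {
    simple_regression_row(joined$cv, joined[[metric]], metric, alpha,
                          strict = FALSE)
  })
}

#' @rdname cv_vs_node_metrics
#' @param topo Per-group topology metrics from [topology_by_group()].
#' @export
cv_vs_topology <- function(cvt, topo, alpha = 0.05) {
  gm <- cv_group_means(cvt)
  joined <- dplyr::inner_join(gm, topo, by = "group")
  if (nrow(joined) == 0L) {
    rlang::abort("no matching group keys between CV table and topology",
                 class = "traitnet_join_error")
  }
  if (nrow(joined) < 3L) {
    rlang::abort("need at least 3 matched groups",
                 class = "traitnet_insufficient_data")
  }
  purrr::map_dfr(c("edge_density", "avg_path_length", "avg_clustering",
                   "modularity"), function(metric) {
    simple_regression_row(joined$mean_cv, joined[[metric]], metric, alpha,
                          strict = FALSE)
  })
}

simple_regression_row <- function(x, y, name, alpha, strict = TRUE) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    if (strict) {
      rlang::abort(paste0("too few observations to regress ", name),
                   class = "traitnet_insufficient_data")
    }
    rlang::warn(paste0("too few defined observations to regress ", name,
                       "; reporting NA"))
    return(tibble::tibble(response = name, intercept = NA_real_,
                          slope = NA_real_, r_squared = NA_real_,
                          p_value = NA_real_, n = length(x),
                          significant = FALSE))
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  pv <- if (nrow(s$coefficients) > 1) s$coefficients[2, 4] else NA_real_
  tibble::tibble(response = name,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = s$r.squared, p_value = pv, n = length(x),
                 significant = !is.na(pv) && pv < alpha)
}
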