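mk_topo <- function(n = 7, seed = 1) {
  set.seed(seed)
  tibble::tibble(group = paste0("WB", 1:n),
                 edge_density = runif(n, 0.2, 0.7),
                 avg_path_length = runif(n, 1.2, 2.2),
                 avg_clustering = runif(n, 0.4, 0.9),
                 modularity = runif(n, 0.05, 0.3))
}

test_that("screening flags perfectly matching variables and skips constants", {
  topo <- mk_topo()
  env <- tibble::tibble(group = topo$group,
                        TP = topo$edge_density,      # exact match -> r = 1
                        flat = 3)
  expect_warning(
    res <- screen_environment(topo, env, metrics = "edge_density"),
    "constant")
  row <- res[res$variable == "TP", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_true(row$selected)
  expect_false(res$selected[res$variable == "flat"])
})

test_that("a variable orthogonal to the metric is not selected", {
  topo <- mk_topo(n = 8, seed = 4)
  x <- topo$edge_density
  set.seed(5)
  v <- rnorm(8)
  v_orth <- residuals(lm(v ~ x))          # constructed to have r = 0 with x
  env <- tibble::tibble(group = topo$group, ortho = v_orth)
  res <- screen_environment(topo, env, metrics = "edge_density")
  expect_equal(res$r, 0, tolerance = 1e-10)
  expect_false(res$selected)
})

test_that("screening needs at least 3 groups", {
  topo <- mk_topo(n = 2)
  env <- tibble::tibble(group = topo$group, TP = c(0.1, 0.2))
  expect_error(screen_environment(topo, env),
               class = "traitnet_insufficient_data")
})

test_that("backward elimination drops decoys and recovers true coefficients", {
  set.seed(17)
  n <- 50
  d <- tibble::tibble(x1 = runif(n), x2 = rnorm(n))
  d$y <- 1.0 + 2.0 * d$x1 + rnorm(n, sd = 0.01)
  fit <- backward_regression(d, "y", c("x1", "x2"))
  expect_equal(fit$predictors, "x1")
  expect_equal(fit$eliminated$predictor, "x2")
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "(Intercept)"] - 1.0),
            3 * td$std_error[td$term == "(Intercept)"] + 1e-6)
  expect_lt(abs(td$estimate[td$term == "x1"] - 2.0),
            3 * td$std_error[td$term == "x1"] + 1e-6)
})

test_that("an exact fit reports R2 = 1 with an infinite-flagged F", {
  d <- tibble::tibble(x1 = 1:10, y = 1:10)
  fit <- backward_regression(d, "y", "x1")
  g <- glance(fit)
  expect_equal(g$r_squared, 1, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate[2], 1, tolerance = 1e-9)
  expect_true(is.infinite(g$f_statistic) || g$f_statistic > 1e12)
})

test_that("insufficient observations and collinearity raise typed errors", {
  d <- tibble::tibble(x1 = 1:3, x2 = c(2, 1, 3), y = c(1, 4, 2))
  expect_error(backward_regression(d, "y", c("x1", "x2")),
               class = "traitnet_insufficient_data")
  set.seed(2)
  d2 <- tibble::tibble(x1 = rnorm(20))
  d2$x2 <- 2 * d2$x1                      # exact collinearity
  d2$y <- d2$x1 + rnorm(20)
  expect_error(backward_regression(d2, "y", c("x1", "x2")),
               class = "traitnet_collinearity_error")
})

test_that("OLS matches the closed-form normal-equations solution", {
  set.seed(23)
  n <- 40
  d <- tibble::tibble(a = rnorm(n), b = runif(n), c = rnorm(n))
  d$y <- 0.5 - 1.2 * d$a + 3 * d$b + 0.4 * d$c + rnorm(n, sd = 0.3)
  fit <- backward_regression(d, "y", c("a", "b", "c"), p_remove = 1)
  X <- cbind(1, d$a, d$b, d$c)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_equal(unname(tidy(fit)$estimate), as.numeric(beta), tolerance = 1e-9)
  # R2 consistent with sums of squares
  yhat <- X %*% beta
  r2 <- 1 - sum((d$y - yhat)^2) / sum((d$y - mean(d$y))^2)
  expect_equal(glance(fit)$r_squared, r2, tolerance = 1e-9)
})

test_that("p_remove = 1 keeps the full model; p_remove -> 0 leaves one predictor", {
  set.seed(29)
  n <- 30
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- d$a + 0.5 * d$b + rnorm(n, sd = 0.5)
  full <- backward_regression(d, "y", c("a", "b", "c"), p_remove = 1)
  expect_setequal(full$predictors, c("a", "b", "c"))
  expect_equal(nrow(full$eliminated), 0L)
  tiny <- backward_regression(d, "y", c("a", "b", "c"), p_remove = 1e-300)
  expect_length(tiny$predictors, 1L)
})

test_that("equation_text mirrors the conventional report format", {
  d <- tibble::tibble(TP = c(0.01, 0.02, 0.03, 0.05, 0.04, 0.06),
                      AL = c(1.4, 1.3, 1.25, 1.1, 1.2, 1.05))
  fit <- backward_regression(d, "AL", "TP")
  txt <- equation_text(fit)
  expect_match(txt, "^AL = ")
  expect_match(txt, "TP")
  expect_match(txt, "R2 = ")
})

test_that("node metrics regress on trait CV, with nonsignificance flagged", {
  # perfectly collinear CV and degree over 18 traits
  traits <- default_trait_names()
  cvt <- tibble::tibble(trait = traits, group = "A",
                        cv = seq(0.1, 0.95, length.out = 18))
  nm <- tibble::tibble(trait = traits, group = "A",
                       degree = 2 * cvt$cv + 1,
                       closeness = 0.5 * cvt$cv,
                       betweenness = 3 * cvt$cv)
  res <- cv_vs_node_metrics(cvt, nm)
  expect_equal(res$r_squared, rep(1, 3), tolerance = 1e-9)
  expect_gt(res$slope[res$response == "degree"], 0)
  expect_true(all(res$significant))

  # CV independent of the metrics by seeded permutation -> nonsignificant
  set.seed(37)
  nm_null <- nm
  nm_null$degree <- sample(nm$degree)
  nm_null$closeness <- sample(nm$closeness)
  nm_null$betweenness <- sample(nm$betweenness)
  res_null <- cv_vs_node_metrics(cvt, nm_null)
  expect_true(all(res_null$p_value > 0.05))
  expect_false(any(res_null$significant))
})

test_that("mismatched keys and single-trait inputs raise typed errors", {
  cvt <- tibble::tibble(trait = "H", group = "A", cv = 0.3)
  nm <- tibble::tibble(trait = "SB", group = "B", degree = 1,
                       closeness = 0.2, betweenness = 0)
  expect_error(cv_vs_node_metrics(cvt, nm), class = "traitnet_join_error")
  nm2 <- tibble::tibble(trait = "H", group = "A", degree = 1,
                        closeness = 0.2, betweenness = 0)
  expect_error(cv_vs_node_metrics(cvt, nm2),
               class = "traitnet_insufficient_data")
})

test_that("topology metrics regress on group mean CV", {
  topo <- mk_topo(n = 7, seed = 8)
  traits <- paste0("T", 1:5)
  cvt <- tidyr::expand_grid(trait = traits, group = topo$group)
  # mean CV proportional to edge density by construction
  cvt <- dplyr::left_join(cvt,
                          tibble::tibble(group = topo$group,
                                         base = topo$edge_density),
                          by = "group")
  cvt$cv <- cvt$base
  res <- cv_vs_topology(cvt[, c("trait", "group", "cv")], topo)
  ed <- res[res$response == "edge_density", ]
  expect_equal(ed$r_squared, 1, tolerance = 1e-9)
  expect_true(ed$significant)
})
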