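# Seeded generator of trait matrices with planted correlation modules and a
# matching environmental gradient, emulating the design of the field study
# the pipeline targets: 18 functional traits, ~30 individuals per water
# body, 7 water bodies.

#' Configuration for the synthetic trait-data generator
#'
#' Individuals are drawn per water body from a multivariate normal with a
#' block correlation structure: correlation `rho_in` within each planted
#' module and `rho_out` between modules.  `rho_in` varies across water
#' bodies as an exact linear function of a total-phosphorus-like gradient
#' (`env_model$tp_range` mapped onto `env_model$rho_in_range`), so that
#' network tightness is linked to the environment by construction; a
#' dissolved-oxygen-like variable runs along the opposite gradient.  Trait
#' CVs are set by shifting each trait's mean at fixed unit variance
#' (mean = 1/CV), which leaves correlations untouched.
#'
#' @param n_groups Number of water bodies (default 7).
#' @param n_individuals Individuals per water body (default 30).
#' @param n_traits Number of traits (default 18).
#' @param trait_names Trait names; default the 18 standard abbreviations
#'   (when `n_traits` is 18), else `T1..Tn`.
#' @param modules Integer vector of planted module ids per trait; default a
#'   balanced partition into 3 modules (2 when fewer than 6 traits).
#' @param rho_in Within-module correlation: a single value, a per-group
#'   vector, or `NULL` (default) to derive it from the environmental
#'   gradient via `env_model`.
#' @param rho_out Between-module correlation (default 0.05).
#' @param cv Per-trait target coefficient of variation; default spans 0.9
#'   down to 0.15 across traits, most variable first.
#' @param env_model List with `tp_range` (mg/L, default 0.014-0.055, the
#'   span typical of mesotrophic impounded lakes), `do_range` (mg/L,
#'   default 12 down to 6), `rho_in_range` (default 0.35-0.75) and the
#'   per-group scatter `tp_sd`, `do_sd` around the two gradients: TP and
#'   DO run linearly across groups plus noise, and `rho_in` is exactly
#'   linear in the realised TP.
#' @param noise_sd Extra independent Gaussian noise added to every trait
#'   value after the correlated draw (default 0).
#' @param seed RNG seed; required, so every dataset is reproducible.
#' @return A `synthetic_config` list, validated (positive-semi-definite
#'   block correlation, CV targets > 0).
#' @export
synthetic_config <- function(n_groups = 7L, n_individuals = 30L,
                             n_traits = 18L, trait_names = NULL,
                             modules = NULL, rho_in = NULL, rho_out = 0.05,
                             cv = NULL, env_model = list(), noise_sd = 0,
                             seed) {
  if (missing(seed)) {
    rlang::abort("`seed` is required: synthetic datasets must be reproducible",
                 class = "traitnet_config_error")
  }
  if (is.null(trait_names)) {
    trait_names <- if (n_traits == 18L) default_trait_names()
                   else paste0("T", seq_len(n_traits))
  }
  stopifnot(length(trait_names) == n_traits)
  if (is.null(modules)) {
    k <- if (n_traits >= 6L) 3L else min(2L, n_traits)
    modules <- sort(rep_len(seq_len(k), n_traits))
  }
  stopifnot(length(modules) == n_traits)
  if (is.null(cv)) {
    # wide CV spread typical of field-sampled macrophyte traits; for the 18
    # standard traits, ordered along the variability ranking observed in
    # the field (stem branch and organ-mass traits most variable, leaf
    # width least)
    cv <- seq(0.9, 0.15, length.out = n_traits)
    if (identical(trait_names, default_trait_names())) {
      by_variability <- c("SB", "DLW", "RLA", "DPW", "LN", "DSW", "NN", "LT",
                          "SLR", "RSL", "NL", "H", "LA", "LMF", "SMF", "LL",
                          "ND", "LW")
      cv <- cv[match(trait_names, by_variability)]
    }
  }
  if (any(cv <= 0)) {
    rlang::abort("cv targets must be > 0", class = "traitnet_config_error")
  }
  em <- utils::modifyList(list(tp_range = c(0.014, 0.055),
                               do_range = c(12, 6),
                               rho_in_range = c(0.35, 0.75),
                               tp_sd = 0.004, do_sd = 0.5),
                          env_model)
  if (!is.null(rho_in)) {
    rho_in <- rep_len(rho_in, n_groups)
    check_rho(rho_in, rho_out)
    for (g in seq_len(n_groups)) {
      check_psd(modules, rho_in[g], rho_out, g)
    }
  } else {
    # rho_in realised in generate() from the noisy TP gradient; check the
    # mapping at both endpoints of its reachable band (+/- 4 sd of TP noise)
    slope <- diff(em$rho_in_range) / diff(em$tp_range)
    band <- sort(em$rho_in_range + c(-1, 1) * abs(slope) * 4 * em$tp_sd)
    check_rho(band, rho_out)
    check_psd(modules, band[2], rho_out, NA)
  }
  structure(list(n_groups = as.integer(n_groups),
                 n_individuals = as.integer(n_individuals),
                 n_traits = as.integer(n_traits),
                 trait_names = trait_names,
                 modules = as.integer(modules),
                 rho_in = rho_in, rho_out = rho_out,
                 cv = cv, env_model = em,
                 groups = paste0("WB", seq_len(n_groups)),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

check_rho <- function(rho_in, rho_out) {
  if (any(rho_out < 0) || any(rho_out > rho_in) || any(rho_in >= 1)) {
    rlang::abort("need 0 <= rho_out <= rho_in < 1",
                 class = "traitnet_config_error")
  }
}

check_psd <- function(modules, rho_in, rho_out, g) {
  sigma <- block_correlation(modules, rho_in, rho_out)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    rlang::abort(paste0("correlation target",
                        if (!is.na(g)) paste0(" for group ", g),
                        " is not positive semi-definite (rho_in = ",
                        signif(rho_in, 3), ", rho_out = ",
                        signif(rho_out, 3), ")"),
                 class = "traitnet_config_error")
  }
}

block_correlation <- function(modules, rho_in, rho_out) {
  same <- outer(modules, modules, "==")
  sigma <- ifelse(same, rho_in, rho_out)
  diag(sigma) <- 1
  sigma
}

#' Generate a synthetic trait dataset
#'
#' Draws `n_individuals` per water body from the block-correlated
#' multivariate normal described by the config, shifts each trait's mean to
#' hit its target CV (unit variance, mean = 1/CV), and returns the trait
#' tibble, the environmental table and the generative truth (planted
#' modules, per-group within-module correlation, and the exact linear link
#' from TP to `rho_in`).
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_dataset`: list with `traits` (tibble with `group`
#'   column), `env` (tibble `group`, `TP`, `DO`), and `truth`.
#' @examples
#' ds <- generate(synthetic_config(seed = 42))
#' dplyr::count(ds$traits, group)
#' @export
generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(config$seed)
  em <- config$env_model
  ng <- config$n_groups
  # environmental gradient plus per-group scatter
  tp <- seq(em$tp_range[1], em$tp_range[2], length.out = ng) +
    stats::rnorm(ng, sd = em$tp_sd)
  tp <- pmax(tp, 1e-4)
  do_ <- seq(em$do_range[1], em$do_range[2], length.out = ng) +
    stats::rnorm(ng, sd = em$do_sd)
  env <- tibble::tibble(group = config$groups, TP = tp, DO = do_)
  rho_in <- config$rho_in
  if (is.null(rho_in)) {
    slope <- diff(em$rho_in_range) / diff(em$tp_range)
    rho_in <- em$rho_in_range[1] + slope * (tp - em$tp_range[1])
    check_rho(rho_in, config$rho_out)
  }
  mu <- 1 / config$cv
  rows <- lapply(seq_len(ng), function(g) {
    sigma <- block_correlation(config$modules, rho_in[g], config$rho_out)
    x <- MASS::mvrnorm(config$n_individuals, mu = rep(0, config$n_traits),
                       Sigma = sigma)
    if (config$noise_sd > 0) {
      x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd),
                      nrow = nrow(x))
    }
    x <- sweep(x, 2, mu, "+")
    colnames(x) <- config$trait_names
    dplyr::bind_cols(tibble::tibble(group = config$groups[g]),
                     tibble::as_tibble(x))
  })
  link <- if (is.null(config$rho_in)) {
    list(intercept = em$rho_in_range[1] -
           diff(em$rho_in_range) / diff(em$tp_range) * em$tp_range[1],
         slope_tp = diff(em$rho_in_range) / diff(em$tp_range))
  } else {
    list(intercept = NA_real_, slope_tp = NA_real_)
  }
  structure(list(
    traits = dplyr::bind_rows(rows),
    env = env,
    truth = list(modules = stats::setNames(config$modules,
                                           config$trait_names),
                 rho_in = stats::setNames(rho_in, config$groups),
                 rho_out = config$rho_out, cv = stats::setNames(
                   config$cv, config$trait_names),
                 rho_in_link = link,
                 seed = config$seed)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$traits), " individuals, ",
      length(x$truth$modules), " traits, ",
      nrow(x$env), " water bodies (seed ", x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Null trait matrix: mutually independent Gaussian traits
#'
#' The type-I-error harness for the significance-threshold rule: every
#' trait is standard normal and independent of every other, so any edge in
#' a network built from this matrix is a false positive and the expected
#' edge density equals the threshold alpha.
#'
#' @param n_traits Number of traits (>= 2).
#' @param n_individuals Number of individuals (>= 3, so that p-values are
#'   defined on n - 2 >= 1 degrees of freedom).
#' @param seed RNG seed.
#' @return Tibble with a `group` column (single group `"null"`) and
#'   `n_traits` standard-normal trait columns `T1..Tn`.
#' @export
null_dataset <- function(n_traits, n_individuals, seed) {
  if (n_traits < 2L) {
    rlang::abort("need at least 2 traits", class = "traitnet_config_error")
  }
  if (n_individuals < 3L) {
    rlang::abort("need at least 3 individuals for defined p-values",
                 class = "traitnet_config_error")
  }
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  x <- matrix(stats::rnorm(n_individuals * n_traits), n_individuals, n_traits,
              dimnames = list(NULL, paste0("T", seq_len(n_traits))))
  dplyr::bind_cols(tibble::tibble(group = "null"), tibble::as_tibble(x))
}

#' Write a synthetic dataset to disk
#'
#' Writes `traits.csv` and `env.csv` in the dialect [read_trait_matrix()]
#' reads, plus the generative truth as `truth.json`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(ds$traits, file.path(dir, "traits.csv"))
  readr::write_csv(ds$env, file.path(dir, "env.csv"))
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
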