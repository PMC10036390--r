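#' Read a per-individual trait matrix from delimited text
#'
#' Reads a CSV or TSV file in which rows are individual plants, one column
#' holds the water-body (group) label, and the remaining numeric columns are
#' functional traits.  Non-numeric trait cells (including the tokens listed
#' in `missing_tokens`) become `NA`; row order is preserved.
#'
#' @param path Path to a delimited text file with a header row.  The
#'   delimiter is inferred from the extension (`.tsv`/`.txt` = tab,
#'   otherwise comma).
#' @param group_column Name of the column holding the water-body label.
#' @param trait_columns Optional character vector naming the trait columns.
#'   Default `NULL` uses every column other than `group_column` that parses
#'   as numeric.
#' @param missing_tokens Strings treated as missing values.
#' @return A tibble with the group column (as character) followed by one
#'   numeric column per trait.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(lake = c("A", "A", "B"), H = c(10, 12, 9),
#'                      LA = c(1.2, 1.5, 0.9)), tf, row.names = FALSE)
#' read_trait_matrix(tf, group_column = "lake")
#' @export
read_trait_matrix <- function(path, group_column,
                              trait_columns = NULL,
                              missing_tokens = c("NA", "")) {
  if (!file.exists(path)) {
    rlang::abort(paste0("trait matrix file not found: ", path),
                 class = "traitnet_io_error")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = missing_tokens, progress = FALSE,
                           show_col_types = FALSE)
  if (!group_column %in% names(raw)) {
    rlang::abort(paste0("group column '", group_column, "' not found in ", path),
                 class = "traitnet_config_error")
  }
  candidates <- setdiff(names(raw), group_column)
  if (is.null(trait_columns)) {
    numericish <- vapply(candidates, function(nm) {
      v <- raw[[nm]]
      suppressWarnings(all(is.na(v) | !is.na(as.numeric(v))))
    }, logical(1))
    trait_columns <- candidates[numericish]
  } else {
    missing_cols <- setdiff(trait_columns, names(raw))
    if (length(missing_cols)) {
      rlang::abort(paste0("trait columns not found: ",
                          paste(missing_cols, collapse = ", ")),
                   class = "traitnet_config_error")
    }
  }
  if (length(trait_columns) == 0L) {
    rlang::abort("no numeric trait columns found", class = "traitnet_format_error")
  }
  out <- tibble::tibble(!!group_column := as.character(raw[[group_column]]))
  for (nm in trait_columns) {
    out[[nm]] <- suppressWarnings(as.numeric(raw[[nm]]))
  }
  if (anyNA(out[[group_column]])) {
    rlang::abort("missing group labels in trait matrix",
                 class = "traitnet_format_error")
  }
  out
}

#' Identify the trait columns of a trait tibble
#'
#' Trait columns are all numeric columns other than the group column.
#'
#' @param data A data frame of individuals.
#' @param group Name of the group column.
#' @return Character vector of trait column names.
#' @export
trait_columns <- function(data, group) {
  if (!group %in% names(data)) {
    rlang::abort(paste0("group column '", group, "' not found"),
                 class = "traitnet_config_error")
  }
  nms <- setdiff(names(data), group)
  nms[vapply(data[nms], is.numeric, logical(1))]
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' reported as a dimensionless ratio (not a percentage).
#'
#' @param x Numeric vector; `NA` dropped when `na.rm = TRUE`.
#' @param na.rm Drop missing values first (default `TRUE`).
#' @return A single non-negative number when the mean is positive.
#' @examples
#' coefficient_of_variation(c(1, 3))  # sqrt(2)/2
#' @export
coefficient_of_variation <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) < 2L) {
    rlang::abort("need at least 2 non-missing values to compute a CV",
                 class = "traitnet_insufficient_data")
  }
  m <- mean(x)
  if (m == 0) {
    rlang::abort("CV undefined: mean is zero", class = "traitnet_undefined_cv")
  }
  stats::sd(x) / m
}

cv_or_na <- function(x) {
  tryCatch(coefficient_of_variation(x),
           traitnet_undefined_cv = function(e) NA_real_,
           traitnet_insufficient_data = function(e) NA_real_)
}

#' Per-group, per-trait coefficients of variation
#'
#' For each water body and each trait, the CV of the individuals measured
#' there.  Undefined CVs (zero mean, or fewer than two non-missing values)
#' are flagged with `NA` and a warning, and are excluded from downstream
#' means.
#'
#' @param data Tibble of individuals with a group column and numeric traits.
#' @param group Name of the group column.
#' @param traits Optional character vector of trait columns; default all
#'   numeric non-group columns.
#' @return A tibble with columns `trait`, `group`, `cv`.
#' @seealso [cv_group_means()], [cv_trait_ranking()]
#' @export
cv_table <- function(data, group, traits = NULL) {
  if (is.null(traits)) traits <- trait_columns(data, group)
  out <- tidyr::expand_grid(group = unique(as.character(data[[group]])),
                            trait = traits)
  out$cv <- purrr::map2_dbl(out$group, out$trait, function(g, tr) {
    cv_or_na(data[[tr]][data[[group]] == g])
  })
  if (anyNA(out$cv)) {
    bad <- out[is.na(out$cv), ]
    rlang::warn(paste0("undefined CV for ", nrow(bad), " trait/group pair(s): ",
                       paste(paste(bad$trait, bad$group, sep = "@"), collapse = ", ")))
  }
  dplyr::select(out, "trait", "group", "cv")
}

#' Mean trait CV per water body
#'
#' The mean of all defined per-trait CVs within each group: the group-level
#' summary of functional trait variability used to contrast tight
#' (high mean CV) and loose (low mean CV) trait networks.
#'
#' @param cvt A CV table from [cv_table()].
#' @return A tibble with columns `group`, `mean_cv`, `n_traits`.
#' @export
cv_group_means <- function(cvt) {
  dplyr::summarise(dplyr::group_by(cvt, .data$group),
                   mean_cv = mean(.data$cv, na.rm = TRUE),
                   n_traits = sum(!is.na(.data$cv)),
                   .groups = "drop")
}

#' Rank traits by variability
#'
#' Orders traits from most to least variable.  Two conventions are offered:
#' `"mean_of_groups"` (default) averages the per-group CVs of a trait and
#' ranks by that mean; `"pooled"` recomputes each trait's CV on all
#' individuals pooled across groups.
#'
#' @param cvt A CV table from [cv_table()] (used for `"mean_of_groups"`).
#' @param mode `"mean_of_groups"` or `"pooled"`.
#' @param data,group Required when `mode = "pooled"`: the original trait
#'   tibble and its group column.
#' @return Tibble with `trait`, `cv`, `rank` (1 = most variable).
#' @export
cv_trait_ranking <- function(cvt, mode = c("mean_of_groups", "pooled"),
                             data = NULL, group = NULL) {
  mode <- match.arg(mode)
  if (mode == "mean_of_groups") {
    out <- dplyr::summarise(dplyr::group_by(cvt, .data$trait),
                            cv = mean(.data$cv, na.rm = TRUE), .groups = "drop")
  } else {
    if (is.null(data) || is.null(group)) {
      rlang::abort("pooled ranking needs `data` and `group`",
                   class = "traitnet_config_error")
    }
    traits <- unique(cvt$trait)
    out <- tibble::tibble(trait = traits,
                          cv = vapply(traits, function(tr) cv_or_na(data[[tr]]),
                                      numeric(1), USE.NAMES = FALSE))
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$cv), .data$trait)
  out$rank <- seq_len(nrow(out))
  out
}

#' Light extinction coefficient from a two-depth PAR profile
#'
#' Assuming exponential attenuation of photosynthetically active radiation
#' with depth, the extinction coefficient is K = (1/d) * ln(I0 / Id), in
#' units of 1/m when `d` is in metres.
#'
#' @param I0 PAR at the water surface (> 0).
#' @param Id PAR at depth `d` (> 0).
#' @param d Depth in metres (> 0).
#' @return Extinction coefficient per metre (vectorised).
#' @examples
#' light_extinction_coefficient(200, 50, 0.5)  # 2 * log(4)
#' @export
light_extinction_coefficient <- function(I0, Id, d) {
  if (any(I0 <= 0) || any(Id <= 0) || any(d <= 0)) {
    rlang::abort("I0, Id and d must all be positive",
                 class = "traitnet_domain_error")
  }
  (1 / d) * log(I0 / Id)
}

#' The 18 functional trait abbreviations used throughout the package
#'
#' Plant height (H), stem branch (SB), internodes number (NN), internode
#' length (NL), internode diameter (ND), relative stem length (RSL), leaf
#' number (LN), leaf thickness (LT), leaf length (LL), leaf width (LW),
#' leaf area (LA), relative leaf area (RLA), dry plant weight (DPW), dry
#' stem weight (DSW), dry leaf weight (DLW), stem:leaf weight ratio (SLR),
#' stem dry mass fraction (SMF), leaf dry mass fraction (LMF).
#'
#' @return Character vector of length 18.
#' @export
default_trait_names <- function() {
  c("H", "SB", "NN", "NL", "ND", "RSL", "LN", "LT", "LL",
    "LW", "LA", "RLA", "DPW", "DSW", "DLW", "SLR", "SMF", "LMF")
}
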