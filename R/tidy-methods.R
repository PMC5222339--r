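#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test
#' @param x a `perm_test`.
#' @param ... ignored.
#' @return one-row tibble: `method`, `statistic`, `p_value`,
#'   `alternative`, `n_perm`, `seed`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, alternative = x$alternative,
                 n_perm = x$n_perm, seed = x$seed)
}

#' Tidy a Pareto clone-size fit
#' @param x a `pareto_fit`.
#' @param ... ignored.
#' @return tibble of the regression support points with fitted values.
#' @method tidy pareto_fit
#' @export
tidy.pareto_fit <- function(x, ...) x$points

#' @rdname tidy.pareto_fit
#' @return for `glance`: one-row tibble `beta`, `r_squared`, `n_mlg`,
#'   `n_sizes`.
#' @method glance pareto_fit
#' @export
glance.pareto_fit <- function(x, ...) {
  tibble::tibble(beta = x$beta, r_squared = x$r_squared,
                 n_mlg = x$n_mlg, n_sizes = nrow(x$points))
}

#' Tidy a principal-coordinates result
#' @param x a `pcoa_result`.
#' @param ... ignored.
#' @return the score tibble (`id`, `axis1`, ...).
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$scores

#' @rdname tidy.pcoa_result
#' @return for `glance`: one row per axis with eigenvalue and percent
#'   variance (positive axes only).
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  k <- length(x$pct_variance)
  tibble::tibble(axis = seq_len(k),
                 eigenvalue = x$eigenvalues[seq_len(k)],
                 pct_variance = x$pct_variance)
}

#' Tidy a pairwise differentiation matrix
#' @param x a `pairwise_matrix` from [pairwise_fst()] or [pairwise_dest()].
#' @param ... ignored.
#' @return long tibble: `pop1`, `pop2`, `estimate`, `p_value` (one row per
#'   unordered pair).
#' @method tidy pairwise_matrix
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  pops <- rownames(x$estimate)
  idx <- which(upper.tri(x$estimate), arr.ind = TRUE)
  tibble::tibble(pop1 = pops[idx[, 1]], pop2 = pops[idx[, 2]],
                 statistic = x$statistic,
                 estimate = x$estimate[idx],
                 p_value = x$p_value[idx])
}

#' Tidy an entire-versus-truncated differentiation analysis
#' @param x a [dual_analysis()] result.
#' @param ... ignored.
#' @return long tibble over datasets and statistics (`dataset`, `pop1`,
#'   `pop2`, `statistic`, `estimate`, `p_value`).
#' @method tidy dual_analysis
#' @export
tidy.dual_analysis <- function(x, ...) {
  purrr::map_dfr(c("entire", "truncated"), function(tag) {
    set <- x[[tag]]
    dplyr::bind_rows(
      if (!is.null(set$fst)) dplyr::mutate(tidy(set$fst), dataset = tag),
      if (!is.null(set$dest)) dplyr::mutate(tidy(set$dest), dataset = tag))
  }) |>
    dplyr::relocate("dataset")
}

#' @rdname tidy.dual_analysis
#' @return for `glance`: one row per dataset with its sample size and the
#'   range of F_ST estimates.
#' @method glance dual_analysis
#' @export
glance.dual_analysis <- function(x, ...) {
  purrr::map_dfr(c("entire", "truncated"), function(tag) {
    set <- x[[tag]]
    est <- if (!is.null(set$fst)) set$fst$estimate else matrix(NA_real_)
    tibble::tibble(dataset = tag, n = set$n,
                   fst_min = min(est, na.rm = TRUE),
                   fst_max = max(est, na.rm = TRUE))
  })
}
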