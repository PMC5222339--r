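#' Clonal richness R
#'
#' `R = (N_MLG - 1) / (N - 1)`: 0 in a monoclonal sample, 1 when every
#' colony carries its own genotype. Defined as 0 for a single sample.
#'
#' @param n_samples number of sampled units N (>= 1).
#' @param n_mlg number of distinct MLGs (1 <= n_mlg <= n_samples).
#' @return numeric in `[0, 1]` (vectorised).
#' @export
#' @examples
#' clonal_richness(158, 44)   # 0.2738854
clonal_richness <- function(n_samples, n_mlg) {
  n <- as.numeric(n_samples); g <- as.numeric(n_mlg)
  if (any(n < 1) || any(g < 1) || any(g > n)) {
    stop("need 1 <= n_mlg <= n_samples")
  }
  ifelse(n == 1, 0, (g - 1) / (n - 1))
}

#' Genotypic diversity G_O and its normalised form G
#'
#' With clone fractions `p_i = n_i / N`, the observed genotypic diversity
#' is the inverse Simpson concentration `G_O = 1 / sum(p_i^2)`; the
#' normalised index `G = G_O / N` spans (0, 1], from fully clonal to fully
#' sexual samples.
#'
#' @param sizes positive integer clone sizes.
#' @return list with `g_obs` and `g`.
#' @export
genotypic_diversity <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) < 1L || any(sizes < 1)) stop("need positive clone sizes")
  n <- sum(sizes)
  g_obs <- 1 / sum((sizes / n)^2)
  list(g_obs = g_obs, g = g_obs / n)
}

#' Simpson evenness ED* of the clone-size distribution
#'
#' Based on the unbiased Simpson complement
#' `D = 1 - sum n_i (n_i - 1) / (N (N - 1))`, rescaled between the least
#' even configuration compatible with (N, G) — one clone of `N - G + 1`
#' plus singletons — and the most even one (sizes differing by at most 1):
#' `ED* = (D - D_min) / (D_max - D_min)`.
#'
#' @param sizes clone sizes; needs >= 2 clones and at least one repeated
#'   clone (otherwise the two bounds coincide and the index is undefined).
#' @return numeric in `[0, 1]`.
#' @export
simpson_evenness <- function(sizes) {
  sizes <- as.numeric(sizes)
  g <- length(sizes)
  n <- sum(sizes)
  if (g < 2L) stop("Simpson evenness undefined for a single clone")
  if (n == g) {
    stop("Simpson evenness undefined when every clone is a singleton ",
         "(the most and least even configurations coincide)")
  }
  simpson_d <- function(s, n) 1 - sum(s * (s - 1)) / (n * (n - 1))
  d_obs <- simpson_d(sizes, n)
  even <- c(rep(ceiling(n / g), n %% g), rep(floor(n / g), g - n %% g))
  d_max <- simpson_d(even, n)
  d_min <- simpson_d(c(n - g + 1, rep(1, g - 1)), n)
  (d_obs - d_min) / (d_max - d_min)
}

#' Pareto exponent of the clone-size spectrum
#'
#' Fits the inverse cumulative clone-size distribution on the log-log
#' scale: for every distinct observed size `x`, the fraction of MLGs of
#' size >= `x` is regressed (OLS) on `log x`; `beta` is minus the slope.
#' Shallow slopes (small beta) flag samples dominated by a few large
#' clones; steep slopes flag many small, even clones.
#'
#' @param sizes clone sizes with >= 2 distinct values.
#' @return object of class `pareto_fit`: list with `beta`, `r_squared`,
#'   `n_mlg`, and `points` (tibble `size`, `frac_ge`, log coordinates).
#' @export
pareto_beta <- function(sizes) {
  sizes <- as.numeric(sizes)
  xs <- sort(unique(sizes))
  if (length(xs) < 2L) {
    stop("Pareto fit needs at least two distinct clone sizes")
  }
  frac <- vapply(xs, function(x) mean(sizes >= x), numeric(1))
  pts <- tibble::tibble(size = xs, frac_ge = frac,
                        log_size = log(xs), log_frac = log(frac))
  fit <- stats::lm(log_frac ~ log_size, data = pts)
  out <- list(beta = -unname(stats::coef(fit)[2]),
              r_squared = summary(fit)$r.squared,
              n_mlg = length(sizes),
              points = pts)
  class(out) <- "pareto_fit"
  out
}

#' @export
print.pareto_fit <- function(x, ...) {
  cat(sprintf("Pareto clone-size fit: beta = %.3f (r^2 = %.3f, %d MLGs, %d sizes)\n",
              x$beta, x$r_squared, x$n_mlg, nrow(x$points)))
  invisible(x)
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction to a common number of genes `g`: per locus
#' the expected number of alleles in a random draw of `g` gene copies,
#' `sum_a [1 - C(2n - n_a, g) / C(2n, g)]`, averaged over loci. This makes
#' allele counts comparable across samples of unequal size (conventionally
#' rarefied to the smallest sample).
#'
#' @param freqs an [allele_frequencies()] table (counts are used).
#' @param g rarefaction size in gene copies; must not exceed the number of
#'   genes available at any locus/population.
#' @return tibble `pop`, `a_hat` (mean over loci), plus per-locus values in
#'   attribute `per_locus`.
#' @export
allelic_richness <- function(freqs, g) {
  stopifnot(g >= 1)
  if (any(freqs$n_genes < g)) {
    stop("rarefaction size g = ", g, " exceeds the genes available at some locus")
  }
  per_locus <- freqs |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(
      a_rare = sum(1 - exp(lchoose(.data$n_genes[1] - .data$count, g) -
                             lchoose(.data$n_genes[1], g))),
      .groups = "drop")
  out <- per_locus |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(a_hat = mean(.data$a_rare), .groups = "drop")
  attr(out, "per_locus") <- per_locus
  out
}

#' Observed and expected heterozygosity
#'
#' Conventionally computed on the genet-level (clone-censored) table.
#' `H_O` is the fraction of heterozygous genets; `H_E` is Nei's unbiased
#' expected heterozygosity `(2n / (2n - 1)) (1 - sum p_i^2)`.
#'
#' @param table a `genotype_tbl` (one population or several; grouped by
#'   site).
#' @return tibble `pop`, `locus`, `n`, `h_obs`, `h_exp`; multilocus means
#'   and s.d. per population in attribute `multilocus`.
#' @export
heterozygosities <- function(table) {
  panel <- gt_loci(table)
  per_locus <- purrr::map_dfr(split(seq_len(nrow(table)), table$site), function(rows) {
    sub <- table[rows, ]
    purrr::map_dfr(panel$locus, function(loc) {
      a <- sub[[paste0(loc, ".1")]]; b <- sub[[paste0(loc, ".2")]]
      ok <- !is.na(a) & !is.na(b)
      a <- a[ok]; b <- b[ok]
      n <- length(a)
      if (n < 2L) return(NULL)
      p <- as.numeric(table(c(a, b))) / (2 * n)
      tibble::tibble(pop = sub$site[1], locus = loc, n = n,
                     h_obs = mean(a != b),
                     h_exp = (2 * n / (2 * n - 1)) * (1 - sum(p^2)))
    })
  })
  multi <- per_locus |>
    dplyr::group_by(.data$pop) |>
    dplyr::summarise(h_obs_mean = mean(.data$h_obs), h_obs_sd = stats::sd(.data$h_obs),
                     h_exp_mean = mean(.data$h_exp), h_exp_sd = stats::sd(.data$h_exp),
                     .groups = "drop")
  attr(per_locus, "multilocus") <- multi
  per_locus
}

#' Per-population clonal diversity report
#'
#' Assembles the summary-table statistics for each population: sample
#' counts, clonal richness R, genotypic diversity G_O and G, Simpson
#' evenness ED*, the Pareto clone-size exponent beta (with r^2), rarefied
#' allelic richness, and multilocus H_O / H_E on the clone-censored data.
#' Indices undefined for a degenerate population (e.g. ED* with all
#' singletons) are reported as `NA` with a note.
#'
#' @param table complete-case `genotype_tbl`.
#' @param partition matching `clonal_partition`.
#' @param n_total optional named vector of raw sample counts per site
#'   (before completeness filtering), echoed as `n_total`.
#' @param rarefy_g rarefaction size in genes; default `2 * min(N_MLG)`
#'   across populations.
#' @return tibble of class `diversity_report`, one row per population.
#' @export
clonal_diversity <- function(table, partition, n_total = NULL, rarefy_g = NULL) {
  freqs <- allele_frequencies(table, partition, scheme = "genet")
  genet_tbl <- truncate_dataset(table, partition)
  n_mlg_by_pop <- tapply(partition$mlg, partition$site,
                         function(v) length(unique(v)))
  if (is.null(rarefy_g)) rarefy_g <- 2L * min(n_mlg_by_pop)
  rich <- tryCatch(allelic_richness(freqs, rarefy_g), error = function(e) NULL)
  het <- heterozygosities(genet_tbl)
  het_multi <- attr(het, "multilocus")
  notes <- character(0)

  rows <- purrr::map_dfr(sort(unique(table$site)), function(s) {
    part <- partition[partition$site == s, ]
    sizes <- as.integer(table(part$mlg))
    n <- nrow(part); n_mlg <- length(sizes)
    gd <- genotypic_diversity(sizes)
    ed <- tryCatch(simpson_evenness(sizes), error = function(e) {
      notes <<- c(notes, paste0(s, ": ", conditionMessage(e))); NA_real_
    })
    pf <- tryCatch(pareto_beta(sizes), error = function(e) {
      notes <<- c(notes, paste0(s, ": ", conditionMessage(e))); NULL
    })
    hm <- het_multi[het_multi$pop == s, ]
    tibble::tibble(
      pop = s,
      n_total = if (!is.null(n_total)) unname(n_total[s]) else NA_integer_,
      n = n, n_mlg = n_mlg,
      r = clonal_richness(n, n_mlg),
      g_obs = gd$g_obs, g = gd$g,
      ed_star = ed,
      beta = if (is.null(pf)) NA_real_ else pf$beta,
      beta_r2 = if (is.null(pf)) NA_real_ else pf$r_squared,
      a_hat = if (is.null(rich)) NA_real_ else rich$a_hat[match(s, rich$pop)],
      h_exp = hm$h_exp_mean, h_exp_sd = hm$h_exp_sd,
      h_obs = hm$h_obs_mean, h_obs_sd = hm$h_obs_sd)
  })
  attr(rows, "rarefy_g") <- rarefy_g
  attr(rows, "notes") <- notes
  class(rows) <- c("diversity_report", class(rows))
  rows
}
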