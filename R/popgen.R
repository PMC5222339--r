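#' Clone-censor a genotype table (one representative per MLG per population)
#'
#' The "truncated" dataset of clonal population genetics: exactly one
#' sample per (population, MLG) pair — the first complete-genotype
#' representative in table order — so that every genet counts once
#' regardless of its ramet number.
#'
#' @param table a `genotype_tbl`.
#' @param partition matching `clonal_partition`.
#' @return A `genotype_tbl` of size `sum over populations of N_MLG`.
#' @export
truncate_dataset <- function(table, partition) {
  idx <- match(table$id, partition$id)
  if (anyNA(idx)) stop("partition does not cover the table")
  key <- paste(table$site, partition$mlg[idx], sep = "\r")
  complete <- rowSums(is.na(allele_matrix(table))) == 0L
  ord <- order(!complete)            # complete samples first, stable
  keep_first <- ord[!duplicated(key[ord])]
  table[sort(keep_first), ]
}

# ---- Weir & Cockerham (1984) variance components -------------------------
#
# Per locus and allele, from r populations with n_i genotyped individuals,
# allele frequency p_i and heterozygote frequency h_i (individuals carrying
# exactly one copy):
#   a: among-population, b: among-individual-within-population, c: within-
#   individual components. theta = sum(a) / sum(a + b + c), f (F_IS, r = 1)
#   = 1 - sum(c) / sum(b + c), both ratios taken over alleles and loci.
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  pbar <- sum(n * p) / sum(n)
  hbar <- sum(n * h) / sum(n)
  if (r > 1L) {
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  } else {
    a <- 0
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  }
  c(a = a, b = b, c = hbar / 2)
}

# per-locus population summaries used by fis/pairwise_fst: for one locus,
# a list of (n, p_a vector, h_a vector) per population, over shared alleles
locus_pop_summary <- function(table, loc) {
  a <- table[[paste0(loc, ".1")]]; b <- table[[paste0(loc, ".2")]]
  ok <- !is.na(a) & !is.na(b)
  split_idx <- split(which(ok), table$site[ok])
  alleles <- sort(unique(c(a[ok], b[ok])))
  list(alleles = alleles, pops = lapply(split_idx, function(rows) {
    aa <- a[rows]; bb <- b[rows]
    list(n = length(rows),
         p = vapply(alleles, function(al) mean((aa == al) + (bb == al)) / 2, numeric(1)),
         h = vapply(alleles, function(al) mean(xor(aa == al, bb == al)), numeric(1)))
  }))
}

#' Multilocus F_IS with a permutation HWE test
#'
#' Weir & Cockerham's small-sample within-population fixation index
#' f-hat, aggregated ratio-of-sums over alleles and loci, per population.
#' The null distribution comes from shuffling the 2n gene copies among
#' individuals within the population at each locus, which preserves allele
#' frequencies and destroys the diploid association; the p-value is
#' two-sided (doubled smaller tail, (b+1)/(m+1) corrected).
#'
#' @param table a `genotype_tbl` (all populations; computed per site).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return tibble of class `fis_report`: `pop`, `fis`, `p_value`, `n_perm`,
#'   `seed`; per-locus estimates in attribute `per_locus`.
#' @export
fis <- function(table, n_perm = 10000L, seed) {
  panel <- gt_loci(table)
  pops <- sort(unique(table$site))
  per_locus <- list()
  rows <- purrr::map_dfr(seq_along(pops), function(pi) {
    sub <- table[table$site == pops[pi], ]
    # per locus: allele vectors (2n) and pairing; p's are permutation-invariant
    locs <- list()
    for (loc in panel$locus) {
      a <- sub[[paste0(loc, ".1")]]; b <- sub[[paste0(loc, ".2")]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2L) next
      al <- c(a[ok], b[ok])
      if (length(unique(al)) < 2L) next        # monomorphic: no information
      locs[[loc]] <- al
    }
    if (length(locs) == 0L) stop("all loci monomorphic in population ", pops[pi])
    fis_parts <- function(al, het_obs) {
      n <- length(al) / 2
      p <- as.numeric(table(al)) / (2 * n)
      sum_b_c <- (n / (n - 1)) *
        (1 - sum(p^2) - ((2 * n - 1) / (2 * n)) * het_obs) + het_obs
      c(c = het_obs, bc = sum_b_c)
    }
    obs_tab <- vapply(locs, function(al) {
      n <- length(al) / 2
      fis_parts(al, mean(al[1:n] != al[(n + 1):(2 * n)]))
    }, numeric(2))
    f_obs <- 1 - sum(obs_tab["c", ]) / sum(obs_tab["bc", ])
    per_locus[[pops[pi]]] <<- tibble::tibble(
      pop = pops[pi], locus = colnames(obs_tab),
      fis = 1 - obs_tab["c", ] / obs_tab["bc", ])
    null <- with_perm_seed(seed + pi, n_perm, function() {
      tab <- vapply(locs, function(al) {
        n <- length(al) / 2
        sh <- sample(al)
        fis_parts(al, mean(sh[1:n] != sh[(n + 1):(2 * n)]))
      }, numeric(2))
      1 - sum(tab["c", ]) / sum(tab["bc", ])
    })
    pt <- perm_test(f_obs, null, n_perm, seed + pi, "two.sided", "F_IS (W&C f-hat)")
    tibble::tibble(pop = pops[pi], fis = f_obs, p_value = pt$p_value,
                   n_perm = n_perm, seed = seed + pi)
  })
  attr(rows, "per_locus") <- dplyr::bind_rows(per_locus)
  class(rows) <- c("fis_report", class(rows))
  rows
}

#' Genotypic disequilibrium between locus pairs
#'
#' For each pair of loci, the log-likelihood-ratio G statistic of the
#' contingency table of single-locus genotypes, with a permutation null
#' built by shuffling one locus's genotypes among individuals (which
#' preserves both margins' genotype frequencies). Conventionally run on
#' the clone-censored table so that large clones do not manufacture
#' associations. Significance is reported against a Bonferroni-adjusted
#' threshold `alpha / n_pairs`.
#'
#' @param table a `genotype_tbl` (one population or pooled; used as given).
#' @param loci optional character vector restricting the loci.
#' @param n_perm permutations per pair (default 1000).
#' @param seed RNG seed.
#' @param alpha family-wise level for the Bonferroni column (default 0.05).
#' @return tibble of class `ld_report`: `locus1`, `locus2`, `g_stat`, `p_value`,
#'   `significant_bonferroni`; skipped (monomorphic) pairs carry `NA` and a note.
#' @export
genotypic_ld <- function(table, loci = NULL, n_perm = 1000L, seed, alpha = 0.05) {
  panel <- gt_loci(table)
  if (is.null(loci)) loci <- panel$locus
  if (nrow(table) < 10L) {
    warning("fewer than 10 genets: genotypic disequilibrium tests are weak")
  }
  geno_code <- lapply(loci, function(loc) {
    a <- table[[paste0(loc, ".1")]]; b <- table[[paste0(loc, ".2")]]
    code <- paste(a, b, sep = "/")
    code[is.na(a) | is.na(b)] <- NA
    factor(code)
  })
  names(geno_code) <- loci
  pairs <- utils::combn(loci, 2L)
  n_pairs <- ncol(pairs)
  notes <- character(0)
  rows <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    l1 <- pairs[1, k]; l2 <- pairs[2, k]
    g1 <- geno_code[[l1]]; g2 <- geno_code[[l2]]
    ok <- !is.na(g1) & !is.na(g2)
    g1 <- droplevels(g1[ok]); g2 <- droplevels(g2[ok])
    if (nlevels(g1) < 2L || nlevels(g2) < 2L) {
      notes <<- c(notes, paste0(l1, " x ", l2, ": monomorphic locus, pair skipped"))
      return(tibble::tibble(locus1 = l1, locus2 = l2, g_stat = NA_real_,
                            p_value = NA_real_, significant_bonferroni = NA))
    }
    obs <- g_statistic(table(g1, g2))
    null <- with_perm_seed(seed + k, n_perm, function() {
      g_statistic(table(g1, sample(g2)))
    })
    p <- (sum(null >= obs) + 1) / (n_perm + 1)
    tibble::tibble(locus1 = l1, locus2 = l2, g_stat = obs, p_value = p,
                   significant_bonferroni = p < alpha / n_pairs)
  })
  attr(rows, "n_pairs") <- n_pairs
  attr(rows, "bonferroni_threshold") <- alpha / n_pairs
  attr(rows, "notes") <- notes
  class(rows) <- c("ld_report", class(rows))
  rows
}

g_statistic <- function(tab) {
  o <- as.numeric(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  nz <- o > 0
  2 * sum(o[nz] * log(o[nz] / as.numeric(e)[nz]))
}

# multilocus W&C theta for exactly the populations present in `table`
wc_theta <- function(table, panel) {
  num <- 0; den <- 0
  for (loc in panel$locus) {
    s <- locus_pop_summary(table, loc)
    if (length(s$pops) < 2L) next
    n <- vapply(s$pops, `[[`, numeric(1), "n")
    if (any(n < 2L)) next
    for (ai in seq_along(s$alleles)) {
      p <- vapply(s$pops, function(x) x$p[ai], numeric(1))
      h <- vapply(s$pops, function(x) x$h[ai], numeric(1))
      if (all(p == 0) || all(p == 1)) next
      comp <- wc_components(n, p, h)
      num <- num + comp["a"]
      den <- den + sum(comp)
    }
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

#' Pairwise Weir-Cockerham F_ST with permutation p-values
#'
#' Multilocus theta-hat aggregated as a ratio of summed variance
#' components over alleles and loci, for every pair of populations.
#' P-values permute individuals between the two populations (one-sided,
#' `theta_perm >= theta_obs`).
#'
#' @param table a `genotype_tbl` with >= 2 populations of >= 2 samples.
#' @param n_perm permutations per pair (default 1000; 0 skips testing).
#' @param seed RNG seed (required when `n_perm > 0`).
#' @return list of class `pairwise_matrix`: symmetric `estimate` matrix,
#'   `p_value` matrix (NA diagonal), `statistic = "fst"`.
#' @export
pairwise_fst <- function(table, n_perm = 1000L, seed = NULL) {
  pairwise_diff(table, statistic = "fst", n_perm = n_perm, seed = seed)
}

#' Pairwise Jost's D_est
#'
#' Per locus, with the unbiased within-population heterozygosity
#' `H_S = (2 n~ / (2 n~ - 1)) * mean(1 - sum p_i^2)` (`n~` the harmonic
#' mean sample size) and the total heterozygosity `H_T` from the
#' unweighted mean allele frequencies,
#' `D = ((H_T - H_S) / (1 - H_S)) * r / (r - 1)` with `r = 2` populations;
#' the multilocus value is the arithmetic mean over polymorphic loci.
#'
#' @inheritParams pairwise_fst
#' @return a `pairwise_matrix` with `statistic = "dest"`.
#' @export
pairwise_dest <- function(table, n_perm = 0L, seed = NULL) {
  pairwise_diff(table, statistic = "dest", n_perm = n_perm, seed = seed)
}

jost_d <- function(table, panel) {
  vals <- c()
  for (loc in panel$locus) {
    s <- locus_pop_summary(table, loc)
    if (length(s$pops) < 2L) next
    n <- vapply(s$pops, `[[`, numeric(1), "n")
    if (any(n < 2L)) next
    pmat <- vapply(s$pops, `[[`, numeric(length(s$alleles)), "p")
    if (length(s$alleles) == 1L) pmat <- matrix(pmat, nrow = 1)
    hs_i <- 1 - colSums(pmat^2)
    ntilde <- length(n) / sum(1 / n)
    hs <- (2 * ntilde / (2 * ntilde - 1)) * mean(hs_i)
    pbar <- rowMeans(pmat)
    ht <- 1 - sum(pbar^2)
    if (ht == 0) next                       # monomorphic across both populations
    if (hs >= 1) next                       # degenerate: zero denominator
    r <- length(n)
    vals <- c(vals, ((ht - hs) / (1 - hs)) * r / (r - 1))
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

pairwise_diff <- function(table, statistic, n_perm, seed) {
  panel <- gt_loci(table)
  pops <- sort(unique(table$site))
  if (length(pops) < 2L) stop("need at least two populations")
  sizes <- table(table$site)
  if (any(sizes < 2L)) {
    stop("population(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  if (n_perm > 0L && is.null(seed)) stop("seed required for permutation p-values")
  stat_fn <- if (statistic == "fst") wc_theta else jost_d
  k <- length(pops)
  est <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pair_idx <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pair_idx <- pair_idx + 1L
    sub <- table[table$site %in% c(pops[i], pops[j]), ]
    obs <- stat_fn(sub, panel)
    if (is.na(obs)) {
      stop("no polymorphic locus between ", pops[i], " and ", pops[j])
    }
    est[i, j] <- est[j, i] <- obs
    if (n_perm > 0L && !is.na(obs)) {
      labs <- sub$site
      null <- with_perm_seed(seed + pair_idx, n_perm, function() {
        sub$site <- sample(labs)
        stat_fn(sub, panel)
      })
      p <- (sum(null >= obs, na.rm = TRUE) + 1) / (n_perm + 1)
      pv[i, j] <- pv[j, i] <- p
    }
  }
  structure(list(estimate = est, p_value = pv, statistic = statistic,
                 n_perm = n_perm, seed = seed),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  cat("pairwise", toupper(x$statistic), "\n")
  print(round(x$estimate, digits))
  invisible(x)
}

#' Differentiation analysis on the entire and clone-censored datasets
#'
#' Runs [fis()], [pairwise_fst()] and [pairwise_dest()] twice — on the
#' table as given ("entire", every ramet kept, so clone fitness weighs in)
#' and on the clone-censored table ("truncated", every genet once) — with
#' identical settings. Loci flagged `excluded` in the panel (e.g. null-
#' allele loci) are removed first. Stage failures on degenerate inputs are
#' caught and recorded in `$notes` rather than aborting the other dataset.
#'
#' @param table complete-case `genotype_tbl`.
#' @param partition matching `clonal_partition`.
#' @param n_perm_fis,n_perm_fst permutation counts (defaults 10000, 1000).
#' @param seed RNG seed.
#' @return list of class `dual_analysis` with elements `entire` and
#'   `truncated`, each a list (`fis`, `fst`, `dest`, `n`), plus `notes`.
#' @export
dual_analysis <- function(table, partition, n_perm_fis = 10000L,
                          n_perm_fst = 1000L, seed) {
  table <- drop_excluded_loci(table)
  notes <- character(0)
  run_set <- function(tbl, tag, seed_off) {
    safe <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        notes <<- c(notes, paste0(tag, " ", what, ": ", conditionMessage(e)))
        NULL
      })
    }
    list(n = nrow(tbl),
         fis = safe("fis", fis(tbl, n_perm = n_perm_fis, seed = seed + seed_off)),
         fst = safe("fst", pairwise_fst(tbl, n_perm = n_perm_fst,
                                        seed = seed + seed_off + 1L)),
         dest = safe("dest", pairwise_dest(tbl, n_perm = n_perm_fst,
                                           seed = seed + seed_off + 2L)))
  }
  entire <- run_set(table, "entire", 0L)
  truncated <- run_set(truncate_dataset(table, partition), "truncated", 100L)
  structure(list(entire = entire, truncated = truncated, notes = notes),
            class = "dual_analysis")
}
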