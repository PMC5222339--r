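#' Spatial aggregation of clonemates (Ac)
#'
#' Compares the probability that a colony's nearest neighbour is a
#' clonemate (`P_nn`) with the all-pairs clonemate probability (`P_all`):
#' `Ac = (P_nn - P_all) / (1 - P_all)`. Ac is 0 in expectation when clone
#' labels are independent of position and 1 under complete aggregation.
#' Significance comes from shuffling MLG labels over the fixed coordinates;
#' the p-value is the fraction of permutations with `Ac_perm >= Ac_obs`,
#' with the (b + 1)/(m + 1) correction.
#'
#' @param df data frame with columns `x`, `y`, `mlg` (>= 3 rows; at least
#'   one MLG must be repeated).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed, recorded in the result.
#' @return object of class `perm_test` with fields `statistic`, `p_value`,
#'   `n_perm`, `seed`, `method`, and the permutation null in `null_dist`.
#' @export
aggregation_index <- function(df, n_perm = 1000L, seed) {
  check_spatial(df, min_n = 3L)
  lab <- as.character(df$mlg)
  if (max(table(lab)) < 2L) stop("aggregation undefined without clonemates")
  nn <- nearest_neighbour(df$x, df$y)
  p_all <- clonemate_pair_fraction(lab)
  ac_of <- function(l) (mean(l == l[nn]) - p_all) / (1 - p_all)
  obs <- ac_of(lab)
  null <- with_perm_seed(seed, n_perm, function() ac_of(sample(lab)))
  perm_test(obs, null, n_perm, seed, alternative = "greater",
            method = "aggregation index (Ac)")
}

#' Edge effect of unique genotypes (Ee)
#'
#' Tests whether colonies carrying singleton MLGs (sampled once — putative
#' new sexual recruits) sit closer to the edge of the sampled area than the
#' average colony: with `D_all` the mean distance to the coordinate
#' centroid over all colonies and `D_uniq` the same mean over
#' singleton-MLG colonies, `Ee = (D_uniq - D_all) / D_all`. Positive
#' values displace unique genotypes toward the periphery; significance is
#' one-sided (`Ee_perm >= Ee_obs`) under MLG-label permutation.
#'
#' @inheritParams aggregation_index
#' @return a `perm_test`.
#' @export
edge_effect <- function(df, n_perm = 1000L, seed) {
  check_spatial(df, min_n = 3L)
  lab <- as.character(df$mlg)
  singleton <- names(which(table(lab) == 1L))
  if (length(singleton) == 0L) stop("edge effect undefined without singleton MLGs")
  d_centroid <- sqrt((df$x - mean(df$x))^2 + (df$y - mean(df$y))^2)
  d_all <- mean(d_centroid)
  ee_of <- function(l) (mean(d_centroid[l %in% singleton]) - d_all) / d_all
  obs <- ee_of(lab)
  null <- with_perm_seed(seed, n_perm, function() ee_of(sample(lab)))
  perm_test(obs, null, n_perm, seed, alternative = "greater",
            method = "edge effect (Ee)")
}

#' Moran's I of allele frequencies against geography
#'
#' Global spatial autocorrelation of individual allele dosages: for every
#' allele `a` at a polymorphic locus, `x_i` is the dosage (copies of
#' `a` in colony i, divided by 2), and Moran's I is computed with
#' inverse-distance weights `w_ij = 1 / d_ij` collapsed into a single
#' distance class. Alleles are averaged weighting by their dosage variance
#' (zero-variance alleles drop out). The two-sided p-value permutes the
#' assignment of coordinates to colonies. Under the null, E(I) = -1/(n-1).
#'
#' @param table a complete-case `genotype_tbl` for one population with `x`,
#'   `y` columns (>= 4 rows, not all coincident).
#' @param n_perm number of coordinate permutations (default 1000).
#' @param seed RNG seed.
#' @return a `perm_test`.
#' @export
morans_i <- function(table, n_perm = 1000L, seed) {
  check_spatial(table, min_n = 4L, need_mlg = FALSE)
  d <- as.matrix(stats::dist(cbind(table$x, table$y)))
  pos <- d[upper.tri(d)]
  pos <- pos[pos > 0]
  if (length(pos) == 0L) stop("all samples coincident; Moran's I undefined")
  d[d == 0] <- min(pos)          # coincident points get the minimum distance
  w <- 1 / d
  diag(w) <- 0
  w_tot <- sum(w)
  n <- nrow(table)

  panel <- gt_loci(table)
  dos <- dosage_matrix(table, panel)          # n x n_alleles, values 0/.5/1
  xc <- scale(dos, center = TRUE, scale = FALSE)
  v <- colSums(xc^2)
  xc <- xc[, v > 0, drop = FALSE]
  if (ncol(xc) == 0L) stop("no polymorphic allele; Moran's I undefined")
  # variance-weighted mean over alleles reduces to a single kernel sum:
  # I = (n / W) * sum_ij w_ij K_ij / trace(K), K = Xc Xc'
  k <- tcrossprod(xc)
  i_of <- function(ord) (n / w_tot) * sum(w * k[ord, ord]) / sum(diag(k))
  obs <- i_of(seq_len(n))
  null <- with_perm_seed(seed, n_perm, function() i_of(sample.int(n)))
  perm_test(obs, null, n_perm, seed, alternative = "two.sided",
            method = "Moran's I (inverse-distance weights)")
}

# allele dosage matrix: one column per (locus, allele), entries in {0, .5, 1}
dosage_matrix <- function(table, panel) {
  cols <- lapply(panel$locus, function(loc) {
    a <- table[[paste0(loc, ".1")]]; b <- table[[paste0(loc, ".2")]]
    alleles <- sort(unique(c(a, b)))
    m <- vapply(alleles, function(al) ((a == al) + (b == al)) / 2, numeric(nrow(table)))
    colnames(m) <- paste0(loc, ":", alleles)
    m
  })
  do.call(cbind, cols)
}

#' Spatial clonal-structure report for every mapped population
#'
#' Runs [aggregation_index()], [edge_effect()] and [morans_i()] for each
#' population that has coordinates; populations without coordinates are
#' skipped (statistics absent, not zero), and statistics whose
#' preconditions fail within a population are reported as `NA` with a note.
#'
#' @param table complete-case `genotype_tbl`.
#' @param partition matching `clonal_partition`.
#' @param n_perm permutations per test (default 1000).
#' @param seed base seed; each population/test gets a distinct derived seed.
#' @return tibble of class `spatial_report`: `pop`, `ac`, `p_ac`, `ee`,
#'   `p_ee`, `moran_i`, `p_i`, `n_perm`, `seed`.
#' @export
spatial_report <- function(table, partition, n_perm = 1000L, seed) {
  has_xy <- all(c("x", "y") %in% names(table))
  pops <- sort(unique(table$site))
  notes <- character(0)
  rows <- purrr::map_dfr(seq_along(pops), function(pi) {
    s <- pops[pi]
    sub <- table[table$site == s, ]
    part <- partition[match(sub$id, partition$id), ]
    if (!has_xy || anyNA(sub$x) || anyNA(sub$y)) {
      notes <<- c(notes, paste0(s, ": no coordinates; spatial statistics skipped"))
      return(tibble::tibble(pop = s, ac = NA_real_, p_ac = NA_real_,
                            ee = NA_real_, p_ee = NA_real_,
                            moran_i = NA_real_, p_i = NA_real_,
                            n_perm = n_perm, seed = seed))
    }
    df <- tibble::tibble(x = sub$x, y = sub$y, mlg = part$mlg)
    run <- function(idx, fn, ...) {
      tryCatch(fn(..., n_perm = n_perm, seed = seed + 13L * pi + idx),
               error = function(e) {
                 notes <<- c(notes, paste0(s, ": ", conditionMessage(e)))
                 NULL
               })
    }
    ac_t <- run(1L, aggregation_index, df)
    ee_t <- run(2L, edge_effect, df)
    mi_t <- run(3L, morans_i, sub)
    tibble::tibble(pop = s,
                   ac = stat_or_na(ac_t), p_ac = p_or_na(ac_t),
                   ee = stat_or_na(ee_t), p_ee = p_or_na(ee_t),
                   moran_i = stat_or_na(mi_t), p_i = p_or_na(mi_t),
                   n_perm = n_perm, seed = seed)
  })
  attr(rows, "notes") <- notes
  class(rows) <- c("spatial_report", class(rows))
  rows
}

stat_or_na <- function(x) if (is.null(x)) NA_real_ else x$statistic
p_or_na <- function(x) if (is.null(x)) NA_real_ else x$p_value

check_spatial <- function(df, min_n, need_mlg = TRUE) {
  need <- c("x", "y", if (need_mlg) "mlg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < min_n) stop("need at least ", min_n, " mapped samples")
  if (anyNA(df$x) || anyNA(df$y)) stop("coordinates contain NA")
  invisible(df)
}

nearest_neighbour <- function(x, y) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1L, which.min)        # which.min resolves ties by lowest index
}

clonemate_pair_fraction <- function(lab) {
  n <- length(lab)
  sizes <- table(lab)
  sum(sizes * (sizes - 1) / 2) / (n * (n - 1) / 2)
}

with_perm_seed <- function(seed, n_perm, fn) {
  stopifnot(!missing(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) fn(), numeric(1))
}

perm_test <- function(statistic, null_dist, n_perm, seed,
                      alternative = c("greater", "less", "two.sided"),
                      method = "permutation test") {
  alternative <- match.arg(alternative)
  m <- length(null_dist)
  p_up <- (sum(null_dist >= statistic) + 1) / (m + 1)
  p_dn <- (sum(null_dist <= statistic) + 1) / (m + 1)
  p <- switch(alternative,
              greater = p_up, less = p_dn,
              two.sided = min(1, 2 * min(p_up, p_dn)))
  structure(list(statistic = statistic, p_value = p, n_perm = n_perm,
                 seed = seed, alternative = alternative, method = method,
                 null_dist = null_dist),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s, %d permutations, seed %s)\n",
              x$method, x$statistic, x$p_value, x$alternative, x$n_perm,
              format(x$seed)))
  invisible(x)
}
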