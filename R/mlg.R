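#' Identify multilocus genotypes (MLGs)
#'
#' Two samples share an MLG iff every locus carries the identical unordered
#' allele pair. MLG ids are assigned by decreasing abundance, ties broken
#' by first occurrence, so `MLG01` is always the most abundant genotype
#' (the superclone, if there is one).
#'
#' @param table a complete-case `genotype_tbl` (see [complete_cases()]).
#' @return A tibble of class `clonal_partition` with columns `id`, `site`,
#'   `mlg` and an `mll` column initialised to `NA` (filled by
#'   [collapse_mll()]).
#' @export
identify_mlgs <- function(table) {
  if (nrow(table) == 0L) stop("cannot identify MLGs in an empty table")
  m <- allele_matrix(table)
  if (anyNA(m)) {
    stop("table contains missing calls; apply complete_cases() first")
  }
  key <- apply(m, 1L, paste, collapse = "/")
  first <- match(unique(key), key)
  counts <- table(key)[unique(key)]
  ord <- order(-as.integer(counts), first)
  ranked <- unique(key)[ord]
  width <- max(2L, nchar(length(ranked)))
  ids <- sprintf(paste0("MLG%0", width, "d"), seq_along(ranked))
  out <- tibble::tibble(id = table$id, site = table$site,
                        mlg = ids[match(key, ranked)],
                        mll = NA_character_)
  class(out) <- c("clonal_partition", class(out))
  attr(out, "threshold") <- NA_integer_
  out
}

#' Clone (MLG) size spectrum
#' @param partition a `clonal_partition`.
#' @param by count per `"mlg"` (default) or `"mll"`.
#' @return tibble `mlg` (or `mll`), `n`, sorted by decreasing size.
#' @export
clone_sizes <- function(partition, by = c("mlg", "mll")) {
  by <- match.arg(by)
  if (by == "mll" && all(is.na(partition$mll))) {
    stop("partition has no MLL assignment; run collapse_mll() first")
  }
  dplyr::arrange(dplyr::count(partition, .data[[by]]), dplyr::desc(.data$n))
}

#' One representative sample per MLG
#'
#' @param table the complete-case `genotype_tbl` the partition was built on.
#' @param partition a `clonal_partition`.
#' @return A `genotype_tbl` with one row per MLG (the first occurrence),
#'   whose `id` column is replaced by the MLG id.
#' @export
mlg_representatives <- function(table, partition) {
  first <- partition[!duplicated(partition$mlg), ]
  out <- table[match(first$id, table$id), ]
  out$id <- first$mlg
  out[order(out$id), ]
}

#' Allele frequencies per population and locus
#'
#' The genet-level (`"genet"`) scheme counts one representative per MLG per
#' population, removing the inflation that large clones impose on ramet
#' counts; the ramet-level (`"ramet"`) scheme counts every sample. Missing
#' calls are dropped locus-wise.
#'
#' @param table a `genotype_tbl`.
#' @param partition a `clonal_partition` (required for the genet scheme).
#' @param scheme `"genet"` (default) or `"ramet"`.
#' @return A tibble of class `allele_freqs` with columns `pop`, `locus`,
#'   `allele`, `count`, `freq`, `n_genes`.
#' @export
allele_frequencies <- function(table, partition = NULL,
                               scheme = c("genet", "ramet")) {
  scheme <- match.arg(scheme)
  if (nrow(table) == 0L) stop("empty genotype table")
  if (scheme == "genet") {
    if (is.null(partition)) stop("genet-level frequencies need a clonal partition")
    table <- truncate_dataset(table, partition)
  }
  panel <- gt_loci(table)
  out <- purrr::map_dfr(split(seq_len(nrow(table)), table$site), function(rows) {
    sub <- table[rows, ]
    purrr::map_dfr(panel$locus, function(loc) {
      al <- c(sub[[paste0(loc, ".1")]], sub[[paste0(loc, ".2")]])
      al <- al[!is.na(al)]
      if (length(al) == 0L) return(NULL)
      tab <- table(al)
      tibble::tibble(pop = sub$site[1], locus = loc,
                     allele = as.integer(names(tab)),
                     count = as.integer(tab),
                     freq = as.integer(tab) / length(al),
                     n_genes = length(al))
    })
  })
  attr(out, "scheme") <- scheme
  class(out) <- c("allele_freqs", class(out))
  out
}

#' Probability of a multilocus genotype under inbreeding
#'
#' Per-locus genotype probabilities allowing a departure from
#' Hardy-Weinberg through a single inbreeding coefficient F_IS:
#' heterozygote A/B contributes `2 p_A p_B (1 - F_IS)`, homozygote A/A
#' contributes `p_A^2 + p_A (1 - p_A) F_IS`; the multilocus probability is
#' their product.
#'
#' @param table a `genotype_tbl` (typically complete-case); one probability
#'   is returned per row, using the allele frequencies of the row's own
#'   population.
#' @param freqs an [allele_frequencies()] table covering every allele that
#'   occurs (an absent allele is an error, not a zero).
#' @param f_is inbreeding coefficient in `[-1, 1)`; a value making any
#'   locus term negative is an error.
#' @return tibble `id`, `pop`, `p_gen`.
#' @export
p_gen <- function(table, freqs, f_is = 0) {
  stopifnot(length(f_is) == 1L, f_is >= -1, f_is <= 1)
  panel <- gt_loci(table)
  fmap <- split(freqs, list(freqs$pop, freqs$locus), drop = TRUE)
  pg <- vapply(seq_len(nrow(table)), function(i) {
    prob <- 1
    for (loc in panel$locus) {
      a <- table[[paste0(loc, ".1")]][i]
      b <- table[[paste0(loc, ".2")]][i]
      if (is.na(a) || is.na(b)) {
        stop("missing call at ", loc, " for sample ", table$id[i])
      }
      f <- fmap[[paste(table$site[i], loc, sep = ".")]]
      pa <- f$freq[match(a, f$allele)]
      pb <- f$freq[match(b, f$allele)]
      if (is.na(pa) || is.na(pb)) {
        stop("allele absent from frequency table at ", loc,
             " (sample ", table$id[i], ")")
      }
      term <- if (a == b) pa^2 + pa * (1 - pa) * f_is else 2 * pa * pb * (1 - f_is)
      if (term < 0) {
        stop("negative genotype probability at ", loc,
             " with f_is = ", f_is)
      }
      prob <- prob * term
    }
    prob
  }, numeric(1))
  tibble::tibble(id = table$id, pop = table$site, p_gen = pg)
}

#' Probability that a repeated MLG arose from independent sexual events
#'
#' The probability that, among the `n_samples - 1` sampling units other
#' than the first carrier, at least `n_obs - 1` independently drew the
#' same multilocus genotype (probability `pgen`) through sexual
#' recombination: the upper binomial tail
#' `P(X >= n_obs - 1), X ~ Binomial(n_samples - 1, pgen)`. Small values
#' reject the sexual-origin hypothesis and support clonality.
#'
#' @param n_obs observed copies of the MLG (>= 1).
#' @param n_samples total sampling units (>= n_obs).
#' @param pgen genotype probability in `[0, 1]` (see [p_gen()]).
#' @return numeric vector of probabilities (arguments are recycled).
#' @export
p_sex <- function(n_obs, n_samples, pgen) {
  k <- vctrs_recycle_int(n_obs, max(length(n_obs), length(n_samples), length(pgen)), "n_obs")
  n <- rep_len(as.integer(n_samples), length(k))
  p <- rep_len(as.numeric(pgen), length(k))
  if (any(k < 1L) || any(k > n)) stop("need 1 <= n_obs <= n_samples")
  if (any(p < 0 | p > 1)) stop("pgen must lie in [0, 1]")
  # P(X >= k - 1) with X ~ Bin(n - 1, p)
  ifelse(k == 1L, 1, stats::pbinom(k - 2L, n - 1L, p, lower.tail = FALSE))
}

#' Probability of identity across loci
#'
#' The probability that two independent sexual products share the same
#' multilocus genotype by chance: the product over loci of
#' `2 (sum p_i^2)^2 - sum p_i^4`.
#'
#' @param freqs an [allele_frequencies()] table for one population (or
#'   pooled frequencies).
#' @param loci optional subset of loci.
#' @return A tibble `pop`, `p_id`.
#' @export
p_id <- function(freqs, loci = NULL) {
  if (!is.null(loci)) freqs <- freqs[freqs$locus %in% loci, ]
  if (nrow(freqs) == 0L) stop("no loci left in frequency table")
  freqs |>
    dplyr::group_by(.data$pop, .data$locus) |>
    dplyr::summarise(term = 2 * sum(.data$freq^2)^2 - sum(.data$freq^4),
                     .groups = "drop_last") |>
    dplyr::summarise(p_id = prod(.data$term), .groups = "drop")
}

#' Stepwise-mutation-model distance between two genotypes
#'
#' At each locus the two unordered allele pairs are matched in whichever of
#' the two pairings minimises the summed absolute size difference, and the
#' result is divided by the repeat-motif length to count mutation steps;
#' loci then sum. A size difference not divisible by the motif is an error
#' naming the locus.
#'
#' @param g1,g2 single-row `genotype_tbl`s or named integer vectors laid
#'   out as the rows of [allele_matrix()].
#' @param panel the [locus_panel()] (taken from `g1` when it is a table).
#' @return integer: total mutation steps.
#' @export
smm_distance <- function(g1, g2, panel = NULL) {
  if (inherits(g1, "genotype_tbl")) {
    panel <- gt_loci(g1)
    g1 <- allele_matrix(g1)[1L, ]
  }
  if (inherits(g2, "genotype_tbl")) g2 <- allele_matrix(g2)[1L, ]
  if (is.null(panel)) stop("need a locus panel")
  sum(smm_locus_steps(matrix(g1, nrow = 1), matrix(g2, nrow = 1), panel))
}

# per-locus SMM steps for row-matched matrices (n x 2L each); returns n x L
smm_locus_steps <- function(m1, m2, panel) {
  L <- nrow(panel)
  out <- matrix(0L, nrow(m1), L)
  for (l in seq_len(L)) {
    a1 <- m1[, 2L * l - 1L]; a2 <- m1[, 2L * l]
    b1 <- m2[, 2L * l - 1L]; b2 <- m2[, 2L * l]
    if (anyNA(c(a1, a2, b1, b2))) {
      stop("missing call at ", panel$locus[l], "; SMM distance needs complete genotypes")
    }
    # SMM requires all alleles at a locus on one repeat ladder: every
    # pairwise size difference must be a multiple of the motif
    mod <- panel$motif_length[l]
    if (mod > 1L) {
      cls <- cbind(a1, a2, b1, b2) %% mod
      if (any(cls != cls[, 1])) {
        stop("allele-size difference at ", panel$locus[l],
             " not divisible by motif length ", mod)
      }
    }
    d <- pmin(abs(a1 - b1) + abs(a2 - b2), abs(a1 - b2) + abs(a2 - b1))
    out[, l] <- d %/% mod
  }
  out
}

#' Pairwise SMM distance matrix among MLGs
#'
#' @param table complete-case `genotype_tbl`.
#' @param partition a `clonal_partition`; distances are computed between
#'   MLG representatives.
#' @return symmetric integer matrix of mutation steps, dimnames = MLG ids.
#'   Note the per-locus minimal pairing can violate the triangle
#'   inequality; only symmetry and the zero diagonal are guaranteed.
#' @export
smm_distance_matrix <- function(table, partition) {
  reps <- mlg_representatives(table, partition)
  panel <- gt_loci(reps)
  if (any(panel$motif_length == 1L)) {
    warning("loci with motif length 1: distances there count base pairs")
  }
  m <- allele_matrix(reps)
  n <- nrow(m)
  d <- matrix(0L, n, n, dimnames = list(reps$id, reps$id))
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    steps <- smm_locus_steps(m[rep(i, length(js)), , drop = FALSE],
                             m[js, , drop = FALSE], panel)
    d[i, js] <- d[js, i] <- as.integer(rowSums(steps))
  }
  d
}

#' Gap-derived threshold for collapsing MLGs into MLLs
#'
#' Scans the distribution of pairwise inter-MLG distances for its first
#' gap: the threshold is the smallest positive step count at which no MLG
#' pair sits. If the minimum observed distance is one step there is no
#' leading gap that separates scoring error from real divergence, and the
#' threshold is 0 (no collapsing).
#'
#' @param dist matrix from [smm_distance_matrix()] (>= 2 MLGs).
#' @return integer threshold.
#' @export
find_collapse_threshold <- function(dist) {
  if (nrow(dist) < 2L) stop("need at least two MLGs to derive a threshold")
  d <- dist[upper.tri(dist)]
  if (1L %in% d) return(0L)
  gaps <- setdiff(seq_len(max(d, 1L)), d)
  as.integer(gaps[1])
}

#' Collapse MLGs into multilocus lineages (MLLs)
#'
#' Single-linkage components of the graph whose edges join MLG pairs at
#' distance <= `threshold`. A threshold of 0 leaves every MLG its own MLL.
#' MLL ids are assigned by decreasing ramet abundance, mirroring MLG
#' naming.
#'
#' @param partition a `clonal_partition` from [identify_mlgs()].
#' @param dist matrix from [smm_distance_matrix()].
#' @param threshold integer >= 0, e.g. from [find_collapse_threshold()].
#' @return The partition with its `mll` column filled and attribute
#'   `threshold` set.
#' @export
collapse_mll <- function(partition, dist, threshold) {
  stopifnot(threshold >= 0)
  mlgs <- rownames(dist)
  if (threshold == 0L) {
    comp <- stats::setNames(seq_along(mlgs), mlgs)
  } else {
    adj <- dist <= threshold
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  }
  # name components by total ramet abundance, then first occurrence
  sizes <- table(partition$mlg)[mlgs]
  comp_size <- tapply(as.integer(sizes), comp, sum)
  first <- tapply(seq_along(mlgs), comp, min)
  ord <- order(-comp_size, first)
  width <- max(2L, nchar(length(ord)))
  mll_ids <- sprintf(paste0("MLL%0", width, "d"), match(comp, names(comp_size)[ord]))
  names(mll_ids) <- mlgs
  partition$mll <- mll_ids[partition$mlg]
  attr(partition, "threshold") <- as.integer(threshold)
  partition
}

#' Per-MLG clonality summary: sizes, P_gen and P_SEX
#'
#' @param table complete-case `genotype_tbl`.
#' @param partition a `clonal_partition`.
#' @param freqs an [allele_frequencies()] table (genet-level by default
#'   upstream).
#' @param f_is inbreeding coefficient fed to [p_gen()].
#' @return tibble `mlg`, `pop`, `n`, `p_gen`, `p_sex` — one row per
#'   (population, MLG) occurrence, with `p_sex` evaluated against the
#'   population's sample count.
#' @export
mlg_summary <- function(table, partition, freqs, f_is = 0) {
  reps <- mlg_representatives(table, partition)
  occ <- dplyr::count(partition, .data$site, .data$mlg, name = "n")
  pop_n <- dplyr::count(partition, .data$site, name = "n_pop")
  occ <- dplyr::left_join(occ, pop_n, by = "site")
  rep_tbl <- reps[match(occ$mlg, reps$id), ]
  rep_tbl$site <- occ$site     # evaluate p_gen under the occurrence population
  pg <- p_gen(rep_tbl, freqs, f_is = f_is)$p_gen
  tibble::tibble(mlg = occ$mlg, pop = occ$site, n = occ$n,
                 p_gen = pg,
                 p_sex = p_sex(occ$n, occ$n_pop, pg)) |>
    dplyr::arrange(.data$mlg, .data$pop)
}
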