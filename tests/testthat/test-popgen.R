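# independent scalar implementation of the Weir & Cockerham (1984) variance
# components, written directly from the 1984 formulas for the test only
wc_oracle_theta <- function(pop_list) {
  # pop_list: per population, a two-column matrix of alleles (one locus)
  alleles <- sort(unique(unlist(pop_list)))
  r <- length(pop_list)
  n <- vapply(pop_list, nrow, numeric(1))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  num <- 0; den <- 0
  for (al in alleles) {
    p <- vapply(pop_list, function(m) mean(m == al), numeric(1))
    h <- vapply(pop_list, function(m) mean((m[, 1] == al) != (m[, 2] == al)),
                numeric(1))
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                          (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

two_pop_table <- function(alleles1, alleles2, loci = "L1") {
  # alleles*: list per locus of two-column matrices
  mk <- function(allele_list, site, offset) {
    n <- nrow(allele_list[[1]])
    df <- tibble::tibble(id = sprintf("%s%03d", site, seq_len(n)), site = site)
    for (i in seq_along(loci)) {
      m <- allele_list[[i]]
      df[[paste0(loci[i], ".1")]] <- as.integer(pmin(m[, 1], m[, 2]))
      df[[paste0(loci[i], ".2")]] <- as.integer(pmax(m[, 1], m[, 2]))
    }
    df
  }
  genotype_table(dplyr::bind_rows(mk(alleles1, "P1"), mk(alleles2, "P2")))
}

test_that("clone-censoring keeps one representative per MLG per population", {
  cfg <- sim_config(ramets_per_site = c(60, 60, 30, 30), seed = 6,
                    missing_rate = 0)
  sim <- simulate_dataset(cfg)
  part <- identify_mlgs(sim$table)
  trunc <- truncate_dataset(sim$table, part)
  per_pop_mlg <- tapply(part$mlg, part$site, function(v) length(unique(v)))
  expect_equal(nrow(trunc), sum(per_pop_mlg))

  # all-unique table is untouched
  rt <- random_table(15, L = 10, seed = 8)
  prt <- identify_mlgs(rt)
  expect_equal(nrow(truncate_dataset(rt, prt)), 15L)

  # an MLG shared by two populations keeps one representative in each
  df <- tibble::as_tibble(tiny_table())
  df$site <- c("A", "A", "B", "B", "B")
  tbl <- genotype_table(df, panel = gt_loci(tiny_table()))
  p <- identify_mlgs(tbl)
  tr <- truncate_dataset(tbl, p)
  expect_equal(nrow(tr), 3L)   # clone1 in A and B, clone2 in B
})

test_that("F_IS reaches its boundary values and matches HWE simulations", {
  het <- genotype_table(tibble::tibble(
    id = paste0("s", 1:10), site = "P",
    L1.1 = 100L, L1.2 = 102L))
  expect_equal(fis(het, n_perm = 199, seed = 1)$fis, -1)

  hom <- genotype_table(tibble::tibble(
    id = paste0("s", 1:10), site = "P",
    L1.1 = rep(c(100L, 102L), each = 5),
    L1.2 = rep(c(100L, 102L), each = 5)))
  expect_equal(fis(hom, n_perm = 199, seed = 1)$fis, 1)

  big <- random_table(600, L = 8, seed = 55)
  f <- fis(big, n_perm = 199, seed = 9)
  expect_lt(abs(f$fis), 0.05)
  expect_gt(f$p_value, 0.05)

  mono <- genotype_table(tibble::tibble(id = c("a", "b", "c"), site = "P",
                                        L1.1 = 100L, L1.2 = 100L))
  expect_error(fis(mono, n_perm = 199, seed = 1), "monomorphic")
})

test_that("generator inbreeding is recovered by the F_IS estimator", {
  cfg <- sim_config(ramets_per_site = 500L, sites = "s", site_centers_x = 0,
                    cluster_of_site = "1", superclone_fraction = NULL,
                    clone_size_beta = 1e6, f_is = 0.5, missing_rate = 0,
                    seed = 14)
  sim <- simulate_dataset(cfg)
  f <- fis(sim$table, n_perm = 199, seed = 2)
  expect_lt(abs(f$fis - 0.5), 0.1)
})

test_that("W&C theta matches the independent component oracle and boundaries", {
  # fixed for different alleles at every locus: theta = 1
  n <- 8
  fixed <- two_pop_table(list(matrix(100L, n, 2)), list(matrix(104L, n, 2)))
  expect_equal(pairwise_fst(fixed, n_perm = 0)$estimate["P1", "P2"], 1)

  # small worked instance against the scalar oracle
  set.seed(19)
  for (rep in 1:5) {
    a1 <- matrix(sample(c(100L, 102L, 104L), 8, TRUE), 4, 2)
    a2 <- matrix(sample(c(100L, 102L, 104L), 8, TRUE), 4, 2)
    if (length(unique(c(a1, a2))) < 2) next
    tbl <- two_pop_table(list(a1), list(a2))
    got <- pairwise_fst(tbl, n_perm = 0)$estimate["P1", "P2"]
    expect_equal(got, wc_oracle_theta(list(a1, a2)), tolerance = 1e-12)
  }

  # a random split of one panmictic population: theta ~ 0, p uniform-ish
  big <- random_table(200, L = 8, sites = rep(c("A", "B"), 100), seed = 23)
  res <- pairwise_fst(big, n_perm = 199, seed = 31)
  expect_lt(abs(res$estimate["A", "B"]), 0.02)
  expect_gt(res$p_value["A", "B"], 0.05)

  small <- random_table(3, L = 4, sites = c("A", "A", "B"), seed = 1)
  expect_error(pairwise_fst(small, n_perm = 0), "fewer than 2")
})

test_that("Jost's D_est matches hand evaluation and boundaries", {
  n <- 8
  fixed <- two_pop_table(list(matrix(100L, n, 2)), list(matrix(104L, n, 2)))
  expect_equal(pairwise_dest(fixed)$estimate["P1", "P2"], 1)

  # freqs (0.9, 0.1) vs (0.1, 0.9), n = 50 each: hand evaluation
  a1 <- matrix(rep(c(100L, 102L), c(90, 10)), ncol = 2)   # 50 x 2, p(100)=0.9
  a2 <- matrix(rep(c(100L, 102L), c(10, 90)), ncol = 2)
  tbl <- two_pop_table(list(a1), list(a2))
  hs <- (2 * 50 / (2 * 50 - 1)) * 0.18
  expected <- ((0.5 - hs) / (1 - hs)) * 2
  expect_equal(pairwise_dest(tbl)$estimate["P1", "P2"], expected)

  # identical frequencies, equal sizes: |D| small
  big <- random_table(400, L = 8, sites = rep(c("A", "B"), 200), seed = 41)
  expect_lt(abs(pairwise_dest(big)$estimate["A", "B"]), 0.02)

  mono <- two_pop_table(list(matrix(100L, 4, 2)), list(matrix(100L, 4, 2)))
  expect_error(pairwise_dest(mono), "no polymorphic")
})

test_that("theta and D_est are invariant under allele relabeling and locus order", {
  set.seed(73)
  tbl <- random_table(60, L = 4, sites = rep(c("A", "B"), 30), seed = 73)
  t1 <- pairwise_fst(tbl, n_perm = 0)$estimate["A", "B"]
  d1 <- pairwise_dest(tbl)$estimate["A", "B"]
  # relabel alleles (order-preserving shift) and permute locus blocks
  df <- tibble::as_tibble(tbl)
  for (col in grep("^L0[12]", names(df), value = TRUE)) {
    df[[col]] <- df[[col]] + 40L
  }
  panel <- gt_loci(tbl)
  perm_loci <- rev(panel$locus)
  df2 <- df[, c("id", "site",
                as.vector(rbind(paste0(perm_loci, ".1"), paste0(perm_loci, ".2"))))]
  tbl2 <- genotype_table(df2, panel = panel[match(perm_loci, panel$locus), ])
  expect_equal(pairwise_fst(tbl2, n_perm = 0)$estimate["A", "B"], t1)
  expect_equal(pairwise_dest(tbl2)$estimate["A", "B"], d1)
})

test_that("Balding-Nichols divergence is recovered by multilocus theta", {
  for (f_target in c(0.05, 0.2)) {
    vals <- vapply(1:10, function(r) {
      cfg <- sim_config(ramets_per_site = c(50L, 50L), sites = c("a", "b"),
                        site_centers_x = c(0, 100), cluster_of_site = c("1", "2"),
                        divergence_f = f_target, f_is = 0,
                        superclone_fraction = NULL, clone_size_beta = 1e6,
                        missing_rate = 0, seed = 700 + r)
      sim <- simulate_dataset(cfg)
      pairwise_fst(sim$table, n_perm = 0)$estimate["a", "b"]
    }, numeric(1))
    expect_lt(abs(mean(vals) - f_target) / f_target, 0.30)
  }
})

test_that("genotypic disequilibrium counts pairs and flags constructed LD", {
  tbl <- random_table(50, L = 13, seed = 91)
  ld <- genotypic_ld(tbl, n_perm = 199, seed = 3)
  expect_equal(nrow(ld), 78L)

  # duplicated locus: perfect association
  df <- tibble::as_tibble(random_table(100, L = 1, n_alleles = 4, seed = 92))
  df$L02.1 <- df$L01.1; df$L02.2 <- df$L01.2
  dup <- genotype_table(df)
  res <- genotypic_ld(dup, n_perm = 999, seed = 5)
  expect_lte(res$p_value[1], 0.001)

  # independent loci are rarely significant
  ind <- genotypic_ld(random_table(80, L = 2, seed = 93), n_perm = 199, seed = 7)
  expect_gt(ind$p_value[1], 0.01)
})

test_that("dual analysis runs both datasets and degrades gracefully", {
  cfg <- sim_config(ramets_per_site = c(60, 60, 30, 30), seed = 16,
                    missing_rate = 0)
  sim <- simulate_dataset(cfg)
  part <- identify_mlgs(sim$table)
  da <- dual_analysis(sim$table, part, n_perm_fis = 199, n_perm_fst = 99,
                      seed = 21)
  expect_s3_class(da, "dual_analysis")
  expect_equal(da$truncated$n, length(unique(paste(part$site, part$mlg))))
  td <- tidy(da)
  expect_setequal(unique(td$dataset), c("entire", "truncated"))
  # small negatives are estimator noise; the truncated samples are tiny
  # (a handful of genets per site), so their D_est noise band is wider
  expect_true(all(td$estimate[td$dataset == "entire"] > -0.1))
  expect_true(all(td$estimate <= 1))

  # entire vs truncated F_IS move in the direction clonal structure implies:
  # ramet duplication of heterozygous superclones depresses F_IS entire
  fe <- da$entire$fis; ft <- da$truncated$fis
  expect_true(is.data.frame(fe) && is.data.frame(ft))

  # monoclonal two-site dataset: truncated stage fails, entire may too, but
  # the analysis still returns with notes rather than aborting
  mono <- genotype_table(tibble::tibble(
    id = paste0("s", 1:6), site = rep(c("A", "B"), each = 3),
    L1.1 = 100L, L1.2 = 102L))
  pm <- identify_mlgs(mono)
  dm <- dual_analysis(mono, pm, n_perm_fis = 199, n_perm_fst = 99, seed = 8)
  expect_true(length(dm$notes) >= 1)

  # all-unique dataset: entire and truncated estimates coincide
  uq <- random_table(40, L = 6, sites = rep(c("A", "B"), 20), seed = 94)
  pu <- identify_mlgs(uq)
  du <- dual_analysis(uq, pu, n_perm_fis = 199, n_perm_fst = 99, seed = 9)
  expect_equal(du$entire$fst$estimate, du$truncated$fst$estimate)
})

test_that("excluded loci are dropped from structure analyses", {
  tbl <- random_table(30, L = 4, sites = rep(c("A", "B"), 15), seed = 95)
  panel <- gt_loci(tbl)
  panel$excluded[1:2] <- TRUE
  attr(tbl, "loci") <- panel
  part <- identify_mlgs(tbl)
  da <- dual_analysis(tbl, part, n_perm_fis = 199, n_perm_fst = 99, seed = 10)
  expect_equal(nrow(attr(da$entire$fis, "per_locus")) / 2, 2)  # 2 pops x 2 kept loci
})
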