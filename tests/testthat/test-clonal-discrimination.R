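test_that("MLG identification groups identical genotypes and ranks by abundance", {
  tbl <- tiny_table()
  part <- identify_mlgs(tbl)
  sizes <- clone_sizes(part)
  expect_equal(sizes$n, c(3L, 2L))
  expect_equal(sizes$mlg, c("MLG01", "MLG02"))   # superclone is MLG01

  distinct <- random_table(8, L = 13, seed = 2)
  expect_equal(length(unique(identify_mlgs(distinct)$mlg)), 8L)

  expect_error(identify_mlgs(tiny_table()[0, ]), "empty")
  raw <- tibble::as_tibble(tiny_table())
  raw$La.1[1] <- NA_integer_; raw$La.2[1] <- NA_integer_
  expect_error(identify_mlgs(genotype_table(raw, panel = gt_loci(tiny_table()))),
               "missing")
})

test_that("MLG recovery matches simulation truth without somatic mutation", {
  cfg <- sim_config(ramets_per_site = c(50, 60, 25, 25), seed = 99,
                    somatic_mu = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  part <- identify_mlgs(complete_cases(sim$table))
  genet <- sim$truth$genet[match(part$id, sim$truth$id)]
  # the two partitions must be identical up to labelling
  expect_true(all(tapply(genet, part$mlg, function(v) length(unique(v)) == 1)))
  expect_true(all(tapply(part$mlg, genet, function(v) length(unique(v)) == 1)))
})

test_that("allele frequencies count ramets or genets as requested", {
  tbl <- genotype_table(tibble::tibble(
    id = c("a", "b"), site = "P",
    L1.1 = c(100L, 100L), L1.2 = c(100L, 102L)))
  f <- allele_frequencies(tbl, scheme = "ramet")
  expect_equal(f$freq[f$allele == 100], 0.75)
  expect_equal(f$freq[f$allele == 102], 0.25)
  expect_equal(f$n_genes, c(4L, 4L))

  # monoclonal population at genet level: frequencies of one representative
  tbl2 <- tiny_table()[1:3, ]
  part2 <- identify_mlgs(tbl2)
  fg <- allele_frequencies(tbl2, part2, scheme = "genet")
  expect_equal(unique(fg$n_genes), 2L)
  expect_equal(sort(fg$freq[fg$locus == "La"]), c(0.5, 0.5))
})

test_that("simulated frequencies converge on the generating law", {
  cfg <- sim_config(ramets_per_site = c(500L), sites = "only",
                    site_centers_x = 0, cluster_of_site = "1",
                    superclone_fraction = NULL, clone_size_beta = 1e6,
                    f_is = 0, missing_rate = 0, seed = 7)
  sim <- simulate_dataset(cfg)
  freqs <- attr(sim$truth, "freqs")
  obs <- allele_frequencies(sim$table, scheme = "ramet")
  for (l in c(1L, 7L, 13L)) {
    loc <- sprintf("L%02d", l)
    sub <- obs[obs$locus == loc, ]
    p_true <- freqs$freqs[l, , "1"]
    p_obs <- sub$freq[match(freqs$sizes[[l]], sub$allele)]
    p_obs[is.na(p_obs)] <- 0
    expect_lt(max(abs(p_obs - p_true)), 0.05)
  }
})

test_that("p_gen matches closed-form genotype probabilities", {
  one_locus <- function(a, b, freqs_df, f_is) {
    tbl <- genotype_table(tibble::tibble(id = "s", site = "P",
                                         L1.1 = a, L1.2 = b))
    p_gen(tbl, freqs_df, f_is = f_is)$p_gen
  }
  f5050 <- tibble::tibble(pop = "P", locus = "L1", allele = c(100L, 102L),
                          count = c(5L, 5L), freq = 0.5, n_genes = 10L)
  expect_equal(one_locus(100L, 102L, f5050, 0), 0.5)
  expect_equal(one_locus(100L, 100L, f5050, 1), 0.5)

  # two loci, hand-verified: (0.4^2 + 0.4*0.6*0.2) * (2*0.3*0.2*0.8)
  tbl <- genotype_table(tibble::tibble(id = "s", site = "P",
                                       L1.1 = 100L, L1.2 = 100L,
                                       L2.1 = 200L, L2.2 = 202L))
  fr <- dplyr::bind_rows(
    tibble::tibble(pop = "P", locus = "L1", allele = c(100L, 102L),
                   freq = c(0.4, 0.6), count = 0L, n_genes = 10L),
    tibble::tibble(pop = "P", locus = "L2", allele = c(200L, 202L, 204L),
                   freq = c(0.3, 0.2, 0.5), count = 0L, n_genes = 10L))
  expect_equal(p_gen(tbl, fr, f_is = 0.2)$p_gen, 0.019968)

  # with F_IS = 0, p_gen = prod(f_i) * 2^h
  set.seed(31)
  rt <- random_table(20, L = 5, seed = 31)
  part <- identify_mlgs(rt)
  fr2 <- allele_frequencies(rt, part, scheme = "ramet")
  pg <- p_gen(rt, fr2, f_is = 0)$p_gen
  m <- allele_matrix(rt)
  for (i in c(1, 10, 20)) {
    prod_f <- 1; h <- 0
    for (l in 1:5) {
      a <- m[i, 2 * l - 1]; b <- m[i, 2 * l]
      loc <- gt_loci(rt)$locus[l]
      sub <- fr2[fr2$locus == loc, ]
      prod_f <- prod_f * sub$freq[match(a, sub$allele)] *
        sub$freq[match(b, sub$allele)]
      if (a != b) h <- h + 1
    }
    expect_equal(pg[i], prod_f * 2^h)
  }

  # a strongly negative F_IS can push a rare homozygote term below zero
  f_rare <- dplyr::mutate(f5050, freq = c(0.1, 0.9))
  expect_error(one_locus(100L, 100L, f_rare, -0.9), "negative")
  f_absent <- dplyr::mutate(f5050, allele = c(104L, 106L))
  expect_error(one_locus(100L, 102L, f_absent, 0), "absent")
})

test_that("p_sex equals the binomial upper tail and is monotone", {
  expect_equal(p_sex(1, 10, 0.7), 1)
  expect_equal(p_sex(2, 10, 0), 0)
  expect_equal(p_sex(2, 3, 0.5), 0.75)   # enumerating 2 Bernoulli trials

  # against the independent log-space summation oracle
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(2:200, 1)
    k <- sample(1:n, 1)
    p <- stats::runif(1)
    expect_equal(p_sex(k, n, p), p_sex_oracle(k, n, p), tolerance = 1e-12)
  }

  # non-increasing in n_obs; non-decreasing in pgen
  ps <- p_sex(1:10, 10, 0.3)
  expect_true(all(diff(ps) <= 1e-12))
  ps2 <- vapply(seq(0, 1, 0.1), function(p) p_sex(3, 10, p), numeric(1))
  expect_true(all(diff(ps2) >= -1e-12))

  expect_error(p_sex(5, 3, 0.5), "n_obs")
})

test_that("p_id follows its closed form", {
  f <- function(freqs) {
    tibble::tibble(pop = "P", locus = rep(paste0("L", seq_along(freqs)),
                                          lengths(freqs)),
                   allele = unlist(lapply(freqs, seq_along)) + 100L,
                   freq = unlist(freqs), count = 0L, n_genes = 10L)
  }
  expect_equal(p_id(f(list(c(0.5, 0.5))))$p_id, 0.375)
  expect_equal(p_id(f(list(1)))$p_id, 1.0)
  expect_equal(p_id(f(list(c(0.5, 0.5), c(0.5, 0.5))))$p_id, 0.140625)
  expect_error(p_id(f(list(c(0.5, 0.5)))[0, ]), "no loci")
})

test_that("SMM distance matches the exhaustive pairing enumeration", {
  tbl <- genotype_table(tibble::tibble(
    id = c("a", "b"), site = "P",
    L1.1 = c(100L, 100L), L1.2 = c(104L, 106L)),
    panel = locus_panel("L1", motif_length = 2L))
  expect_equal(smm_distance(tbl[1, ], tbl[2, ]), 1L)
  expect_equal(smm_distance(tbl[1, ], tbl[1, ]), 0L)

  set.seed(17)
  rt <- random_table(40, L = 13, seed = 17)
  m <- allele_matrix(rt)
  motif <- gt_loci(rt)$motif_length
  for (rep in 1:60) {
    ij <- sample(nrow(m), 2)
    got <- smm_distance(m[ij[1], ], m[ij[2], ], panel = gt_loci(rt))
    expect_equal(got, smm_oracle(m[ij[1], ], m[ij[2], ], motif))
  }

  # symmetry and identity of indiscernibles on the matrix form
  part <- identify_mlgs(rt)
  d <- smm_distance_matrix(rt, part)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[upper.tri(d)] > 0))

  bad <- genotype_table(tibble::tibble(id = c("a", "b"), site = "P",
                                       L1.1 = c(100L, 101L), L1.2 = c(100L, 101L)),
                        panel = locus_panel("L1", motif_length = 2L))
  expect_error(smm_distance(bad[1, ], bad[2, ]), "divisible")
})

test_that("collapse threshold finds the first gap and MLL collapsing is single-linkage", {
  mk <- function(vals, ids = LETTERS[1:3]) {
    d <- matrix(0L, 3, 3, dimnames = list(ids, ids))
    d[upper.tri(d)] <- vals
    d[lower.tri(d)] <- t(d)[lower.tri(d)]
    d
  }
  expect_equal(find_collapse_threshold(mk(c(2L, 3L, 5L))), 1L)
  expect_equal(find_collapse_threshold(mk(c(1L, 2L, 4L))), 0L)
  expect_equal(find_collapse_threshold(mk(c(3L, 3L, 7L))), 1L)
  expect_error(find_collapse_threshold(mk(c(1L))[1, 1, drop = FALSE]), "two MLGs")

  part <- tibble::tibble(id = c("s1", "s2", "s3"), site = "P",
                         mlg = c("A", "B", "C"), mll = NA_character_)
  class(part) <- c("clonal_partition", class(part))

  # min distance 2, threshold 1: every MLG its own MLL
  p1 <- collapse_mll(part, mk(c(2L, 3L, 5L)), 1L)
  expect_equal(length(unique(p1$mll)), 3L)

  # chain A-B=1, B-C=1, A-C=2 at threshold 1: one MLL
  chain <- mk(c(1L, 2L, 1L))    # upper.tri order: (A,B), (A,C), (B,C)
  p2 <- collapse_mll(part, chain, 1L)
  expect_equal(length(unique(p2$mll)), 1L)

  p3 <- collapse_mll(part, mk(c(2L, 3L, 5L)), 5L)
  expect_equal(length(unique(p3$mll)), 1L)
  expect_equal(attr(p3, "threshold"), 5L)
})

test_that("somatic mutation is healed by MLL collapsing at the gap threshold", {
  cfg <- sim_config(ramets_per_site = c(80, 80, 40, 40), seed = 12,
                    somatic_mu = 0.002, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  comp <- complete_cases(sim$table)
  part <- identify_mlgs(comp)
  n_genets <- length(unique(sim$truth$genet[match(comp$id, sim$truth$id)]))
  expect_gt(length(unique(part$mlg)), n_genets)   # mutation split some clones
  d <- smm_distance_matrix(comp, part)
  thr <- find_collapse_threshold(d)
  part <- collapse_mll(part, d, max(thr, 2L))
  expect_equal(length(unique(part$mll)), n_genets)
})
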