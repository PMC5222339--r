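test_that("the generator is fully deterministic given its seed", {
  cfg <- sim_config(ramets_per_site = c(40, 40, 20, 20), seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(tibble::as_tibble(s1$table), tibble::as_tibble(s2$table))
  expect_identical(tibble::as_tibble(s1$truth), tibble::as_tibble(s2$truth))
  f1 <- simulate_allele_freqs(cfg)
  f2 <- simulate_allele_freqs(cfg)
  expect_identical(f1, f2)
})

test_that("cluster divergence behaves as configured at both extremes", {
  cfg0 <- sim_config(divergence_f = 0, seed = 5)
  f0 <- simulate_allele_freqs(cfg0)
  expect_identical(f0$freqs[, , "1"], f0$freqs[, , "2"])

  cfg2 <- sim_config(divergence_f = 0.2, seed = 5)
  f2 <- simulate_allele_freqs(cfg2)
  expect_gt(max(abs(f2$freqs[, , "1"] - f2$freqs[, , "2"])), 0.01)
  # frequencies are simplex-valued
  expect_equal(unname(apply(f2$freqs, c(1, 3), sum)),
               matrix(1, cfg2$n_loci, 2), tolerance = 1e-12)
})

test_that("inbreeding in genet draws matches its definition", {
  cfg <- sim_config(seed = 9)
  fr <- simulate_allele_freqs(cfg)
  g1 <- simulate_genets(fr, "1", 50, f_is = 1, seed = 2)
  expect_true(all(g1[, seq(1, 25, 2)] == g1[, seq(2, 26, 2)]))

  # two equifrequent alleles, f_is = 0: heterozygote fraction ~ 0.5
  fr2 <- fr
  fr2$freqs[, , ] <- 0
  fr2$freqs[, 1:2, ] <- 0.5
  g0 <- simulate_genets(fr2, "1", 2000, f_is = 0, seed = 3)
  odd <- seq(1, ncol(g0), 2)
  het <- mean(g0[, odd] != g0[, odd + 1])   # pooled over the 13 loci
  expect_lt(abs(het - 0.5), 0.03)
})

test_that("clone sizes conserve totals and honour the superclone fraction", {
  cfg <- sim_config(seed = 1)
  sizes <- assign_clone_sizes(510L, cfg, seed = 4)
  expect_equal(sum(sizes), 510L)
  expect_equal(max(sizes), 240L)          # round(0.47 * 510)

  cfg_big_beta <- sim_config(clone_size_beta = 50, superclone_fraction = NULL,
                             seed = 1)
  s2 <- assign_clone_sizes(200L, cfg_big_beta, seed = 5)
  expect_equal(sum(s2), 200L)
  expect_gt(mean(s2 == 1L), 0.95)         # huge beta: nearly all singletons

  expect_error(assign_clone_sizes(1L, sim_config(superclone_fraction = 0.2,
                                                 seed = 1), seed = 6),
               "infeasible")
})

test_that("ramet placement respects sites, dispersal and migration", {
  cfg0 <- sim_config(clonal_migration_rate = 0, ramet_dispersal_sigma = 1e-9,
                     seed = 3)
  asg <- tibble::tibble(genet = rep(1:5, each = 4),
                        site = rep(cfg0$sites[1:5 %% 4 + 1], each = 4))
  placed <- place_ramets(asg, cfg0, seed = 8)
  expect_equal(placed$site, asg$site)     # no migration: sites unchanged
  # near-zero dispersal: clonemates coincide
  spread <- tapply(placed$x, placed$genet, function(v) diff(range(v)))
  expect_true(all(spread < 1e-6))
  # all ramets inside their site disc
  centers <- stats::setNames(cfg0$site_centers_x, cfg0$sites)
  r <- sqrt((placed$x - centers[placed$site])^2 + placed$y^2)
  expect_true(all(r <= cfg0$site_radius + 1e-9))

  # migration count has the configured expectation
  cfg2 <- sim_config(clonal_migration_rate = 0.02, seed = 3)
  asg2 <- tibble::tibble(genet = 1:500, site = rep(cfg2$sites, length.out = 500))
  placed2 <- place_ramets(asg2, cfg2, seed = 10)
  n_mig <- sum(placed2$site != asg2$site)
  expect_gte(n_mig, 2); expect_lte(n_mig, 25)   # ~Binomial(500, 0.02)
})

test_that("missing-data masking matches its closed-form expectation", {
  cfg <- sim_config(ramets_per_site = c(120, 120, 60, 60), missing_rate = 0.1,
                    seed = 31)
  sim <- simulate_dataset(cfg)
  n <- nrow(sim$table)
  p_keep <- (1 - 0.1)^13
  n_cc <- nrow(complete_cases(sim$table))
  expect_lt(abs(n_cc - n * p_keep), 3 * sqrt(n * p_keep * (1 - p_keep)))
})

test_that("truth bookkeeping is conserved", {
  cfg <- sim_config(ramets_per_site = c(50, 50, 25, 25), seed = 21)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth), nrow(sim$table))
  expect_identical(sim$truth$id, sim$table$id)
  expect_equal(as.vector(table(sim$truth$site)), as.vector(table(sim$table$site)))
  # every genet has one cluster
  expect_true(all(tapply(sim$truth$cluster, sim$truth$genet,
                         function(v) length(unique(v))) == 1))
  # no migration: every MLG confined to one site
  cfg0 <- sim_config(ramets_per_site = c(50, 50, 25, 25), seed = 21,
                     clonal_migration_rate = 0, superclone_fraction = NULL)
  sim0 <- simulate_dataset(cfg0)
  expect_true(all(tapply(sim0$truth$site, sim0$truth$genet,
                         function(v) length(unique(v))) == 1))
})

test_that("temperature series honour offset, amplitude and seeding", {
  a <- simulate_temperature_series(100, 25, 1.5, daily_offset = 0.4,
                                   noise_sd = 0, seed = 1)
  b <- simulate_temperature_series(100, 25, 1.5, daily_offset = 0,
                                   noise_sd = 0, seed = 1)
  expect_equal(mean(a$temp - b$temp), 0.4)
  flat <- simulate_temperature_series(50, 25, 0, noise_sd = 0, seed = 1)
  expect_true(all(flat$temp == 25))
  n1 <- simulate_temperature_series(50, 25, 1, noise_sd = 0.3, seed = 7)
  n2 <- simulate_temperature_series(50, 25, 1, noise_sd = 0.3, seed = 7)
  expect_identical(n1, n2)
})
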