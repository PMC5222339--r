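#' Configuration for the partially clonal population simulator
#'
#' Defaults emulate the statistical structure of a four-site coral
#' microsatellite survey: two divergent genetic clusters plus a mixed
#' site, a dominant superclone holding ~47% of all colonies, a discrete-
#' Pareto spectrum of remaining clone sizes, clonemates aggregated inside
#' 12 m radius sampling discs, rare long-distance clonal dispersal,
#' optional stepwise somatic mutation, and missing data.
#'
#' @param n_loci number of microsatellite loci (default 13).
#' @param n_alleles alleles per locus on the motif ladder (default 8).
#' @param motif_length repeat-unit length(s) in bp (default 2, recycled).
#' @param sites site labels (default `site1`..`site4`).
#' @param ramets_per_site sampled colonies per site (default
#'   `c(183, 297, 50, 57)`).
#' @param site_centers_x along-coast site positions in metres (default
#'   `c(0, 2000, 25000, 40000)`, i.e. 2-40 km apart).
#' @param cluster_of_site `"1"`, `"2"` or `"mixed"` per site (default
#'   `c("1","1","mixed","2")`; the mixed site draws genets from both
#'   clusters 50:50).
#' @param divergence_f Balding-Nichols divergence between the two clusters
#'   (default 0.2).
#' @param f_is inbreeding coefficient used when drawing genets (default
#'   0.15).
#' @param clone_size_beta exponent of the discrete Pareto clone-size law
#'   (default 1.0).
#' @param superclone_fraction share of all ramets given to the largest
#'   clone (default 0.47; `NULL` disables the superclone).
#' @param ramet_dispersal_sigma Gaussian scatter of ramets around their
#'   genet origin, metres (default 2).
#' @param site_radius sampling-disc radius, metres (default 12).
#' @param clonal_migration_rate probability that a ramet is carried to a
#'   different site (default 0.01).
#' @param somatic_mu per-ramet, per-locus probability of a one-step
#'   stepwise somatic mutation (default 0).
#' @param missing_rate per-ramet, per-locus probability of a missing call
#'   (default 0.01).
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 13L, n_alleles = 8L, motif_length = 2L,
                       sites = paste0("site", 1:4),
                       ramets_per_site = c(183L, 297L, 50L, 57L),
                       site_centers_x = c(0, 2000, 25000, 40000),
                       cluster_of_site = c("1", "1", "mixed", "2"),
                       divergence_f = 0.2, f_is = 0.15,
                       clone_size_beta = 1.0, superclone_fraction = 0.47,
                       ramet_dispersal_sigma = 2, site_radius = 12,
                       clonal_migration_rate = 0.01, somatic_mu = 0,
                       missing_rate = 0.01, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_loci >= 1, n_alleles >= 2,
            length(sites) == length(ramets_per_site),
            length(sites) == length(cluster_of_site),
            length(sites) == length(site_centers_x),
            divergence_f >= 0, divergence_f < 1,
            f_is >= 0, f_is <= 1, clone_size_beta > 0,
            clonal_migration_rate >= 0, clonal_migration_rate <= 1,
            somatic_mu >= 0, somatic_mu <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(superclone_fraction)) {
    stopifnot(superclone_fraction > 0, superclone_fraction < 1)
  }
  cfg <- list(n_loci = as.integer(n_loci), n_alleles = as.integer(n_alleles),
              motif_length = rep_len(as.integer(motif_length), n_loci),
              sites = sites, ramets_per_site = as.integer(ramets_per_site),
              site_centers_x = site_centers_x,
              cluster_of_site = cluster_of_site,
              divergence_f = divergence_f, f_is = f_is,
              clone_size_beta = clone_size_beta,
              superclone_fraction = superclone_fraction,
              ramet_dispersal_sigma = ramet_dispersal_sigma,
              site_radius = site_radius,
              clonal_migration_rate = clonal_migration_rate,
              somatic_mu = somatic_mu, missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate per-cluster allele frequencies (Balding-Nichols)
#'
#' Ancestral frequencies are Dirichlet-uniform per locus; each cluster's
#' frequencies are drawn from a Dirichlet with parameters
#' `p_ancestral (1 - F) / F`, the Balding-Nichols model, so the expected
#' Weir-Cockerham divergence between clusters is governed by `F`.
#' Allele sizes sit on a motif-spaced ladder per locus.
#'
#' @param config a [sim_config()].
#' @param seed optional seed (defaults to the config's).
#' @return list with `sizes` (list of allele-size vectors per locus) and
#'   `freqs`: a 3-d array `[locus, allele, cluster]`.
#' @export
simulate_allele_freqs <- function(config, seed = config$seed) {
  set.seed(seed)
  L <- config$n_loci; K <- config$n_alleles
  sizes <- lapply(seq_len(L), function(l) {
    100L + 20L * l + config$motif_length[l] * (0:(K - 1L))
  })
  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (sum(g) == 0) g[which.max(alpha)] <- 1
    g / sum(g)
  }
  freqs <- array(0, dim = c(L, K, 2L),
                 dimnames = list(NULL, NULL, c("1", "2")))
  for (l in seq_len(L)) {
    anc <- rdirichlet1(rep(1, K))
    if (config$divergence_f == 0) {
      freqs[l, , 1] <- anc; freqs[l, , 2] <- anc
    } else {
      conc <- anc * (1 - config$divergence_f) / config$divergence_f
      freqs[l, , 1] <- rdirichlet1(conc)
      freqs[l, , 2] <- rdirichlet1(conc)
    }
  }
  list(sizes = sizes, freqs = freqs)
}

#' Draw genet genotypes from cluster allele frequencies
#'
#' Per locus, with probability `f_is` one allele is drawn and duplicated
#' (identity by descent), otherwise two alleles are drawn independently —
#' giving expected homozygosity `f_is + (1 - f_is) sum p^2`.
#'
#' @param freqs output of [simulate_allele_freqs()].
#' @param cluster `"1"` or `"2"` per genet (recycled).
#' @param n number of genets.
#' @param f_is inbreeding coefficient in `[0, 1]`.
#' @param seed optional seed (set it when calling standalone).
#' @return integer matrix `n x 2L` laid out like [allele_matrix()] (pairs
#'   sorted within locus).
#' @export
simulate_genets <- function(freqs, cluster, n, f_is, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cluster <- rep_len(as.character(cluster), n)
  L <- dim(freqs$freqs)[1]
  out <- matrix(0L, n, 2L * L)
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      p <- freqs$freqs[l, , cluster[i]]
      sz <- freqs$sizes[[l]]
      if (stats::runif(1) < f_is) {
        a <- sample(sz, 1L, prob = p); b <- a
      } else {
        ab <- sample(sz, 2L, replace = TRUE, prob = p)
        a <- ab[1]; b <- ab[2]
      }
      out[i, 2L * l - 1L] <- min(a, b)
      out[i, 2L * l] <- max(a, b)
    }
  }
  out
}

#' Draw a clone-size list with an optional superclone
#'
#' If a superclone fraction is configured the largest clone receives
#' `round(fraction * n)` ramets; the remainder is filled with sizes from a
#' discrete Pareto law with survival `P(X >= x) = x^(-beta)` (drawn as
#' `floor(U^(-1/beta))`), the last clone clipped so that the sizes sum to
#' `n` exactly.
#'
#' @param n_ramets_target total number of ramets (>= 1).
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return integer vector of clone sizes summing to `n_ramets_target`,
#'   sorted decreasingly.
#' @export
assign_clone_sizes <- function(n_ramets_target, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_ramets_target)
  stopifnot(n >= 1)
  sizes <- integer(0)
  if (!is.null(config$superclone_fraction)) {
    sc <- as.integer(round(config$superclone_fraction * n))
    if (sc < 1L || sc > n) stop("infeasible superclone fraction for n = ", n)
    sizes <- sc
  }
  remaining <- n - sum(sizes)
  beta <- config$clone_size_beta
  while (remaining > 0L) {
    draw <- min(as.integer(floor(stats::runif(1)^(-1 / beta))), remaining)
    sizes <- c(sizes, draw)
    remaining <- remaining - draw
  }
  sort(sizes, decreasing = TRUE)
}

#' Place ramets around their genets' origins
#'
#' Each genet gets a uniform origin inside its home site's sampling disc;
#' its ramets scatter isotropically (Gaussian, sd `ramet_dispersal_sigma`)
#' around the origin and are radially reflected back into the disc. With
#' probability `clonal_migration_rate` a ramet is instead carried to a
#' random other site and given a fresh uniform position there (long-
#' distance clonal dispersal).
#'
#' @param assignments tibble with one row per ramet: columns `genet`
#'   (integer id) and `site` (home-site label).
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return the tibble with columns `site` (possibly reassigned), `x`, `y`.
#' @export
place_ramets <- function(assignments, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- config$site_radius
  centers <- stats::setNames(config$site_centers_x, config$sites)
  unif_disc <- function(n) {
    r <- R * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th))
  }
  # one origin per (genet, home site)
  key <- paste(assignments$genet, assignments$site)
  origins <- unif_disc(length(unique(key)))
  rownames(origins) <- unique(key)
  xy <- origins[key, , drop = FALSE] +
    matrix(stats::rnorm(2L * nrow(assignments), 0, config$ramet_dispersal_sigma),
           ncol = 2L)
  # radial reflection into the disc
  r <- sqrt(rowSums(xy^2))
  out_of <- r > R
  if (any(out_of)) {
    r_ref <- pmax(2 * R - r[out_of], 0)
    r_ref <- pmin(r_ref, R)
    scale <- ifelse(r[out_of] > 0, r_ref / r[out_of], 0)
    xy[out_of, ] <- xy[out_of, ] * scale
  }
  site <- assignments$site
  mig <- stats::runif(nrow(assignments)) < config$clonal_migration_rate
  if (any(mig) && length(config$sites) > 1L) {
    for (i in which(mig)) {
      site[i] <- sample(setdiff(config$sites, site[i]), 1L)
      xy[i, ] <- unif_disc(1L)
    }
  }
  tibble::tibble(genet = assignments$genet, site = site,
                 x = xy[, 1] + centers[site], y = xy[, 2])
}

#' Simulate a complete multi-site, partially clonal dataset
#'
#' Composes the generator: cluster allele frequencies, a global clone-size
#' list (superclone + discrete Pareto), assignment of genets to home
#' sites, genotype draws with inbreeding, spatial placement with clonal
#' migration, one-step stepwise somatic mutation at rate `somatic_mu`, and
#' missing-data masking. With `somatic_mu = 0` and `missing_rate = 0` the
#' MLG partition recovered by [identify_mlgs()] equals the genet partition
#' (up to vanishingly rare genotype collisions).
#'
#' @param config a [sim_config()].
#' @return list with `table` (a `genotype_tbl`), and `truth` of class
#'   `sim_truth`: tibble `id`, `site`, `genet`, `cluster` plus attributes
#'   `freqs` and `config`.
#' @export
simulate_dataset <- function(config) {
  set.seed(config$seed)
  freqs <- simulate_allele_freqs(config, seed = config$seed)
  n_total <- sum(config$ramets_per_site)

  # the superclone is the one genet that spans sites: its ramets are spread
  # over the cluster-1 and mixed sites proportionally to site size; every
  # other genet is drawn per site, so clones stay local unless migration
  # moves a ramet
  quota <- stats::setNames(config$ramets_per_site, config$sites)
  home_site <- character(0)
  ramet_site <- character(0)
  ramet_genet <- integer(0)
  have_sc <- !is.null(config$superclone_fraction)
  if (have_sc) {
    sc <- as.integer(round(config$superclone_fraction * n_total))
    if (sc < 1L || sc > n_total) stop("infeasible superclone fraction")
    host <- config$sites[config$cluster_of_site %in% c("1", "mixed")]
    if (length(host) == 0L) host <- config$sites
    alloc <- round(sc * quota[host] / sum(quota[host]))
    alloc <- pmin(alloc, quota[host])
    diff <- sc - sum(alloc)
    while (diff != 0L) {
      j <- which.max(quota[host] - alloc)
      alloc[j] <- alloc[j] + sign(diff)
      diff <- diff - sign(diff)
    }
    for (s in host) if (alloc[s] > 0) {
      ramet_site <- c(ramet_site, rep(s, alloc[s]))
      ramet_genet <- c(ramet_genet, rep(1L, alloc[s]))
    }
    quota[host] <- quota[host] - alloc
    home_site <- host[which.max(alloc)]
  }
  cfg_local <- config
  cfg_local$superclone_fraction <- NULL
  next_genet <- length(home_site) + 1L
  for (s in config$sites) {
    if (quota[s] == 0L) next
    local_sizes <- assign_clone_sizes(quota[s], cfg_local)
    gids <- seq.int(next_genet, length.out = length(local_sizes))
    next_genet <- next_genet + length(local_sizes)
    ramet_site <- c(ramet_site, rep(s, quota[s]))
    ramet_genet <- c(ramet_genet, rep(gids, local_sizes))
    home_site <- c(home_site, rep(s, length(local_sizes)))
  }

  # cluster per genet from its home site (mixed sites: 50:50)
  site_cluster <- stats::setNames(config$cluster_of_site, config$sites)
  genet_cluster <- vapply(seq_along(home_site), function(g) {
    cl <- site_cluster[home_site[g]]
    if (cl == "mixed") sample(c("1", "2"), 1L) else unname(cl)
  }, character(1))
  genotypes <- simulate_genets(freqs, genet_cluster, length(home_site),
                               config$f_is)

  placed <- place_ramets(tibble::tibble(genet = ramet_genet, site = ramet_site),
                         config)
  m <- genotypes[placed$genet, , drop = FALSE]

  # one-step SMM somatic mutation: per ramet, per locus, mutate one of the
  # two alleles by +/- one motif unit
  if (config$somatic_mu > 0) {
    L <- config$n_loci
    hit <- matrix(stats::runif(nrow(m) * L) < config$somatic_mu, ncol = L)
    for (l in which(colSums(hit) > 0)) {
      for (i in which(hit[, l])) {
        which_allele <- sample(c(2L * l - 1L, 2L * l), 1L)
        step <- sample(c(-1L, 1L), 1L) * config$motif_length[l]
        m[i, which_allele] <- m[i, which_allele] + step
        pair <- sort(m[i, c(2L * l - 1L, 2L * l)])
        m[i, c(2L * l - 1L, 2L * l)] <- pair
      }
    }
  }
  if (config$missing_rate > 0) {
    L <- config$n_loci
    miss <- matrix(stats::runif(nrow(m) * L) < config$missing_rate, ncol = L)
    for (l in seq_len(L)) {
      m[miss[, l], c(2L * l - 1L, 2L * l)] <- NA_integer_
    }
  }

  ord <- order(match(placed$site, config$sites))
  df <- tibble::tibble(id = character(nrow(m)), site = placed$site,
                       x = placed$x, y = placed$y)
  df <- df[ord, ]
  df$id <- sprintf("%s_%04d", df$site,
                   stats::ave(seq_len(nrow(df)), df$site, FUN = seq_along))
  geno <- tibble::as_tibble(as.data.frame(m[ord, , drop = FALSE]))
  loci_names <- sprintf("L%02d", seq_len(config$n_loci))
  names(geno) <- locus_colnames(loci_names)
  panel <- locus_panel(loci_names, motif_length = config$motif_length)
  table <- genotype_table(dplyr::bind_cols(df, geno), panel = panel,
                          provenance = "simulate_dataset")
  truth <- tibble::tibble(id = df$id, site = df$site,
                          genet = ramet_genet[ord],
                          cluster = genet_cluster[ramet_genet[ord]])
  attr(truth, "freqs") <- freqs
  attr(truth, "config") <- config
  class(truth) <- c("sim_truth", class(truth))
  list(table = table, truth = truth)
}

#' Simulate a daily sea-temperature series
#'
#' A sinusoidal annual cycle plus a constant offset and Gaussian noise:
#' `mean + daily_offset + amplitude * sin(2 pi (day + phase) / 365) +
#' noise`. Two series generated with the same seed and different
#' `daily_offset` differ by the offset exactly (noiseless) or in
#' expectation.
#'
#' @param n_days series length (>= 1).
#' @param mean mean temperature, degrees C.
#' @param amplitude annual half-range, degrees C.
#' @param daily_offset constant shift, degrees C (default 0).
#' @param noise_sd Gaussian daily noise sd (default 0).
#' @param seed RNG seed.
#' @param phase day-of-year offset of the sinusoid (default 0).
#' @return tibble `day`, `temp`.
#' @export
simulate_temperature_series <- function(n_days, mean, amplitude,
                                        daily_offset = 0, noise_sd = 0, seed,
                                        phase = 0) {
  stopifnot(n_days >= 1)
  set.seed(seed)
  day <- seq_len(n_days)
  temp <- mean + daily_offset + amplitude * sin(2 * pi * (day + phase) / 365) +
    stats::rnorm(n_days, 0, noise_sd)
  tibble::tibble(day = day, temp = temp)
}
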