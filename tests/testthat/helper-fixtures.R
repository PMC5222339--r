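# fixture builders shared across the suite; everything is generated in code

# tiny two-locus table: 5 samples in one site, two clones of sizes 3 and 2
tiny_table <- function() {
  genotype_table(tibble::tibble(
    id = paste0("C0", 1:5),
    site = "A",
    La.1 = c(100L, 100L, 100L, 100L, 100L),
    La.2 = c(102L, 102L, 102L, 104L, 104L),
    Lb.1 = c(150L, 150L, 150L, 150L, 150L),
    Lb.2 = c(150L, 150L, 150L, 152L, 152L)
  ), panel = locus_panel(c("La", "Lb"), motif_length = 2L))
}

# random complete table: n samples, L loci, alleles on a motif-2 ladder
random_table <- function(n, L = 13L, n_alleles = 6L, sites = "A", seed = 1L) {
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(L))
  df <- tibble::tibble(id = sprintf("S%04d", seq_len(n)),
                       site = rep_len(sites, n))
  for (l in seq_len(L)) {
    ladder <- 100L + 2L * (0:(n_alleles - 1L))
    a <- sample(ladder, n, replace = TRUE)
    b <- sample(ladder, n, replace = TRUE)
    df[[paste0(loci[l], ".1")]] <- pmin(a, b)
    df[[paste0(loci[l], ".2")]] <- pmax(a, b)
  }
  genotype_table(df, panel = locus_panel(loci, motif_length = 2L))
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             path)
  path
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate k positions of a DNA string
mutate_dna <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# independent oracle: SMM distance by exhaustive enumeration over all 2^L
# per-locus pairing choices (never calls the package's per-locus min)
smm_oracle <- function(g1, g2, motif) {
  L <- length(motif)
  dA <- numeric(L); dB <- numeric(L)
  for (l in seq_len(L)) {
    a <- g1[c(2 * l - 1, 2 * l)]; b <- g2[c(2 * l - 1, 2 * l)]
    dA[l] <- (abs(a[1] - b[1]) + abs(a[2] - b[2])) / motif[l]
    dB[l] <- (abs(a[1] - b[2]) + abs(a[2] - b[1])) / motif[l]
  }
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), L)))
  min(combos %*% dA + (1 - combos) %*% dB)
}

# independent oracle: binomial upper tail by direct log-space summation
p_sex_oracle <- function(n_obs, n_samples, pgen) {
  if (n_obs == 1) return(1)
  if (pgen == 0) return(0)
  if (pgen == 1) return(1)
  j <- (n_obs - 1):(n_samples - 1)
  sum(exp(lchoose(n_samples - 1, j) + j * log(pgen) +
            (n_samples - 1 - j) * log1p(-pgen)))
}
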