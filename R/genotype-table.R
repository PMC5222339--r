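#' Define a microsatellite locus panel
#'
#' A locus panel records, for each locus, the repeat-motif length in base
#' pairs (used to convert allele-size differences into stepwise-mutation
#' steps) and whether the locus is excluded from population-structure
#' analyses (e.g. loci carrying null alleles are typically kept for clone
#' discrimination but dropped from F-statistics).
#'
#' @param locus character vector of unique locus names.
#' @param motif_length integer vector (recycled) of repeat-unit lengths in
#'   bp; must be >= 1.
#' @param excluded logical vector (recycled); `TRUE` marks loci to drop from
#'   structure analyses.
#' @return A tibble of class `locus_panel` with columns `locus`,
#'   `motif_length`, `excluded`.
#' @export
#' @examples
#' locus_panel(c("Pd2-001", "Poc40"), motif_length = c(2, 3),
#'             excluded = c(TRUE, TRUE))
locus_panel <- function(locus, motif_length = 1L, excluded = FALSE) {
  locus <- as.character(locus)
  if (anyDuplicated(locus)) stop("locus names must be unique within a panel")
  motif_length <- vctrs_recycle_int(motif_length, length(locus), "motif_length")
  if (any(motif_length < 1L)) stop("motif_length must be >= 1")
  excluded <- rep_len(as.logical(excluded), length(locus))
  out <- tibble::tibble(locus = locus, motif_length = motif_length,
                        excluded = excluded)
  class(out) <- c("locus_panel", class(out))
  out
}

vctrs_recycle_int <- function(x, n, what) {
  x <- as.integer(x)
  if (anyNA(x)) stop(what, " must not contain NA")
  rep_len(x, n)
}

#' Construct a genotype table
#'
#' The central container: one row per sampled colony (ramet), with an id, a
#' site (population) label, optional planar coordinates in metres, an
#' optional colour phenotype, and two allele-size columns per locus named
#' `<locus>.1` / `<locus>.2`. Allele pairs are unordered; internally each
#' pair is normalised so that `<locus>.1 <= <locus>.2`. A locus call is
#' either complete (two positive integer sizes) or missing (both `NA`);
#' the sentinels `0` and blank are normalised to missing, and half-missing
#' calls are promoted to fully missing with a warning.
#'
#' @param df a data frame with columns `id`, `site`, optional `x`, `y`,
#'   `color`, and two columns per locus.
#' @param panel optional [locus_panel()]; if absent, loci are inferred from
#'   the paired columns and given motif length 1 (distances then count base
#'   pairs, with a warning at SMM-distance time).
#' @param provenance free-text metadata carried along with the table.
#' @return A tibble of class `genotype_tbl` with attributes `loci`
#'   (the panel) and `provenance`.
#' @export
genotype_table <- function(df, panel = NULL, provenance = "") {
  df <- tibble::as_tibble(df)
  if (!all(c("id", "site") %in% names(df))) {
    stop("genotype table needs 'id' and 'site' columns")
  }
  df$id <- as.character(df$id)
  df$site <- as.character(df$site)
  if (anyDuplicated(df$id)) {
    stop("duplicate sample ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  if (any(!nzchar(df$site) | is.na(df$site))) stop("site labels must be non-empty")

  meta_cols <- intersect(c("id", "site", "x", "y", "color"), names(df))
  locus_cols <- setdiff(names(df), meta_cols)
  if (length(locus_cols) %% 2L != 0L) {
    stop("odd number of allele columns: every locus needs a '.1' and '.2' column")
  }
  loci <- infer_loci(locus_cols)
  if (is.null(panel)) {
    panel <- locus_panel(loci)
  } else {
    if (!all(loci %in% panel$locus)) {
      stop("loci in data absent from panel: ",
           paste(setdiff(loci, panel$locus), collapse = ", "))
    }
    panel <- panel[match(loci, panel$locus), ]
  }

  # normalise alleles: integer sizes, 0 -> NA, sort each pair, pair-wise missing
  n_half <- 0L
  for (loc in loci) {
    a <- normalise_allele(df[[paste0(loc, ".1")]])
    b <- normalise_allele(df[[paste0(loc, ".2")]])
    half <- xor(is.na(a), is.na(b))
    n_half <- n_half + sum(half)
    a[half] <- NA_integer_
    b[half] <- NA_integer_
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    df[[paste0(loc, ".1")]] <- lo
    df[[paste0(loc, ".2")]] <- hi
  }
  if (n_half > 0L) {
    warning(n_half, " half-missing locus call(s) normalised to missing")
  }
  df <- df[, c(meta_cols, as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2"))))]
  attr(df, "loci") <- panel
  attr(df, "provenance") <- provenance
  class(df) <- c("genotype_tbl", class(df))
  df
}

infer_loci <- function(locus_cols) {
  base <- sub("\\.[12]$", "", locus_cols)
  loci <- unique(base)
  ok <- vapply(loci, function(l) {
    all(paste0(l, c(".1", ".2")) %in% locus_cols)
  }, logical(1))
  if (!all(ok)) {
    stop("allele columns must come in '<locus>.1'/'<locus>.2' pairs; offending: ",
         paste(loci[!ok], collapse = ", "))
  }
  loci
}

normalise_allele <- function(x) {
  if (is.character(x)) x[!nzchar(trimws(x))] <- NA
  x <- suppressWarnings(as.integer(as.character(x)))
  x[!is.na(x) & x <= 0L] <- NA_integer_
  x
}

#' @export
print.genotype_tbl <- function(x, ...) {
  panel <- gt_loci(x)
  cat(sprintf("# genotype table: %d samples, %d loci, %d site(s)\n",
              nrow(x), nrow(panel), dplyr::n_distinct(x$site)))
  NextMethod()
}

#' Locus panel of a genotype table
#' @param table a `genotype_tbl`.
#' @return The [locus_panel()] attached to the table.
#' @export
gt_loci <- function(table) {
  panel <- attr(table, "loci")
  if (is.null(panel)) stop("not a genotype table: no locus panel attribute")
  panel
}

locus_colnames <- function(loci) {
  as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
}

#' Allele matrix of a genotype table
#'
#' @param table a `genotype_tbl`.
#' @param loci optional character vector restricting the loci.
#' @return integer matrix with `2 * length(loci)` columns (pairs of columns
#'   per locus, sorted within pair) and one row per sample.
#' @export
allele_matrix <- function(table, loci = NULL) {
  panel <- gt_loci(table)
  if (is.null(loci)) loci <- panel$locus
  m <- as.matrix(table[, locus_colnames(loci)])
  storage.mode(m) <- "integer"
  rownames(m) <- table$id
  m
}

#' Drop loci flagged as excluded in the panel
#'
#' @param table a `genotype_tbl`.
#' @return The table restricted to non-excluded loci.
#' @export
drop_excluded_loci <- function(table) {
  panel <- gt_loci(table)
  keep <- panel$locus[!panel$excluded]
  subset_loci(table, keep)
}

subset_loci <- function(table, loci) {
  panel <- gt_loci(table)
  meta <- intersect(c("id", "site", "x", "y", "color"), names(table))
  out <- table[, c(meta, locus_colnames(loci))]
  attr(out, "loci") <- panel[match(loci, panel$locus), ]
  attr(out, "provenance") <- attr(table, "provenance")
  class(out) <- class(table)
  out
}

#' Keep only samples with a complete multilocus genotype
#'
#' Mirrors the standard pre-filter before clone discrimination: a sample is
#' kept iff it has no missing locus call.
#'
#' @param table a `genotype_tbl`.
#' @return The filtered table, in the original order. An all-missing input
#'   yields an empty table (with a message).
#' @export
complete_cases <- function(table) {
  m <- allele_matrix(table)
  keep <- rowSums(is.na(m)) == 0L
  out <- table[keep, ]
  if (nrow(out) == 0L) message("complete_cases: no sample has a complete genotype")
  out
}

#' Count of samples carrying at least one missing call
#' @param table a `genotype_tbl`.
#' @return integer count.
#' @export
n_incomplete <- function(table) {
  m <- allele_matrix(table)
  sum(rowSums(is.na(m)) > 0L)
}

#' Read a genotype table from CSV
#'
#' Expects a header with `id`, `site`, optional `x`, `y`, `color`, then two
#' columns per locus named `<locus>.1` / `<locus>.2`. Missing calls are
#' encoded as 0 or blank. Cells that fail to parse as integers become
#' missing, with a warning giving the count.
#'
#' @param path CSV file.
#' @param panel optional [locus_panel()].
#' @return A `genotype_tbl`.
#' @export
read_genotype_table <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  meta <- intersect(c("id", "site", "x", "y", "color"), names(raw))
  locus_cols <- setdiff(names(raw), meta)
  n_bad <- sum(vapply(raw[locus_cols], function(col) {
    sum(!is.na(col) & nzchar(trimws(col)) &
          is.na(suppressWarnings(as.integer(col))))
  }, numeric(1)))
  if (n_bad > 0) warning(n_bad, " unparseable allele cell(s) treated as missing")
  for (v in intersect(c("x", "y"), names(raw))) raw[[v]] <- as.numeric(raw[[v]])
  genotype_table(raw, panel = panel,
                 provenance = paste0("read from ", basename(path)))
}

#' Write a genotype table to CSV
#'
#' Inverse of [read_genotype_table()]: missing calls are written as 0.
#'
#' @param table a `genotype_tbl`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  out <- tibble::as_tibble(table)
  panel <- gt_loci(table)
  for (col in locus_colnames(panel$locus)) {
    v <- out[[col]]
    v[is.na(v)] <- 0L
    out[[col]] <- v
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a STRUCTURE-style two-row genotype file (read-only support)
#'
#' Two consecutive rows per individual: `id site a(locus1) ... a(locusL)`,
#' whitespace-separated, missing encoded as `-9` or `0`. The first row of
#' the file must be a header naming the loci.
#'
#' @param path file path.
#' @param panel optional [locus_panel()].
#' @return A `genotype_tbl`.
#' @export
read_structure_genotypes <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(body) %% 2L != 0L) stop("two-row format needs an even number of data rows")
  rows <- lapply(seq(1, length(body), by = 2), function(i) {
    r1 <- body[[i]]; r2 <- body[[i + 1]]
    if (r1[1] != r2[1]) stop("row pair with mismatched ids: ", r1[1], " / ", r2[1])
    a1 <- as.integer(r1[-(1:2)]); a2 <- as.integer(r2[-(1:2)])
    a1[a1 %in% c(-9L, 0L)] <- NA_integer_
    a2[a2 %in% c(-9L, 0L)] <- NA_integer_
    stats::setNames(
      c(list(r1[1], r1[2]), as.list(as.vector(rbind(a1, a2)))),
      c("id", "site", locus_colnames(loci)))
  })
  genotype_table(dplyr::bind_rows(rows), panel = panel,
                 provenance = paste0("read from ", basename(path), " (two-row)"))
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; duplicate ids and empty files are errors. Used
#' for the mitochondrial ORF amplicons that gate colonies to a lineage.
#'
#' @param path FASTA file.
#' @return named character vector of nucleotide sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) stop("empty FASTA: ", path)
    seqs <- toupper(as.character(set))
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L) stop("empty FASTA: ", path)
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      toupper(paste0(lines[(hdr[i] + 1L):ends[i]], collapse = ""))
    }, character(1))
    names(seqs) <- ids
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}
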