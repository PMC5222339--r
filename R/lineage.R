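#' Assign query sequences to reference lineages by Hamming distance
#'
#' Each query (an mtDNA ORF amplicon) is compared with every reference over
#' their shared leading window (both sequences trimmed to the shorter
#' length) and assigned to the lineage of the closest reference. The marker
#' is a fixed-length amplicon, so ungapped comparison is appropriate; indel
#' handling is deliberately out of scope. Ties between lineages are flagged
#' ambiguous rather than broken.
#'
#' @param queries named character vector of query sequences (see
#'   [read_fasta()]).
#' @param references named character vector; lineage labels are taken from
#'   the part of each name after the last `|` (e.g. `"KT879932|beta"`), or
#'   from `ref_lineages` if given.
#' @param ref_lineages optional character vector of lineage labels parallel
#'   to `references`, overriding the `|` convention.
#' @param min_length minimum sequence length accepted (default 200 bp).
#' @return A tibble with columns `id`, `best_lineage`, `hamming_distance`,
#'   `ambiguous`.
#' @export
assign_lineage <- function(queries, references, ref_lineages = NULL,
                           min_length = 200L) {
  if (length(references) == 0L) stop("no reference sequences supplied")
  if (is.null(ref_lineages)) {
    ref_lineages <- ifelse(grepl("\\|", names(references)),
                           sub("^.*\\|", "", names(references)),
                           names(references))
  }
  if (length(ref_lineages) != length(references)) {
    stop("ref_lineages must be parallel to references")
  }
  short_q <- nchar(queries) < min_length
  if (any(short_q)) {
    stop("query sequence(s) shorter than ", min_length, " bp: ",
         paste(names(queries)[short_q], collapse = ", "))
  }
  short_r <- nchar(references) < min_length
  if (any(short_r)) {
    stop("reference sequence(s) shorter than ", min_length, " bp: ",
         paste(names(references)[short_r], collapse = ", "))
  }
  purrr::map_dfr(seq_along(queries), function(i) {
    q <- queries[[i]]
    d <- vapply(references, function(r) hamming_leading(q, r), numeric(1))
    # distance to a lineage = distance to its closest reference
    dl <- tapply(d, ref_lineages, min)
    dmin <- min(dl)
    hits <- names(dl)[dl == dmin]
    tibble::tibble(id = names(queries)[i],
                   best_lineage = hits[1],
                   hamming_distance = as.integer(dmin),
                   ambiguous = length(hits) > 1L)
  })
}

hamming_leading <- function(a, b) {
  w <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1L, w), "")[[1]]
  bv <- strsplit(substr(b, 1L, w), "")[[1]]
  sum(av != bv)
}

#' Filter a genotype table to one lineage
#'
#' Removes samples assigned to a non-target lineage; ambiguous assignments
#' are removed too (conservative exclusion) and counted separately. Samples
#' without an assignment pass through unchanged with a warning. When a
#' clonal partition is supplied, assignments made for one representative of
#' an MLG are extended to all its clonemates (the usual design: one colony
#' sequenced per MLG).
#'
#' @param table a `genotype_tbl`.
#' @param assignments output of [assign_lineage()].
#' @param target lineage label to keep.
#' @param partition optional [identify_mlgs()] partition enabling per-MLG
#'   gating.
#' @return The filtered `genotype_tbl`; removal counts per site are
#'   reported via `message()` and attached as attribute `gate_log`.
#' @export
filter_to_lineage <- function(table, assignments, target, partition = NULL) {
  stopifnot(is.character(target), length(target) == 1L)
  call_of <- stats::setNames(assignments$best_lineage, assignments$id)
  ambig_of <- stats::setNames(assignments$ambiguous, assignments$id)
  if (!is.null(partition)) {
    # extend each sequenced sample's call to its whole MLG
    mlg_of <- stats::setNames(partition$mlg, partition$id)
    seq_ids <- intersect(names(call_of), names(mlg_of))
    mlg_call <- tapply(call_of[seq_ids], mlg_of[seq_ids], function(v) v[1])
    mlg_ambig <- tapply(ambig_of[seq_ids], mlg_of[seq_ids], any)
    idx <- match(mlg_of[table$id], names(mlg_call))
    call <- as.character(mlg_call[idx])
    ambig <- as.logical(mlg_ambig[idx])
  } else {
    call <- as.character(call_of[table$id])
    ambig <- as.logical(ambig_of[table$id])
  }
  unassigned <- is.na(call)
  if (any(unassigned)) {
    warning(sum(unassigned), " sample(s) without a lineage assignment retained")
  }
  drop_off <- !unassigned & !ambig & call != target
  drop_amb <- !unassigned & ambig
  keep <- !(drop_off | drop_amb)
  log <- dplyr::count(
    tibble::tibble(site = table$site,
                   fate = dplyr::case_when(drop_off ~ "removed_off_target",
                                           drop_amb ~ "removed_ambiguous",
                                           TRUE ~ "kept")),
    .data$site, .data$fate)
  for (s in unique(log$site[log$fate != "kept"])) {
    n_rm <- sum(log$n[log$site == s & log$fate != "kept"])
    message("lineage gate: removed ", n_rm, " sample(s) from ", s)
  }
  out <- table[keep, ]
  attr(out, "gate_log") <- log
  out
}
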