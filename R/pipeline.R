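#' Pipeline configuration
#'
#' @param seed mandatory base seed; every stage derives its own stream
#'   from it, so a rerun with the same seed is bit-identical.
#' @param n_perm_spatial permutations for Ac/Ee/Moran (default 1000).
#' @param n_perm_fis permutations for the F_IS HWE test (default 10000).
#' @param n_perm_fst permutations for F_ST/D_est p-values (default 1000).
#' @param n_perm_ld permutations per locus-pair disequilibrium test
#'   (default 1000).
#' @param mll_threshold optional integer overriding the gap-derived MLL
#'   collapse threshold.
#' @param target_lineage lineage label kept by the gate (only used when
#'   sequences are supplied to [run_pipeline()]).
#' @param f_is_scheme dataset feeding the F_IS used inside P_SEX:
#'   `"truncated"` (default) or `"entire"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, n_perm_spatial = 1000L, n_perm_fis = 10000L,
                            n_perm_fst = 1000L, n_perm_ld = 1000L,
                            mll_threshold = NULL, target_lineage = NULL,
                            f_is_scheme = c("truncated", "entire")) {
  if (missing(seed)) stop("pipeline_config: seed is mandatory")
  stopifnot(n_perm_spatial >= 100L, n_perm_fis >= 100L, n_perm_fst >= 100L,
            n_perm_ld >= 100L)
  structure(list(seed = as.integer(seed),
                 n_perm_spatial = as.integer(n_perm_spatial),
                 n_perm_fis = as.integer(n_perm_fis),
                 n_perm_fst = as.integer(n_perm_fst),
                 n_perm_ld = as.integer(n_perm_ld),
                 mll_threshold = mll_threshold,
                 target_lineage = target_lineage,
                 f_is_scheme = match.arg(f_is_scheme)),
            class = "pipeline_config")
}

#' Run the full clonal-structure analysis
#'
#' Orchestrates the stages end to end: completeness filtering, optional
#' mtDNA lineage gating, MLG identification, SMM distances and MLL
#' collapsing, the per-MLG clonality summary (P_gen/P_SEX), the
#' per-population diversity report, spatial statistics (where coordinates
#' exist), the entire-versus-truncated differentiation analysis, and the
#' Dice-PCoA / shared-allele network views. Non-fatal stage failures are
#' collected in a failure manifest and the remaining stages still run.
#'
#' @param table a `genotype_tbl`.
#' @param config a [pipeline_config()].
#' @param queries,references optional named sequence vectors activating
#'   the lineage gate (see [assign_lineage()]).
#' @param out_dir optional directory; when given, every report is written
#'   as CSV/JSON and a `summary.json` + `manifest.csv` are produced.
#' @return list of class `pipeline_result` with elements `table`
#'   (analysed complete-case table), `partition`, `threshold`,
#'   `mlg_summary`, `p_id`, `diversity`, `spatial`, `differentiation`,
#'   `ordination`, `network`, `failures`, `config`.
#' @export
run_pipeline <- function(table, config, queries = NULL, references = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  failures <- character(0)
  note_fail <- function(stage, e) {
    failures <<- c(failures, paste0(stage, ": ", conditionMessage(e)))
    NULL
  }
  n_total <- table(table$site)

  complete <- complete_cases(table)
  partition <- identify_mlgs(complete)

  if (!is.null(queries) && !is.null(references)) {
    gated <- tryCatch({
      assignments <- assign_lineage(queries, references)
      if (is.null(config$target_lineage)) {
        stop("target_lineage must be set when gating sequences are supplied")
      }
      filter_to_lineage(complete, assignments, config$target_lineage,
                        partition = partition)
    }, error = function(e) note_fail("lineage_gate", e))
    if (!is.null(gated)) {
      complete <- gated
      partition <- identify_mlgs(complete)
    }
  }

  dist <- smm_distance_matrix(complete, partition)
  threshold <- config$mll_threshold %||%
    tryCatch(find_collapse_threshold(dist), error = function(e) {
      note_fail("collapse_threshold", e); 0L
    })
  partition <- collapse_mll(partition, dist, threshold)

  freqs <- allele_frequencies(complete, partition, scheme = "genet")
  pid <- p_id(freqs)

  differentiation <- tryCatch(
    dual_analysis(complete, partition, n_perm_fis = config$n_perm_fis,
                  n_perm_fst = config$n_perm_fst, seed = config$seed + 300L),
    error = function(e) note_fail("differentiation", e))

  f_is_by_pop <- NULL
  if (!is.null(differentiation)) {
    fr <- differentiation[[config$f_is_scheme]]$fis
    if (!is.null(fr)) f_is_by_pop <- stats::setNames(fr$fis, fr$pop)
  }
  summary_mlg <- tryCatch({
    # P_SEX(F_IS): single multilocus F_IS per population fed into P_gen
    parts <- lapply(sort(unique(complete$site)), function(s) {
      fi <- if (!is.null(f_is_by_pop)) unname(f_is_by_pop[s]) else 0
      if (is.na(fi) || fi >= 1) fi <- 0
      mlg_summary(complete[complete$site == s, ],
                  partition[partition$site == s, ], freqs, f_is = max(fi, -1))
    })
    dplyr::bind_rows(parts)
  }, error = function(e) note_fail("mlg_summary", e))

  diversity <- tryCatch(
    clonal_diversity(complete, partition, n_total = n_total),
    error = function(e) note_fail("diversity", e))

  spatial <- tryCatch(
    spatial_report(complete, partition, n_perm = config$n_perm_spatial,
                   seed = config$seed + 200L),
    error = function(e) note_fail("spatial", e))

  ld <- tryCatch({
    trunc_tbl <- drop_excluded_loci(truncate_dataset(complete, partition))
    genotypic_ld(trunc_tbl, n_perm = config$n_perm_ld,
                 seed = config$seed + 400L)
  }, error = function(e) note_fail("genotypic_ld", e))

  ordination <- tryCatch({
    reps <- mlg_representatives(complete, partition)
    pcoa(dice_distance(reps))
  }, error = function(e) note_fail("ordination", e))

  network <- tryCatch({
    reps <- mlg_representatives(complete, partition)
    node_data <- dplyr::count(partition, .data$mlg, name = "size")
    build_network(shared_allele_distance(reps), node_data = node_data)
  }, error = function(e) note_fail("network", e))

  result <- structure(list(table = complete, partition = partition,
                           threshold = threshold, mlg_summary = summary_mlg,
                           p_id = pid, diversity = diversity, spatial = spatial,
                           ld = ld, differentiation = differentiation,
                           ordination = ordination, network = network,
                           failures = failures, config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' Write a pipeline result bundle to disk
#'
#' Emits the per-stage CSV/JSON files, a machine-readable `summary.json`
#' and a `manifest.csv` with MD5 checksums of every written file.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit_csv <- function(x, name) {
    if (is.null(x)) return()
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(x), p, progress = FALSE)
    paths <<- c(paths, p)
  }
  emit_csv(result$partition, "mlg_assignments.csv")
  emit_csv(result$mlg_summary, "mlg_summary.csv")
  emit_csv(result$diversity, "diversity_report.csv")
  emit_csv(result$spatial, "spatial_report.csv")
  emit_csv(result$ld, "ld_tests.csv")
  emit_csv(result$p_id, "p_id.csv")
  if (!is.null(result$ordination)) {
    emit_csv(result$ordination$scores, "ordination.csv")
  }
  if (!is.null(result$network)) {
    write_network(result$network,
                  graphml = file.path(out_dir, "network.graphml"),
                  edges_csv = file.path(out_dir, "edges.csv"))
    paths <- c(paths, file.path(out_dir, c("network.graphml", "edges.csv")))
  }
  if (!is.null(result$differentiation)) {
    for (tag in c("entire", "truncated")) {
      set <- result$differentiation[[tag]]
      if (!is.null(set$fst)) {
        emit_csv(as.data.frame(set$fst$estimate), paste0("fst_", tag, ".csv"))
      }
      if (!is.null(set$dest)) {
        emit_csv(as.data.frame(set$dest$estimate), paste0("dest_", tag, ".csv"))
      }
      if (!is.null(set$fis)) emit_csv(set$fis, paste0("fis_", tag, ".csv"))
    }
  }
  summary <- pipeline_summary(result)
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), progress = FALSE)
  invisible(c(paths, file.path(out_dir, "manifest.csv")))
}

pipeline_summary <- function(result) {
  div <- result$diversity
  list(
    seed = result$config$seed,
    n_samples = nrow(result$table),
    n_mlg = length(unique(result$partition$mlg)),
    n_mll = length(unique(result$partition$mll)),
    mll_threshold = result$threshold,
    superclone_share = max(table(result$partition$mlg)) / nrow(result$partition),
    p_id = if (!is.null(result$p_id)) stats::setNames(as.list(result$p_id$p_id),
                                                      result$p_id$pop) else NULL,
    diversity = if (!is.null(div)) div else NULL,
    failures = result$failures)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d samples, %d MLGs, %d MLLs (threshold %d)\n",
              nrow(x$table), length(unique(x$partition$mlg)),
              length(unique(x$partition$mll)), x$threshold))
  if (length(x$failures)) {
    cat("stage failures:\n")
    for (f in x$failures) cat("  -", f, "\n")
  }
  invisible(x)
}
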