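#' Dice distance between multilocus genotypes
#'
#' Each genotype is encoded as its set of (locus, allele) presences — a
#' homozygote contributes one band, a heterozygote two — and compared with
#' the Dice dissimilarity `1 - 2 |A n B| / (|A| + |B|)`.
#'
#' @param table a complete-case `genotype_tbl` (typically MLG
#'   representatives, see [mlg_representatives()]).
#' @return symmetric numeric matrix with the table's ids as dimnames.
#' @export
dice_distance <- function(table) {
  panel <- gt_loci(table)
  bands <- presence_matrix(table, panel)       # n x n_bands, 0/1
  inter <- tcrossprod(bands)
  sizes <- rowSums(bands)
  d <- 1 - 2 * inter / outer(sizes, sizes, "+")
  diag(d) <- 0
  dimnames(d) <- list(table$id, table$id)
  d
}

presence_matrix <- function(table, panel) {
  cols <- lapply(panel$locus, function(loc) {
    a <- table[[paste0(loc, ".1")]]; b <- table[[paste0(loc, ".2")]]
    if (anyNA(a) || anyNA(b)) stop("missing call at ", loc)
    alleles <- sort(unique(c(a, b)))
    m <- vapply(alleles, function(al) as.numeric(a == al | b == al),
                numeric(nrow(table)))
    if (nrow(table) == 1L) m <- matrix(m, nrow = 1)
    m
  })
  do.call(cbind, cols)
}

#' Shared-allele distance between multilocus genotypes
#'
#' Per locus, the multiset intersection of the two allele pairs (0, 1 or 2
#' shared copies); the distance is `1 - sum(shared) / (2 L)` over `L` loci.
#'
#' @inheritParams dice_distance
#' @return symmetric numeric matrix in `[0, 1]`.
#' @export
shared_allele_distance <- function(table) {
  panel <- gt_loci(table)
  m <- allele_matrix(table)
  if (anyNA(m)) stop("shared-allele distance needs complete genotypes")
  n <- nrow(m); L <- nrow(panel)
  shared <- matrix(0, n, n)
  for (l in seq_len(L)) {
    a1 <- m[, 2 * l - 1]; a2 <- m[, 2 * l]
    # multiset intersection of two sorted pairs: 2 iff the pairs are equal,
    # else 1 iff any allele is common, else 0
    eq_pair <- outer(a1, a1, "==") & outer(a2, a2, "==")
    any_common <- outer(a1, a1, "==") | outer(a2, a2, "==") |
      outer(a1, a2, "==") | outer(a2, a1, "==")
    shared <- shared + eq_pair + any_common
  }
  d <- 1 - shared / (2 * L)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Principal coordinates of a dissimilarity matrix
#'
#' Classical metric scaling (Gower double-centering of `-d^2/2` and
#' eigendecomposition, via [stats::cmdscale()]): the standard realisation
#' of a "PCA on a dissimilarity matrix". Coordinates are eigenvectors
#' scaled by the square root of their eigenvalues; negative eigenvalues
#' (possible for non-Euclidean input such as Dice) are reported but
#' excluded from the percent-variance denominators.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param n_axes number of axes to retain (default: all positive).
#' @return object of class `pcoa_result`: `scores` (tibble `id`, `axis1`,
#'   ...), `eigenvalues`, `pct_variance` (over positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  n <- nrow(d)
  if (is.null(rownames(d))) dimnames(d) <- list(as.character(seq_len(n)),
                                                as.character(seq_len(n)))
  # negative eigenvalues are expected for non-Euclidean input; they are
  # reported below rather than warned about
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-9 * max(abs(eig)))
  if (is.null(n_axes)) n_axes <- length(pos)
  n_axes <- min(n_axes, length(pos))
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(n_axes))
  scores <- tibble::as_tibble(coords)
  scores <- dplyr::bind_cols(tibble::tibble(id = rownames(d)), scores)
  structure(list(scores = scores,
                 eigenvalues = eig,
                 pct_variance = 100 * eig[pos] / sum(eig[pos]),
                 n_axes = n_axes),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d points, %d retained axes; axis percentages: %s\n",
              nrow(x$scores), x$n_axes,
              paste(sprintf("%.1f%%", utils::head(x$pct_variance, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a clone network from a genetic distance matrix
#'
#' Nodes are MLGs; edges join pairs whose distance does not exceed a
#' threshold. When no threshold is given, the percolation threshold is
#' used: the smallest edge weight at which the thresholded graph becomes
#' connected (found by scanning the sorted unique weights), the standard
#' choice for shared-allele clone networks.
#'
#' @param d symmetric distance matrix (e.g. [shared_allele_distance()]).
#' @param node_data optional tibble with a first column matching the
#'   matrix dimnames (e.g. MLG sizes and per-site composition).
#' @param threshold optional numeric edge threshold.
#' @return object of class `clone_network`: `graph` (igraph), `nodes`,
#'   `edges` (tibbles), `threshold`.
#' @export
build_network <- function(d, node_data = NULL, threshold = NULL) {
  d <- as.matrix(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(d)))
  if (nrow(d) == 1L) {
    g <- igraph::make_empty_graph(1, directed = FALSE)
    igraph::V(g)$name <- ids
    return(structure(list(graph = g,
                          nodes = tibble::tibble(id = ids),
                          edges = tibble::tibble(from = character(), to = character(),
                                                 weight = numeric()),
                          threshold = threshold %||% 0),
                     class = "clone_network"))
  }
  w <- d[upper.tri(d)]
  if (is.null(threshold)) threshold <- percolation_threshold(d)
  keep <- which(upper.tri(d) & d <= threshold, arr.ind = TRUE)
  edges <- tibble::tibble(from = ids[keep[, 1]], to = ids[keep[, 2]],
                          weight = d[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  nodes <- tibble::tibble(id = ids)
  if (!is.null(node_data)) {
    names(node_data)[1] <- "id"
    nodes <- dplyr::left_join(nodes, node_data, by = "id")
  }
  structure(list(graph = g, nodes = nodes, edges = edges, threshold = threshold),
            class = "clone_network")
}

percolation_threshold <- function(d) {
  ws <- sort(unique(d[upper.tri(d)]))
  for (w in ws) {
    adj <- d <= w
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no == 1L) return(w)
  }
  ws[length(ws)]
}

#' @export
print.clone_network <- function(x, ...) {
  cat(sprintf("clone network: %d nodes, %d edges, threshold %.4f\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Export a clone network as GraphML and edge-list CSV
#' @param network a `clone_network`.
#' @param graphml,edges_csv output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
write_network <- function(network, graphml = NULL, edges_csv = NULL) {
  if (!is.null(graphml)) {
    g <- network$graph
    for (col in setdiff(names(network$nodes), "id")) {
      g <- igraph::set_vertex_attr(g, col,
                                   value = network$nodes[[col]][match(igraph::V(g)$name,
                                                                      network$nodes$id)])
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  if (!is.null(edges_csv)) readr::write_csv(network$edges, edges_csv, progress = FALSE)
  invisible(list(graphml = graphml, edges_csv = edges_csv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
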