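# Single-cell cluster-enrichment check: is a transcript uniformly
# distributed across precomputed cell clusters (a maternally loaded
# reservoir present in every cell), or enriched in specific clusters
# (early lineage-specific localization)? Enrichment is defined on
# expressing-cell fractions (detection at count > 0), the robust signal
# at the low expression levels typical of these stages, not on mean
# counts.

#' Score cluster enrichment of one gene's expressing cells
#'
#' For each cluster c: the expressing fraction (#cells with count > 0
#' divided by cluster size), the fold enrichment of the in-cluster over
#' the out-of-cluster expressing fraction (add-one smoothing on the
#' expressing-cell counts keeps folds finite), the one-sided
#' hypergeometric tail probability of drawing at least the observed
#' number of expressing cells into the cluster, and Benjamini-Hochberg
#' q-values across the K clusters.
#'
#' @param counts Cells x genes numeric matrix (rownames = cell ids,
#'   colnames = gene symbols); any non-negative values, binarized at
#'   count > 0.
#' @param clusters Integer/character vector of cluster labels, one per
#'   cell (every cluster non-empty, K >= 2).
#' @param gene Gene symbol (column of `counts`).
#' @param min_cells Minimum total expressing cells for a call
#'   (default 20); below it the result is NO_CALL.
#' @return An `enrichment_result`: list with `gene`, `n_expressing`,
#'   `table` (per-cluster data frame: `cluster`, `n_cells`,
#'   `n_expressing`, `expressing_fraction`, `fold_enrichment`, `p_value`,
#'   `q_value`), `no_call`.
#' @export
score_cluster_enrichment <- function(counts, clusters, gene, min_cells = 20) {
  stopifnot(is.matrix(counts) || inherits(counts, "Matrix"))
  if (length(clusters) != nrow(counts))
    stop("`clusters` must have one label per cell (row of `counts`)",
         call. = FALSE)
  j <- match(gene, colnames(counts))
  if (is.na(j)) stop("gene not in matrix: ", gene, call. = FALSE)
  cl <- factor(clusters)
  if (nlevels(cl) < 2) stop("need K >= 2 clusters", call. = FALSE)
  if (any(table(cl) == 0)) stop("every cluster must have >= 1 cell", call. = FALSE)

  expressing <- as.numeric(counts[, j]) > 0
  N <- length(expressing)
  K_tot <- sum(expressing)

  n_c <- as.integer(table(cl))
  k_c <- as.integer(tapply(expressing, cl, sum))
  k_c[is.na(k_c)] <- 0L
  frac_in <- k_c / n_c
  n_out <- N - n_c
  k_out <- K_tot - k_c
  fold <- ((k_c + 1) / (n_c + 1)) / ((k_out + 1) / (n_out + 1))
  # P(X >= k_c), X ~ Hypergeometric(K_tot expressing in N, draw n_c)
  p <- stats::phyper(k_c - 1, K_tot, N - K_tot, n_c, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")

  structure(list(
    gene = gene, n_expressing = K_tot,
    table = data.frame(cluster = levels(cl), n_cells = n_c,
                       n_expressing = k_c, expressing_fraction = frac_in,
                       fold_enrichment = fold, p_value = p, q_value = q,
                       stringsAsFactors = FALSE),
    no_call = K_tot < min_cells
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: %d expressing cells%s\n", x$gene,
              x$n_expressing, if (x$no_call) " [NO_CALL]" else ""))
  top <- x$table[order(x$table$q_value), ][1:min(3, nrow(x$table)), ]
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Classify a gene as uniform or cluster-enriched
#'
#' ENRICHED in the (sorted) clusters meeting both criteria, fold
#' enrichment >= `fold_min` and q-value <= `q_max`; UNIFORM when none
#' does; NO_CALL propagated from scoring.
#'
#' @param result An `enrichment_result`.
#' @param fold_min Minimum fold enrichment (default 2).
#' @param q_max Maximum BH q-value (default 0.05).
#' @return List with `call` (`"UNIFORM"`, `"ENRICHED"` or `"NO_CALL"`)
#'   and `clusters` (character vector, empty unless ENRICHED).
#' @export
classify_distribution <- function(result, fold_min = 2, q_max = 0.05) {
  stopifnot(inherits(result, "enrichment_result"))
  if (result$no_call) return(list(call = "NO_CALL", clusters = character(0)))
  tab <- result$table
  hits <- tab$cluster[tab$fold_enrichment >= fold_min & tab$q_value <= q_max]
  hits <- sort(hits)
  if (length(hits) == 0) list(call = "UNIFORM", clusters = character(0))
  else list(call = "ENRICHED", clusters = hits)
}

#' Read a cells x genes matrix from MTX plus barcode/feature lists
#'
#' Standard MatrixMarket triplet layout as written by common single-cell
#' pipelines; the matrix is transposed if needed so that rows are cells.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param barcodes_path One cell id per line.
#' @param features_path One gene symbol per line (first column if
#'   tab-separated).
#' @return Dense cells x genes matrix with dimnames.
#' @export
read_cell_matrix <- function(mtx_path, barcodes_path, features_path) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  cells <- readLines(barcodes_path)
  feats <- vapply(strsplit(readLines(features_path), "\t"), `[`, "", 1)
  if (nrow(m) == length(feats) && ncol(m) == length(cells) &&
      length(feats) != length(cells))
    m <- t(m)
  if (nrow(m) != length(cells) || ncol(m) != length(feats))
    stop("matrix dimensions do not match barcode/feature counts",
         call. = FALSE)
  dimnames(m) <- list(cells, feats)
  m
}
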