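#' Per-cell depth normalization with log transform
#'
#' Scales every cell to a common depth and log-transforms:
#' `value(c, g) = ln(1 + count(c, g) * scale_factor / n_umi(c))`.
#' All-zero cells stay all-zero. This is the standard library-size
#' normalization for UMI data; sperm cells carry ~50 fg of fragmented RNA,
#' so depths are tiny and the scaling matters.
#'
#' @param gbm A (filtered) [gene_barcode_matrix()].
#' @param scale_factor Target depth per cell (default 10000).
#' @return A `normalized_matrix`: list with `values` (sparse barcodes x genes
#'   matrix of normalized log expression), `scale_factor`, `sample_id`.
#' @export
log_normalize <- function(gbm, scale_factor = 10000) {
  stopifnot_gbm(gbm)
  n_umi <- Matrix::rowSums(gbm$counts)
  inv <- ifelse(n_umi > 0, scale_factor / n_umi, 0)
  values <- Matrix::Diagonal(x = inv) %*% gbm$counts
  values <- as(values, "CsparseMatrix")
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(gbm$counts)
  structure(list(values = values, scale_factor = scale_factor,
                 sample_id = gbm$sample_id),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d cells x %d genes, ln(1 + x * %g / depth)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Pool several samples into one matrix over common genes
#'
#' Cells from all samples are stacked (barcodes prefixed with the sample id
#' to stay unique); genes are restricted to those present in every sample.
#'
#' @param matrices List of [gene_barcode_matrix()] objects.
#' @return A list: `matrix` (the pooled `gene_barcode_matrix`) and `cells`
#'   (tibble mapping pooled `barcode` to `sample_id` and original barcode).
#' @export
pool_samples <- function(matrices) {
  purrr::walk(matrices, stopifnot_gbm)
  common <- Reduce(intersect, purrr::map(matrices, genes_of))
  if (length(common) == 0) abort("No genes are common to all samples.")
  parts <- purrr::map(matrices, function(m) {
    x <- m$counts[, common, drop = FALSE]
    rownames(x) <- paste(m$sample_id, rownames(x), sep = "_")
    x
  })
  pooled <- do.call(rbind, parts)
  cells <- purrr::map_dfr(matrices, function(m) {
    tibble(barcode = paste(m$sample_id, barcodes_of(m), sep = "_"),
           sample_id = m$sample_id, original_barcode = barcodes_of(m))
  })
  mask <- matrices[[1]]$mito_mask[common]
  list(matrix = gene_barcode_matrix(pooled, mito_mask = mask,
                                    sample_id = "pooled"),
       cells = cells)
}

#' Cross-cohort correlation of average expression
#'
#' Averages normalized expression per gene across the cells of each cohort
#' and reports the squared Pearson correlation of the two mean vectors over
#' the common gene universe.
#'
#' @param norm_a,norm_b `normalized_matrix` objects for the two cohorts.
#' @return A one-row tibble: `n_genes`, `pearson_r`, `r_squared`.
#' @export
average_expression_correlation <- function(norm_a, norm_b) {
  stopifnot(inherits(norm_a, "normalized_matrix"),
            inherits(norm_b, "normalized_matrix"))
  common <- intersect(colnames(norm_a$values), colnames(norm_b$values))
  if (length(common) < 2) {
    abort("Need at least 2 common genes to compute a correlation.")
  }
  mean_a <- Matrix::colMeans(norm_a$values[, common, drop = FALSE])
  mean_b <- Matrix::colMeans(norm_b$values[, common, drop = FALSE])
  if (stats::sd(mean_a) == 0 || stats::sd(mean_b) == 0) {
    abort("A cohort's per-gene means are constant; the correlation is undefined.")
  }
  r <- stats::cor(mean_a, mean_b)
  tibble(n_genes = length(common), pearson_r = r, r_squared = r^2)
}

#' Single-cell-level Wilcoxon rank-sum differential expression
#'
#' Tests every gene for a distributional shift between the two cohorts
#' across all single cells, after dropping genes expressed (value > 0) in
#' fewer than `min_fraction` of the cells of *both* groups (a gene is kept
#' if it clears the fraction in either group). P-values come from the
#' two-sided rank-sum test — tie-corrected continuity-corrected normal
#' approximation, or exact enumeration of all label assignments when the
#' total cell count is at most `exact_max_n`. Bonferroni adjustment
#' multiplies by the number of genes actually tested.
#'
#' @param norm A `normalized_matrix` of the pooled cells.
#' @param labels Cohort label per cell (exactly two distinct values).
#' @param group_a The label treated as group A (fold changes are
#'   group A minus group B); defaults to the first distinct label.
#' @param min_fraction Marker-expression filter (default 0.01: present in at
#'   least 1% of cells in either group).
#' @param exact_max_n Use exact enumeration when `n_a + n_b` is at most this.
#' @return A tibble sorted by decreasing `avg_log_fc`: `gene_id`,
#'   `avg_log_fc`, `p_value`, `adjusted_p` (Bonferroni, capped at 1),
#'   `pct_group1`, `pct_group2` (expression fractions in A and B).
#' @export
wilcoxon_deg <- function(norm, labels, group_a = NULL, min_fraction = 0.01,
                         exact_max_n = 16) {
  stopifnot(inherits(norm, "normalized_matrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(norm$values)) {
    abort("`labels` must have one entry per cell.")
  }
  lv <- unique(labels)
  if (length(lv) != 2) abort("Exactly two cohorts are required.")
  group_a <- group_a %||% lv[1]
  if (!group_a %in% lv) abort(sprintf("Label '%s' not present.", group_a))
  in_a <- labels == group_a
  n_a <- sum(in_a); n_b <- sum(!in_a)
  if (n_a == 0 || n_b == 0) abort("Both cohorts must be non-empty.")

  vals <- norm$values
  pct1 <- Matrix::colSums(vals[in_a, , drop = FALSE] > 0) / n_a
  pct2 <- Matrix::colSums(vals[!in_a, , drop = FALSE] > 0) / n_b
  test_gene <- pct1 >= min_fraction | pct2 >= min_fraction
  genes <- colnames(vals)[test_gene]
  m <- length(genes)
  if (m == 0) {
    return(tibble(gene_id = character(), avg_log_fc = numeric(),
                  p_value = numeric(), adjusted_p = numeric(),
                  pct_group1 = numeric(), pct_group2 = numeric()))
  }

  mean_a <- Matrix::colMeans(vals[in_a, genes, drop = FALSE])
  mean_b <- Matrix::colMeans(vals[!in_a, genes, drop = FALSE])
  use_exact <- (n_a + n_b) <= exact_max_n
  p <- vapply(genes, function(g) {
    x <- as.numeric(vals[, g])
    if (use_exact) {
      rank_sum_p_exact(x, in_a, "two.sided")
    } else {
      rank_sum_p_normal(rank_sum_moments(x, in_a), "two.sided")
    }
  }, numeric(1))

  tibble(
    gene_id = genes,
    avg_log_fc = as.numeric(mean_a - mean_b),
    p_value = as.numeric(p),
    adjusted_p = pmin(1, as.numeric(p) * m),
    pct_group1 = as.numeric(pct1[test_gene]),
    pct_group2 = as.numeric(pct2[test_gene])
  ) |>
    arrange(desc(.data$avg_log_fc))
}

#' Export a pre-ranked gene list (RNK format)
#'
#' Writes a two-column tab-separated file (gene, score) ordered by
#' decreasing score, for consumption by pre-ranked gene-set enrichment
#' tools. Ties are broken lexicographically by gene id so the file order is
#' fully determined.
#'
#' @param results Tibble from [wilcoxon_deg()].
#' @param path Output file path.
#' @param score Ranking score: the average log fold change (default) or the
#'   signed -log10 p-value.
#' @return The path, invisibly.
#' @export
export_preranked <- function(results, path,
                             score = c("avg_log_fc", "signed_log10_p")) {
  score <- match.arg(score)
  if (nrow(results) == 0) abort("No results to export.")
  if (anyDuplicated(results$gene_id)) abort("Duplicate gene ids in results.")
  s <- switch(score,
    avg_log_fc = results$avg_log_fc,
    signed_log10_p = sign(results$avg_log_fc) * -log10(pmax(results$p_value, 1e-300))
  )
  ord <- order(-s, results$gene_id)
  readr::write_tsv(tibble(gene = results$gene_id[ord], score = s[ord]),
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a pre-ranked gene list written by [export_preranked()]
#'
#' @param path RNK file path.
#' @return Tibble with columns `gene`, `score` in file order.
#' @export
read_preranked <- function(path) {
  readr::read_tsv(path, col_names = c("gene", "score"),
                  col_types = readr::cols(gene = "c", score = "d"))
}
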