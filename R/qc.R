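#' Per-cell quality-control metrics
#'
#' Computes, for every barcode, the total UMI count (`n_umi`), the number of
#' detected genes (`n_genes`, genes with at least one UMI) and the percentage
#' of UMI coming from mitochondrial genes (`pct_mito`; 0 for an all-zero
#' cell). Mature spermatozoa carry very little RNA, so these metrics sit far
#' below typical somatic-cell scRNA-seq values; the filtering thresholds in
#' [filter_thresholds()] reflect that.
#'
#' @param gbm A [gene_barcode_matrix()].
#' @return A tibble with columns `barcode`, `n_umi`, `n_genes`, `pct_mito`.
#' @export
#' @examples
#' m <- matrix(c(3, 0, 2), nrow = 1, dimnames = list("AAAC", c("g1", "g2", "MT-1")))
#' compute_cell_metrics(gene_barcode_matrix(m, c(FALSE, FALSE, TRUE)))
compute_cell_metrics <- function(gbm) {
  stopifnot_gbm(gbm)
  counts <- gbm$counts
  n_umi <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito_umi <- if (any(gbm$mito_mask)) {
    Matrix::rowSums(counts[, gbm$mito_mask, drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  pct_mito <- ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  tibble(
    barcode = rownames(counts) %||% character(),
    n_umi = as.integer(n_umi),
    n_genes = as.integer(n_genes),
    pct_mito = as.numeric(pct_mito)
  )
}

#' Filtering thresholds for the QC cascade
#'
#' The defaults are the study thresholds for sperm scRNA-seq: cells need at
#' least 25 UMI and at least 10 detected genes, cells with more than 40% of
#' UMI from mitochondrial genes are excluded, and genes must be detected in
#' at least 20 of the retained cells. All boundaries are inclusive on the
#' "keep" side: a cell with exactly 25 UMI, exactly 10 genes or exactly 40%
#' mitochondrial UMI is retained, and a gene detected in exactly 20 cells is
#' retained.
#'
#' @param min_umi Minimum UMI per cell (keep `n_umi >= min_umi`).
#' @param min_genes_per_cell Minimum detected genes per cell.
#' @param min_cells_per_gene Minimum retained cells a gene must be detected in.
#' @param max_pct_mito Maximum mitochondrial percentage (keep `<=`).
#' @return A named list of thresholds, class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_umi = 25, min_genes_per_cell = 10,
                              min_cells_per_gene = 20, max_pct_mito = 40) {
  vals <- list(min_umi = min_umi, min_genes_per_cell = min_genes_per_cell,
               min_cells_per_gene = min_cells_per_gene,
               max_pct_mito = max_pct_mito)
  if (any(unlist(vals) < 0)) abort("All thresholds must be non-negative.")
  structure(vals, class = "filter_thresholds")
}

#' Apply the cell/gene filtering cascade
#'
#' Cell filters are evaluated on the metrics of the *original* matrix: a cell
#' is retained iff `n_umi >= min_umi` and `n_genes >= min_genes_per_cell` and
#' `pct_mito <= max_pct_mito`. The gene filter then runs once on the
#' surviving cells: a gene is retained iff detected (count > 0) in at least
#' `min_cells_per_gene` retained cells. The cascade is a single pass — it is
#' not iterated, so a gene's removal never feeds back into cell removal.
#' Counts are never altered, only subset.
#'
#' @param gbm A [gene_barcode_matrix()].
#' @param thresholds A [filter_thresholds()].
#' @return A list with elements:
#'   \describe{
#'     \item{matrix}{the filtered `gene_barcode_matrix`}
#'     \item{removed}{tibble of removed entities: `entity` ("cell"/"gene"),
#'       `id`, and `rule` — the first failing rule in the order
#'       `min_umi`, `min_genes_per_cell`, `max_pct_mito`, `min_cells_per_gene`}
#'     \item{metrics}{the per-cell QC metrics of the original matrix}
#'   }
#' @export
filter_cells_genes <- function(gbm, thresholds = filter_thresholds()) {
  stopifnot_gbm(gbm)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  met <- compute_cell_metrics(gbm)

  fail_umi <- met$n_umi < thresholds$min_umi
  fail_genes <- met$n_genes < thresholds$min_genes_per_cell
  fail_mito <- met$pct_mito > thresholds$max_pct_mito
  keep_cell <- !(fail_umi | fail_genes | fail_mito)

  first_rule <- dplyr::case_when(
    fail_umi ~ "min_umi",
    fail_genes ~ "min_genes_per_cell",
    fail_mito ~ "max_pct_mito",
    TRUE ~ NA_character_
  )
  removed_cells <- tibble(
    entity = "cell",
    id = met$barcode[!keep_cell],
    rule = first_rule[!keep_cell]
  )

  kept <- gbm$counts[keep_cell, , drop = FALSE]
  cells_per_gene <- Matrix::colSums(kept > 0)
  keep_gene <- cells_per_gene >= thresholds$min_cells_per_gene
  removed_genes <- tibble(
    entity = "gene",
    id = colnames(kept)[!keep_gene],
    rule = "min_cells_per_gene"
  )

  out <- gene_barcode_matrix(
    kept[, keep_gene, drop = FALSE],
    mito_mask = gbm$mito_mask[keep_gene],
    sample_id = gbm$sample_id
  )
  list(matrix = out, removed = bind_rows(removed_cells, removed_genes),
       metrics = met)
}

#' Common-gene counts within and across cohorts
#'
#' A gene counts as detected in a sample if it is expressed (count > 0) in at
#' least one retained cell. Returns the size of the gene-set intersection
#' within each cohort and across all samples.
#'
#' @param matrices List of (filtered) [gene_barcode_matrix()] objects.
#' @param group_labels Character vector of cohort labels, one per matrix.
#' @return A tibble with columns `group` (each cohort label plus `"all"`),
#'   `n_samples` and `n_common_genes`.
#' @export
gene_set_intersections <- function(matrices, group_labels) {
  stopifnot(length(matrices) == length(group_labels), length(matrices) >= 1)
  purrr::walk(matrices, stopifnot_gbm)
  if (anyNA(group_labels)) abort("Cohort labels must not be missing.")
  detected <- purrr::map(matrices, function(m) {
    genes_of(m)[Matrix::colSums(m$counts > 0) > 0]
  })
  groups <- unique(group_labels)
  per_group <- purrr::map(groups, function(g) {
    sets <- detected[group_labels == g]
    if (length(sets) == 0) abort(sprintf("Cohort '%s' has no samples.", g))
    Reduce(intersect, sets)
  })
  tibble(
    group = c(groups, "all"),
    n_samples = c(as.integer(table(factor(group_labels, levels = groups))),
                  length(matrices)),
    n_common_genes = c(lengths(per_group),
                       length(Reduce(intersect, detected)))
  )
}

#' Seeded uniform subsampling of cells
#'
#' Draws `n_target` barcodes uniformly without replacement, reproducibly
#' under `seed`. If the sample has fewer cells than `n_target`, all cells are
#' kept and a warning is raised — with sperm samples the per-sample cell
#' count after filtering can fall short of a nominal target.
#'
#' @param gbm A [gene_barcode_matrix()].
#' @param n_target Number of cells to draw (study value: 12000 per sample).
#' @param seed Integer seed; no global random state is touched.
#' @return A `gene_barcode_matrix` with at most `n_target` cells.
#' @export
subsample_cells <- function(gbm, n_target = 12000, seed) {
  stopifnot_gbm(gbm)
  if (n_target < 1) abort("`n_target` must be at least 1.")
  n <- nrow(gbm$counts)
  if (n < n_target) {
    warn(sprintf("Sample '%s' has %d cells, fewer than the %d requested; keeping all.",
                 gbm$sample_id, n, n_target))
    return(gbm)
  }
  idx <- withr::with_seed(seed, sort(sample.int(n, n_target)))
  gene_barcode_matrix(gbm$counts[idx, , drop = FALSE],
                      mito_mask = gbm$mito_mask,
                      sample_id = gbm$sample_id)
}

#' @rdname plot_qc_metrics
#' @param object A [gene_barcode_matrix()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_barcode_matrix <- function(object, ...) {
  met <- compute_cell_metrics(object)
  met$sample_id <- object$sample_id
  plot_qc_metrics(met)
}

#' Violin plot of per-cell QC metrics
#'
#' @param metrics Tibble from [compute_cell_metrics()], optionally with a
#'   `sample_id` column (added automatically when you `bind_rows()` metrics
#'   of several samples with `.id`).
#' @return A ggplot object with one facet per metric.
#' @export
plot_qc_metrics <- function(metrics) {
  if (!"sample_id" %in% names(metrics)) metrics$sample_id <- "sample"
  long <- tidyr::pivot_longer(metrics, c("n_umi", "n_genes", "pct_mito"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey80", scale = "width") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
}
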