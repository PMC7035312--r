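test_that("per-cell metrics match hand arithmetic and a dense-loop oracle", {
  met <- compute_cell_metrics(tiny_gbm())
  # BC1: counts 3,0,2 with g3 mitochondrial
  expect_equal(met$n_umi[met$barcode == "BC1"], 5L)
  expect_equal(met$n_genes[met$barcode == "BC1"], 2L)
  expect_equal(met$pct_mito[met$barcode == "BC1"], 40)
  # all-zero cell
  expect_equal(met$n_umi[met$barcode == "BC2"], 0L)
  expect_equal(met$n_genes[met$barcode == "BC2"], 0L)
  expect_equal(met$pct_mito[met$barcode == "BC2"], 0)

  g <- random_gbm()
  oracle <- metrics_oracle(g)
  met2 <- compute_cell_metrics(g)
  expect_equal(met2$barcode, oracle$barcode)
  expect_equal(met2$n_umi, as.integer(oracle$n_umi))
  expect_equal(met2$n_genes, as.integer(oracle$n_genes))
  expect_equal(met2$pct_mito, oracle$pct_mito)
})

test_that("cell filters keep exactly the quoted boundaries", {
  # one gene per rule; min_cells_per_gene = 0 so only cell rules act
  mk <- function(umi_counts) {
    n <- length(umi_counts)
    m <- matrix(0, nrow = n, ncol = 30,
                dimnames = list(sprintf("BC%02d", seq_len(n)),
                                sprintf("g%02d", 1:30)))
    for (i in seq_len(n)) {
      m[i, seq_len(min(umi_counts[i], 30))] <-
        rep(1, min(umi_counts[i], 30))
      extra <- umi_counts[i] - min(umi_counts[i], 30)
      if (extra > 0) m[i, 1] <- m[i, 1] + extra
    }
    gene_barcode_matrix(m, sample_id = "B")
  }
  t0 <- filter_thresholds(min_umi = 25, min_genes_per_cell = 10,
                          min_cells_per_gene = 0, max_pct_mito = 40)
  # 24 UMI removed, 25 retained, 26 retained (each cell has >= 10 genes)
  g <- mk(c(24, 25, 26))
  f <- filter_cells_genes(g, t0)
  expect_setequal(rownames(f$matrix$counts), c("BC02", "BC03"))
  expect_equal(f$removed$rule[f$removed$id == "BC01"], "min_umi")

  # 9 genes removed, 10 retained, 11 retained (UMI padded above 25)
  m <- matrix(0, 3, 12, dimnames = list(c("a", "b", "c"), sprintf("g%d", 1:12)))
  m[1, 1:9] <- 3; m[2, 1:10] <- 3; m[3, 1:11] <- 3
  f2 <- filter_cells_genes(gene_barcode_matrix(m), t0)
  expect_setequal(rownames(f2$matrix$counts), c("b", "c"))
  expect_equal(f2$removed$rule[f2$removed$id == "a"], "min_genes_per_cell")

  # mito 39 / 40 / 41 percent: only strictly above 40 is removed
  m3 <- matrix(0, 3, 30, dimnames = list(c("p39", "p40", "p41"),
                                         sprintf("g%d", 1:30)))
  mito <- c(rep(FALSE, 29), TRUE)
  # exact mito percentages on 100 UMI spread over >= 10 genes
  mk_pct <- function(pct) {
    row <- numeric(30); row[1:19] <- 1; row[20] <- 81 - pct; row[30] <- pct
    row
  }
  m3[1, ] <- mk_pct(39); m3[2, ] <- mk_pct(40); m3[3, ] <- mk_pct(41)
  f3 <- filter_cells_genes(gene_barcode_matrix(m3, mito_mask = mito), t0)
  expect_setequal(rownames(f3$matrix$counts), c("p39", "p40"))
  expect_equal(f3$removed$rule[f3$removed$id == "p41"], "max_pct_mito")
})

test_that("gene filter counts detection among retained cells at the 20-cell boundary", {
  # 25 healthy cells; gene gA detected in 19, gB in 20, gC in 21
  n <- 25
  m <- matrix(0, n, 14, dimnames = list(sprintf("BC%02d", 1:n),
                                        c(sprintf("f%02d", 1:11), "gA", "gB", "gC")))
  m[, 1:11] <- 3  # every cell: 11 genes, 33+ UMI
  m[1:19, "gA"] <- 1
  m[1:20, "gB"] <- 1
  m[1:21, "gC"] <- 1
  f <- filter_cells_genes(gene_barcode_matrix(m))
  expect_false("gA" %in% colnames(f$matrix$counts))
  expect_true(all(c("gB", "gC") %in% colnames(f$matrix$counts)))
  expect_equal(f$removed$rule[f$removed$id == "gA"], "min_cells_per_gene")
})

test_that("filtering conserves barcodes, alters no counts, and is monotone in thresholds", {
  g <- random_gbm(n_cells = 60, n_genes = 20, seed = 7)
  f <- filter_cells_genes(g, filter_thresholds(3, 2, 2, 60))
  removed_cells <- f$removed$id[f$removed$entity == "cell"]
  expect_setequal(c(rownames(f$matrix$counts), removed_cells),
                  rownames(g$counts))
  kept <- f$matrix
  expect_equal(as.matrix(kept$counts),
               as.matrix(g$counts[rownames(kept$counts), colnames(kept$counts)]))

  base_cells <- nrow(f$matrix$counts); base_genes <- ncol(f$matrix$counts)
  for (t in list(filter_thresholds(5, 2, 2, 60), filter_thresholds(3, 4, 2, 60),
                 filter_thresholds(3, 2, 5, 60), filter_thresholds(3, 2, 2, 30))) {
    f2 <- filter_cells_genes(g, t)
    expect_lte(nrow(f2$matrix$counts), base_cells)
    expect_lte(ncol(f2$matrix$counts), base_genes)
  }
})

test_that("one-pass cascade is a fixed point on the cell side", {
  g <- random_gbm(n_cells = 80, n_genes = 25, seed = 11)
  t <- filter_thresholds(3, 2, 4, 60)
  f1 <- filter_cells_genes(g, t)
  f2 <- filter_cells_genes(f1$matrix, t)
  # no cell is removed on the second pass: cell metrics only shrink via
  # gene removal, and a re-run may only drop genes that fell below the
  # detection floor after cell removal
  expect_equal(sum(f2$removed$entity == "cell"), 0)
  f3 <- filter_cells_genes(f2$matrix, t)
  expect_equal(nrow(f3$removed), 0)
})

test_that("gene-set intersections equal brute-force set algebra", {
  mk <- function(genes, id) {
    m <- matrix(1, 2, length(genes), dimnames = list(c("a", "b"), genes))
    gene_barcode_matrix(m, sample_id = id)
  }
  same <- gene_set_intersections(list(mk(c("x", "y"), "s1"), mk(c("x", "y"), "s2")),
                                 c("G", "G"))
  expect_equal(same$n_common_genes[same$group == "G"], 2L)
  disjoint <- gene_set_intersections(list(mk("x", "s1"), mk("y", "s2")),
                                     c("G", "G"))
  expect_equal(disjoint$n_common_genes[disjoint$group == "G"], 0L)

  withr::with_seed(9, {
    sets <- purrr::map(1:4, ~sample(sprintf("g%02d", 1:30), 15))
    mats <- purrr::imap(sets, ~mk(.x, paste0("s", .y)))
    labels <- c("A", "A", "B", "B")
    res <- gene_set_intersections(mats, labels)
    expect_equal(res$n_common_genes[res$group == "A"],
                 length(intersect(sets[[1]], sets[[2]])))
    expect_equal(res$n_common_genes[res$group == "B"],
                 length(intersect(sets[[3]], sets[[4]])))
    expect_equal(res$n_common_genes[res$group == "all"],
                 length(Reduce(intersect, sets)))
  })
  expect_error(gene_set_intersections(list(), character()), ".")
})

test_that("subsampling is uniform, seeded, and warns on shortfall", {
  g <- random_gbm(n_cells = 50, n_genes = 8, seed = 3)
  s1 <- subsample_cells(g, 20, seed = 123)
  s2 <- subsample_cells(g, 20, seed = 123)
  expect_equal(nrow(s1$counts), 20)
  expect_identical(rownames(s1$counts), rownames(s2$counts))
  s3 <- subsample_cells(g, 20, seed = 124)
  expect_false(identical(rownames(s1$counts), rownames(s3$counts)))
  expect_warning(keep_all <- subsample_cells(g, 12000, seed = 1),
                 "fewer")
  expect_equal(nrow(keep_all$counts), 50)
})

test_that("QC and burden plots build without evaluation errors", {
  g <- random_gbm(n_cells = 20, n_genes = 10, seed = 77)
  p1 <- plot_qc_metrics(compute_cell_metrics(g))
  expect_s3_class(p1, "ggplot")
  lab <- tibble::tibble(chrom = "c1", pos = 1:30, ref = "A", alt = "G",
                        region = rep(c("exonic", "intronic", "intergenic"), 10))
  s <- normalize_burden(sample_variant_stats(lab, lab[1:3, ], "S1",
                                             reads_mapped = 1e5,
                                             read_size = 98,
                                             chrom_lengths = c(c1 = 1e5)))
  p2 <- plot_burden(list(s))
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
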