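# Umbrella configuration and end-to-end driver: simulate -> qc -> deg ->
# cellvar -> burden, with a manifest and a summary so every reported count
# is reproducible from the artifact directory alone.

default_config <- function() {
  list(
    design = list(n_asd_samples = 2, n_control_samples = 4,
                  barcodes_per_sample = 1500, genes = 300,
                  mito_gene_fraction = 0.1, seed = 1),
    qc = list(min_umi = 25, min_genes_per_cell = 10, min_cells_per_gene = 20,
              max_pct_mito = 40, subsample = 12000),
    deg = list(scale_factor = 10000, min_fraction = 0.01, alpha = 0.05,
               n_planted_degs = 4, planted_lfc = 1),
    cellvar = list(n_cells = 300, reads_per_cell_mean = 150,
                   reads_per_cell_size = 5, per_base_error = 0.001,
                   min_reads_per_cell = 100, min_base_quality = 13,
                   error_rate = 0.001, min_alt_reads_per_cell = 1,
                   min_qual = 20, min_cells = 10, stringent = FALSE,
                   shared_variants = 3, asd_extra_variants = 2,
                   carrier_fraction = 0.3),
    burden = list(read_size = 98, max_af = 0.001, cluster_window = 35,
                  min_cluster = 3, min_alt_depth = 20,
                  alternative = "greater")
  )
}

#' Pipeline configuration
#'
#' Builds the nested configuration for [run_pipeline()]. Every default
#' matching a study threshold carries the study value (25 UMI, 10 genes,
#' 40% mito, 20 cells/gene, 12000-cell subsampling, 1% marker fraction,
#' 100 reads/cell, quality 20, 10 cells, 35 bp / 3-SNP clusters, 20X
#' alternative depth, allele frequency 0.001, read size 98, one-sided
#' "greater" alternative); overrides are merged recursively.
#'
#' @param ... Named nested overrides, e.g.
#'   `pipeline_config(design = list(seed = 7), qc = list(min_umi = 30))`.
#' @return A config list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  cfg <- default_config()
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips losslessly.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return [write_pipeline_config()]: `path`, invisibly;
#'   [read_pipeline_config()]: the configuration.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_abort <- function(stage, msg) {
  abort(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline on synthetic data
#'
#' Simulates the cohort, applies the QC cascade per sample, pools and tests
#' for differential expression, simulates per-sample barcoded alignments
#' with planted SNVs and runs the per-cell caller, then feeds the calls
#' through the bulk hard filters into the normalized burden comparison.
#' ASD samples carry extra planted variants so the one-sided burden
#' hypothesis is exercised end to end. All outputs, a manifest and a
#' summary JSON are written under `out_dir`; rerunning with the same
#' configuration reproduces the summary byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created).
#' @return Invisibly, a list with the in-memory stage results (`qc`,
#'   `deg`, `cellvar`, `burden`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()

  ## ---- simulate ----
  design <- do.call(cohort_design, config$design)
  ids <- design_gene_ids(design)
  nd <- config$deg$n_planted_degs
  planted_degs <- if (nd > 0) {
    cand <- setdiff(ids, c("PRM1L", "PRM2L"))[seq_len(nd)]
    purrr::map_dfr(seq_len(nd), function(i) {
      planted_deg(cand[i], config$deg$planted_lfc,
                  if (i %% 2 == 1) "up_in_asd" else "down_in_asd")
    })
  } else {
    NULL
  }
  sim <- simulate_count_matrices(design, planted_degs)
  ann <- simulate_annotation_popaf(design)

  ## ---- qc ----
  thresholds <- filter_thresholds(config$qc$min_umi,
                                  config$qc$min_genes_per_cell,
                                  config$qc$min_cells_per_gene,
                                  config$qc$max_pct_mito)
  qc <- purrr::map(sim$matrices, filter_cells_genes, thresholds = thresholds)
  filtered <- purrr::map(qc, "matrix")
  if (!is.null(config$qc$subsample)) {
    filtered <- purrr::imap(filtered, function(m, nm) {
      suppressWarnings(
        subsample_cells(m, config$qc$subsample,
                        seed = design$seed + 37L + match(nm, names(filtered))))
    })
  }
  removal_log <- purrr::imap_dfr(qc, function(q, nm) {
    q$removed |> mutate(sample_id = nm)
  })
  readr::write_tsv(removal_log, file.path(out_dir, "qc_removal_log.tsv"))
  intersections <- gene_set_intersections(filtered, sim$samples$cohort)
  summary$qc <- list(
    cells_in = purrr::map_int(sim$matrices, ~nrow(.x$counts)),
    cells_retained = purrr::map_int(filtered, ~nrow(.x$counts)),
    genes_retained = purrr::map_int(filtered, ~ncol(.x$counts)),
    common_genes = setNames(as.list(intersections$n_common_genes),
                            intersections$group)
  )

  ## ---- deg ----
  pooled <- pool_samples(filtered)
  if (nrow(pooled$matrix$counts) == 0) stage_abort("deg", "no cells survived QC")
  norm <- log_normalize(pooled$matrix, config$deg$scale_factor)
  labels <- sim$samples$cohort[match(pooled$cells$sample_id,
                                     sim$samples$sample_id)]
  deg <- wilcoxon_deg(norm, labels, group_a = "ASD",
                      min_fraction = config$deg$min_fraction)
  readr::write_tsv(deg, file.path(out_dir, "deg_table.tsv"))
  export_preranked(deg, file.path(out_dir, "deg_preranked.rnk"))
  asd_cells <- labels == "ASD"
  corr <- average_expression_correlation(
    structure(list(values = norm$values[asd_cells, , drop = FALSE],
                   scale_factor = norm$scale_factor, sample_id = "ASD"),
              class = "normalized_matrix"),
    structure(list(values = norm$values[!asd_cells, , drop = FALSE],
                   scale_factor = norm$scale_factor, sample_id = "Control"),
              class = "normalized_matrix"))
  summary$deg <- list(
    n_tested = nrow(deg),
    n_significant = sum(deg$adjusted_p < config$deg$alpha),
    mean_expression_r_squared = corr$r_squared
  )

  ## ---- cellvar + burden inputs per sample ----
  cv <- config$cellvar
  segs <- NULL
  reference <- ann$reference
  # deterministic shared + ASD-extra variant sites at exon interiors
  exon_sites <- ann$annotation$regions |>
    filter(.data$region == "exonic") |>
    mutate(site = (.data$start + .data$end) %/% 2L)
  n_sites <- cv$shared_variants + cv$asd_extra_variants
  if (nrow(exon_sites) < n_sites) stage_abort("cellvar", "too few exons for planted sites")
  sites <- exon_sites$site[seq_len(n_sites)]
  site_chrom <- exon_sites$chrom[seq_len(n_sites)]
  planted_all <- purrr::map_dfr(seq_len(n_sites), function(i) {
    ref <- ref_base_at(reference, site_chrom[i], sites[i])
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    planted_variant(site_chrom[i], sites[i], ref, alt, cv$carrier_fraction)
  })

  per_sample <- purrr::map(seq_len(nrow(sim$samples)), function(i) {
    is_asd <- sim$samples$cohort[i] == "ASD"
    planted <- if (is_asd) planted_all else
      planted_all[seq_len(cv$shared_variants), , drop = FALSE]
    al <- simulate_barcoded_alignments(
      design, planted,
      reads_per_cell = list(mean = cv$reads_per_cell_mean,
                            size = cv$reads_per_cell_size),
      n_cells = cv$n_cells, per_base_error = cv$per_base_error,
      seed = design$seed + 500009L + i * 101L)
    grp <- regroup_by_barcode(al$alignments, cv$min_reads_per_cell)
    pile <- build_pileups(grp$reads, reference, cv$min_base_quality)
    calls <- call_cell_variants(pile, reference, cv$error_rate,
                                cv$min_alt_reads_per_cell)
    kept <- filter_calls(calls, cv$min_qual, cv$min_cells, cv$stringent)
    list(sample_id = sim$samples$sample_id[i], calls = calls, kept = kept,
         n_reads = nrow(al$alignments), truth = al$truth)
  })
  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  purrr::walk(per_sample, function(s) {
    write_vcf(s$kept, file.path(vcf_dir, paste0(s$sample_id, ".vcf")),
              reference = reference,
              barcodes_path = file.path(vcf_dir,
                                        paste0(s$sample_id, "_barcodes.tsv")))
  })
  summary$cellvar <- list(
    calls_raw = purrr::map_int(per_sample, ~nrow(.x$calls)),
    calls_kept = purrr::map_int(per_sample, ~nrow(.x$kept)),
    sample_id = purrr::map_chr(per_sample, "sample_id")
  )

  ## ---- burden ----
  bu <- config$burden
  stats <- purrr::map(per_sample, function(s) {
    v <- s$kept |>
      mutate(alt_depth = .data$alt_reads) |>
      select("chrom", "pos", "ref", "alt", "alt_depth") |>
      arrange(.data$chrom, .data$pos)
    v <- snp_cluster_filter(v, bu$cluster_window, bu$min_cluster)
    v <- alt_depth_filter(v, bu$min_alt_depth)
    cls <- classify_regions(v, ann$annotation)
    rare <- rare_filter(cls$variants, ann$popaf, bu$max_af)
    sample_variant_stats(cls$variants, rare, s$sample_id,
                         reads_mapped = s$n_reads, read_size = bu$read_size,
                         chrom_lengths = ann$annotation$chrom_lengths) |>
      normalize_burden()
  })
  burden_tbl <- purrr::map_dfr(stats, function(s) {
    s$by_region |> mutate(sample_id = s$sample_id)
  })
  readr::write_tsv(burden_tbl |> mutate(log10_normalized =
                                          log10(.data$normalized)),
                   file.path(out_dir, "burden_by_region.tsv"))
  all_burden <- burden_tbl |> filter(.data$region == "all")
  cohorts <- sim$samples$cohort[match(all_burden$sample_id,
                                      sim$samples$sample_id)]
  test <- cohort_rank_test(all_burden$normalized[cohorts == "ASD"],
                           all_burden$normalized[cohorts == "Control"],
                           alternative = bu$alternative)
  summary$burden <- list(
    normalized_all = setNames(as.list(all_burden$normalized),
                              all_burden$sample_id),
    rank_sum_W = test$rank_sum_W, z = test$z,
    p_one_sided = test$p_one_sided, p_exact = test$p_exact
  )

  manifest <- list(package = "scsperm",
                   version = as.character(utils::packageVersion("scsperm")),
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, filtered = filtered, deg = deg,
                 cellvar = per_sample, burden = stats, test = test,
                 summary = summary))
}
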