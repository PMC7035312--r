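# Synthetic single-sperm data with planted truth. The generator emulates the
# study design — two "ASD" and four "Control" donors, sparse sperm-like
# expression dominated by a couple of protamine-like transcripts, a
# mitochondrial gene subset, and cell-barcoded single-end alignments on a
# small synthetic reference — so every downstream stage can be tested
# against known planted differential expression and planted SNVs.

#' Cohort design for the synthetic generator
#'
#' @param n_asd_samples,n_control_samples Samples per cohort (study design:
#'   2 vs 4).
#' @param barcodes_per_sample Cells per sample before QC.
#' @param genes Number of genes, including the mitochondrial subset.
#' @param mito_gene_fraction Fraction of genes that are mitochondrial
#'   (named `MT-*`).
#' @param seed Integer seed; the same design and seed always reproduce the
#'   same data, and no global random state is touched.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_asd_samples = 2, n_control_samples = 4,
                          barcodes_per_sample = 1500, genes = 300,
                          mito_gene_fraction = 0.1, seed = 1) {
  stopifnot(n_asd_samples >= 1, n_control_samples >= 1,
            barcodes_per_sample >= 1, genes >= 1,
            mito_gene_fraction >= 0, mito_gene_fraction <= 1)
  structure(list(n_asd_samples = as.integer(n_asd_samples),
                 n_control_samples = as.integer(n_control_samples),
                 barcodes_per_sample = as.integer(barcodes_per_sample),
                 genes = as.integer(genes),
                 mito_gene_fraction = mito_gene_fraction,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design> %d ASD + %d Control samples, %d barcodes x %d genes each (%.0f%% mito), seed %d\n",
              x$n_asd_samples, x$n_control_samples, x$barcodes_per_sample,
              x$genes, 100 * x$mito_gene_fraction, x$seed))
  invisible(x)
}

#' Gene identifiers implied by a design
#'
#' The first two genes are the protamine-like dominant transcripts
#' (`PRM1L`, `PRM2L`); mitochondrial genes are named `MT-###`.
#'
#' @param design A [cohort_design()].
#' @return Character vector of gene ids, length `design$genes`.
#' @export
design_gene_ids <- function(design) {
  n_mito <- round(design$genes * design$mito_gene_fraction)
  n_reg <- design$genes - n_mito
  reg <- c("PRM1L", "PRM2L", sprintf("GENE-%04d", seq_len(max(0, n_reg - 2))))
  reg <- reg[seq_len(n_reg)]
  c(reg, sprintf("MT-%03d", seq_len(n_mito)))
}

design_sample_sheet <- function(design) {
  tibble(
    sample_id = c(sprintf("ASD%d", seq_len(design$n_asd_samples)),
                  sprintf("Control%d", seq_len(design$n_control_samples))),
    cohort = rep(c("ASD", "Control"),
                 c(design$n_asd_samples, design$n_control_samples))
  )
}

#' A planted differentially expressed gene
#'
#' @param gene_id Gene identifier (must exist in the design).
#' @param log_fold_change Natural-log fold change magnitude (non-zero).
#' @param direction `"up_in_asd"` or `"down_in_asd"`.
#' @return One-row tibble usable as a row of the `planted` argument of
#'   [simulate_count_matrices()].
#' @export
planted_deg <- function(gene_id, log_fold_change,
                        direction = c("up_in_asd", "down_in_asd")) {
  direction <- match.arg(direction)
  if (log_fold_change == 0) abort("`log_fold_change` must be non-zero.")
  tibble(gene_id = gene_id, log_fold_change = log_fold_change,
         direction = direction)
}

# Relative gene abundance: the two protamine-like genes take a fixed large
# share of the non-mito mass, the rest follow a power-law tail; the
# mitochondrial subset takes `mito_gene_fraction` of total mass so a
# typical cell sits well below the 40% mito threshold.
gene_weights <- function(design) {
  ids <- design_gene_ids(design)
  is_mito <- startsWith(ids, "MT-")
  n_reg <- sum(!is_mito)
  w <- numeric(length(ids))
  if (n_reg > 0) {
    wr <- 1 / seq_len(n_reg)^1.3
    if (n_reg >= 1) wr[1] <- sum(wr) * 0.8          # PRM1L-like dominance
    if (n_reg >= 2) wr[2] <- sum(wr[-(1:2)]) * 1.5  # PRM2L-like
    w[!is_mito] <- wr / sum(wr) * (1 - design$mito_gene_fraction)
  }
  if (any(is_mito)) {
    wm <- 1 / seq_len(sum(is_mito))^0.5
    w[is_mito] <- wm / sum(wm) * design$mito_gene_fraction
  }
  setNames(w / sum(w), ids)
}

#' Simulate UMI count matrices for every sample
#'
#' Counts follow a zero-inflated negative binomial: per-cell expected depth
#' is log-normal (many cells below the 25-UMI QC floor, mirroring the
#' extreme sparsity of the ~50 fg of fragmented RNA in mature sperm), gene
#' means are `depth x weight`, a small subpopulation of cells has its
#' mitochondrial mass inflated past the 40% threshold, and planted DEGs
#' multiply the gene mean in ASD cells by `exp(+/- log_fold_change)` so the
#' cohort mean ratio equals the planted fold change exactly in expectation.
#'
#' @param design A [cohort_design()].
#' @param planted Tibble of planted DEGs ([planted_deg()] rows), or `NULL`.
#' @return A list: `matrices` (named list of [gene_barcode_matrix()], one
#'   per sample), `samples` (sample sheet with cohort labels), `truth`
#'   (the planted table with the applied ASD multiplier).
#' @export
simulate_count_matrices <- function(design, planted = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  ids <- design_gene_ids(design)
  if (!is.null(planted) && nrow(planted) > 0) {
    missing <- setdiff(planted$gene_id, ids)
    if (length(missing) > 0) {
      abort(sprintf("Planted gene '%s' is not in the design.", missing[1]))
    }
    if (any(planted$log_fold_change == 0)) {
      abort("Planted log fold changes must be non-zero.")
    }
  }
  w <- gene_weights(design)
  is_mito <- startsWith(ids, "MT-")
  samples <- design_sample_sheet(design)

  asd_mult <- setNames(rep(1, length(ids)), ids)
  if (!is.null(planted) && nrow(planted) > 0) {
    signed <- ifelse(planted$direction == "up_in_asd",
                     abs(planted$log_fold_change),
                     -abs(planted$log_fold_change))
    asd_mult[planted$gene_id] <- exp(signed)
  }

  matrices <- purrr::map(seq_len(nrow(samples)), function(i) {
    withr::with_seed(design$seed + i * 1009L, {
      n <- design$barcodes_per_sample
      depth <- rlnorm(n, meanlog = log(60), sdlog = 1.1)
      # ~6% of cells are mitochondria-dominated (degraded cells)
      high_mito <- runif(n) < 0.06
      wm <- matrix(w, nrow = n, ncol = length(ids), byrow = TRUE)
      wm[high_mito, is_mito] <- wm[high_mito, is_mito] * 12
      if (samples$cohort[i] == "ASD") {
        wm <- sweep(wm, 2, asd_mult, `*`)
      }
      mu <- depth * wm
      counts <- matrix(rnbinom(length(mu), mu = mu, size = 2),
                       nrow = n)
      dropout <- matrix(runif(length(mu)) < 0.2, nrow = n)
      counts[dropout] <- 0L
      dimnames(counts) <- list(sprintf("%s-BC%05d", samples$sample_id[i],
                                       seq_len(n)), ids)
      gene_barcode_matrix(counts, mito_mask = is_mito,
                          sample_id = samples$sample_id[i])
    })
  })
  names(matrices) <- samples$sample_id
  truth <- if (is.null(planted)) {
    tibble(gene_id = character(), log_fold_change = numeric(),
           direction = character(), asd_multiplier = numeric())
  } else {
    planted |> mutate(asd_multiplier = unname(asd_mult[.data$gene_id]))
  }
  list(matrices = matrices, samples = samples, truth = truth)
}

#' Synthetic reference genome for a design
#'
#' Three small chromosomes (two autosome analogues and one X analogue) of
#' i.i.d. bases, deterministic under the design seed.
#'
#' @param design A [cohort_design()].
#' @return Named character vector of chromosome sequences.
#' @export
synthetic_reference <- function(design) {
  lens <- c(chr1 = 40000L, chr2 = 30000L, chrX = 20000L)
  withr::with_seed(design$seed + 900007L, {
    vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  })
}

#' A planted single-nucleotide variant
#'
#' Sperm cells are haploid: a carrier cell carries the alternative allele at
#' the site, a non-carrier the reference allele, before sequencing error.
#'
#' @param chrom,pos Site (1-based).
#' @param ref,alt Reference and alternative base (`ref` must match the
#'   reference sequence; checked at generation).
#' @param carrier_cell_fraction Probability that a cell is a carrier
#'   (carriers are drawn per cell, so the realized carrier count is
#'   binomial).
#' @return One-row tibble for the `planted` argument of
#'   [simulate_barcoded_alignments()].
#' @export
planted_variant <- function(chrom, pos, ref, alt, carrier_cell_fraction) {
  if (ref == alt) abort("`ref` and `alt` must differ.")
  if (carrier_cell_fraction <= 0 || carrier_cell_fraction > 1) {
    abort("`carrier_cell_fraction` must be in (0, 1].")
  }
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
         carrier_cell_fraction = carrier_cell_fraction)
}

#' Simulate cell-barcoded single-end alignments with planted SNVs
#'
#' Each cell emits single-block 98-bp reads from a set of expressed
#' segments (transcript analogues). Every cell additionally anchors one
#' read across each planted site so carriers are always covered there. A
#' carrier cell's reads show the alternative base at the site with
#' probability `1 - per_base_error`; any other base of any read is
#' substituted (uniformly to one of the three other bases) with probability
#' `per_base_error`, so non-carriers show the alternative with probability
#' `per_base_error / 3`. Base qualities are constant Phred 37.
#'
#' @param design A [cohort_design()] (supplies the seed and reference).
#' @param planted Tibble of [planted_variant()] rows, or `NULL`.
#' @param reads_per_cell Either a single number (every cell gets exactly
#'   that many reads) or a list `list(mean =, size =)` for a negative
#'   binomial per-cell read count — the default
#'   `list(mean = 150, size = 5)` puts some cells below and some above the
#'   100-read floor.
#' @param n_cells Number of cells (default 300).
#' @param per_base_error Per-base substitution error probability (0 turns
#'   sequencing error off).
#' @param segments Expressed segments tibble (`chrom`, `start`, `end`);
#'   default: four 500-bp windows per chromosome.
#' @param read_length Read length in bp (default 98, the cDNA read).
#' @param seed Seed for this simulation; default derives one from the
#'   design seed. Pass distinct seeds to simulate several samples.
#' @return A list: `alignments` (tibble `qname`, `chrom`, `pos`, `seq`,
#'   `qual`, `barcode`), `truth` (tibble of carrier cells per variant),
#'   `reference`.
#' @export
simulate_barcoded_alignments <- function(design, planted = NULL,
                                         reads_per_cell = list(mean = 150, size = 5),
                                         n_cells = 300,
                                         per_base_error = 0.001,
                                         segments = NULL,
                                         read_length = 98,
                                         seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  seed <- seed %||% (design$seed + 500009L)
  if (per_base_error < 0 || per_base_error >= 0.5) {
    abort("`per_base_error` must be in [0, 0.5).")
  }
  reference <- synthetic_reference(design)
  if (is.null(segments)) {
    segments <- purrr::map_dfr(names(reference), function(ch) {
      L <- nchar(reference[[ch]])
      starts <- round(seq(0.1, 0.8, length.out = 4) * L)
      tibble(chrom = ch, start = as.integer(starts),
             end = as.integer(starts + 499L))
    })
  }
  if (!is.null(planted) && nrow(planted) > 0) {
    lim <- nchar(reference)[planted$chrom]
    if (anyNA(lim) || any(planted$pos < 1 | planted$pos > lim)) {
      abort("A planted variant lies outside the reference.")
    }
    ref_obs <- ref_base_at(reference, planted$chrom, planted$pos)
    if (any(ref_obs != planted$ref)) {
      abort("A planted variant's `ref` does not match the reference sequence.")
    }
    if (any(planted$ref == planted$alt)) abort("`ref` and `alt` must differ.")
  }

  withr::with_seed(seed, {
    barcodes <- sprintf("CB%06d", seq_len(n_cells))
    n_reads <- if (is.numeric(reads_per_cell) && length(reads_per_cell) == 1) {
      rep(as.integer(reads_per_cell), n_cells)
    } else {
      rnbinom(n_cells, mu = reads_per_cell$mean, size = reads_per_cell$size)
    }

    # carrier assignment per variant x cell
    truth <- if (is.null(planted) || nrow(planted) == 0) {
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), barcode = character())
    } else {
      purrr::map_dfr(seq_len(nrow(planted)), function(v) {
        carrier <- runif(n_cells) < planted$carrier_cell_fraction[v]
        tibble(chrom = planted$chrom[v], pos = planted$pos[v],
               ref = planted$ref[v], alt = planted$alt[v],
               barcode = barcodes[carrier])
      })
    }

    n_anchor <- if (is.null(planted)) 0L else nrow(planted)
    reads <- purrr::map_dfr(seq_len(n_cells), function(ci) {
      n_free <- max(0L, n_reads[ci] - n_anchor)
      seg_i <- sample.int(nrow(segments), n_free, replace = TRUE)
      free <- tibble(
        chrom = segments$chrom[seg_i],
        pos = segments$start[seg_i] +
          floor(runif(n_free) * (segments$end[seg_i] - segments$start[seg_i] -
                                   read_length + 2))
      )
      anchor <- if (n_anchor > 0) {
        tibble(
          chrom = planted$chrom,
          pos = pmax(1L, planted$pos - sample.int(read_length, n_anchor,
                                                  replace = TRUE) + 1L)
        )
      } else {
        tibble(chrom = character(), pos = numeric())
      }
      out <- bind_rows(anchor, free)
      out$pos <- as.integer(pmin(out$pos,
                                 nchar(reference)[out$chrom] - read_length + 1L))
      out$barcode <- barcodes[ci]
      out
    })
    reads$qname <- sprintf("read%07d", seq_len(nrow(reads)))
    reads$seq <- unname(substr(reference[reads$chrom], reads$pos,
                               reads$pos + read_length - 1L))

    # plant alternative alleles into carrier reads
    if (nrow(truth) > 0) {
      for (v in seq_len(nrow(planted))) {
        carriers <- truth$barcode[truth$chrom == planted$chrom[v] &
                                    truth$pos == planted$pos[v]]
        covers <- reads$chrom == planted$chrom[v] &
          reads$pos <= planted$pos[v] &
          reads$pos + read_length - 1L >= planted$pos[v] &
          reads$barcode %in% carriers
        off <- planted$pos[v] - reads$pos[covers] + 1L
        s <- reads$seq[covers]
        # substr<- does not recycle vector start positions; per read
        s <- vapply(seq_along(s), function(k) {
          x <- s[k]
          substr(x, off[k], off[k]) <- planted$alt[v]
          x
        }, character(1))
        reads$seq[covers] <- s
      }
    }

    # uniform per-base substitution error
    if (per_base_error > 0) {
      n_bases <- nrow(reads) * read_length
      n_err <- rbinom(1, n_bases, per_base_error)
      if (n_err > 0) {
        sites <- sample.int(n_bases, n_err)
        ri <- (sites - 1L) %/% read_length + 1L
        oi <- (sites - 1L) %% read_length + 1L
        for (k in seq_len(n_err)) {
          cur <- substr(reads$seq[ri[k]], oi[k], oi[k])
          sub <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          s <- reads$seq[ri[k]]
          substr(s, oi[k], oi[k]) <- sub
          reads$seq[ri[k]] <- s
        }
      }
    }
    reads$qual <- strrep(rawToChar(as.raw(37L + 33L)), read_length)

    list(alignments = reads |>
           select("qname", "chrom", "pos", "seq", "qual", "barcode") |>
           arrange(.data$chrom, .data$pos),
         truth = truth, reference = reference)
  })
}

#' Simulate the region annotation and population allele-frequency table
#'
#' Tiles every chromosome of the synthetic reference into
#' intergenic / gene blocks; each gene contributes three exons separated by
#' introns, with a CDS spanning the exons (strand alternating between
#' genes, GFF-style frames implied by cumulative length). Also draws a
#' population allele-frequency table in the spirit of a gnomAD extract:
#' some sites below the 0.001 rarity cutoff, some above, most of the genome
#' absent.
#'
#' @param design A [cohort_design()].
#' @param n_popaf Number of allele-frequency records to draw.
#' @return A list: `annotation` (a [region_annotation()]), `popaf` (tibble
#'   `chrom`, `pos`, `ref`, `alt`, `af`), `reference`.
#' @export
simulate_annotation_popaf <- function(design, n_popaf = 200) {
  stopifnot(inherits(design, "cohort_design"))
  reference <- synthetic_reference(design)
  chrom_lengths <- nchar(reference)

  exon_lens <- c(300L, 301L, 299L)  # total 900, divisible by 3
  intron_len <- 200L
  intergenic_len <- 1000L

  regions <- list(); cds <- list(); gi <- 0L
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    pos <- 1L
    while (pos + intergenic_len + sum(exon_lens) + 2L * intron_len <= L) {
      regions[[length(regions) + 1L]] <-
        tibble(chrom = ch, start = pos, end = pos + intergenic_len - 1L,
               region = "intergenic")
      pos <- pos + intergenic_len
      gi <- gi + 1L
      strand <- if (gi %% 2L == 1L) "+" else "-"
      cum <- 0L
      for (e in seq_along(exon_lens)) {
        regions[[length(regions) + 1L]] <-
          tibble(chrom = ch, start = pos, end = pos + exon_lens[e] - 1L,
                 region = "exonic")
        frame <- if (strand == "+") (3L - cum %% 3L) %% 3L else
          (3L - (sum(exon_lens) - cum - exon_lens[e]) %% 3L) %% 3L
        cds[[length(cds) + 1L]] <-
          tibble(chrom = ch, start = pos, end = pos + exon_lens[e] - 1L,
                 strand = strand, frame = frame,
                 cds_id = sprintf("CDS%03d", gi))
        cum <- cum + exon_lens[e]
        pos <- pos + exon_lens[e]
        if (e < length(exon_lens)) {
          regions[[length(regions) + 1L]] <-
            tibble(chrom = ch, start = pos, end = pos + intron_len - 1L,
                   region = "intronic")
          pos <- pos + intron_len
        }
      }
    }
    if (pos <= L) {
      regions[[length(regions) + 1L]] <-
        tibble(chrom = ch, start = pos, end = L, region = "intergenic")
    }
  }
  annotation <- region_annotation(bind_rows(regions), bind_rows(cds),
                                  chrom_lengths)

  popaf <- withr::with_seed(design$seed + 700001L, {
    ch <- sample(names(chrom_lengths), n_popaf, replace = TRUE)
    pos <- as.integer(floor(runif(n_popaf) * chrom_lengths[ch]) + 1L)
    ref <- ref_base_at(reference, ch, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    tibble(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
           af = 10^runif(n_popaf, -5, -0.5)) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      arrange(.data$chrom, .data$pos)
  })
  list(annotation = annotation, popaf = popaf, reference = reference)
}
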