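# Small fixtures built in code, shared across test files.

# A tiny dense matrix with known metrics; gene g3 is mitochondrial.
tiny_gbm <- function(sample_id = "S1") {
  m <- matrix(c(3, 0, 2,
                0, 0, 0,
                10, 20, 0,
                1, 1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("BC", 1:4), c("g1", "g2", "g3")))
  gene_barcode_matrix(m, mito_mask = c(FALSE, FALSE, TRUE),
                      sample_id = sample_id)
}

# Random sparse-ish matrix for oracle comparisons.
random_gbm <- function(n_cells = 30, n_genes = 12, seed = 42,
                       sample_id = "R1") {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, 1.2) *
                  (runif(n_cells * n_genes) < 0.5),
                nrow = n_cells,
                dimnames = list(sprintf("BC%03d", seq_len(n_cells)),
                                sprintf("g%02d", seq_len(n_genes))))
    mito <- seq_len(n_genes) > n_genes - 3
    gene_barcode_matrix(m, mito_mask = mito, sample_id = sample_id)
  })
}

# Hand-built alignment tibble: each row one single-block read.
make_reads <- function(chrom, pos, seq, barcode,
                       qual = strrep("F", nchar(seq))) {
  tibble::tibble(
    qname = sprintf("r%03d", seq_along(pos)),
    chrom = chrom, pos = as.integer(pos), seq = seq,
    qual = qual, barcode = barcode
  )
}

# A 60-bp two-chromosome reference with fixed sequence.
tiny_reference <- function() {
  c(c1 = paste(rep("ACGT", 15), collapse = ""),
    c2 = paste(rep("GGCA", 15), collapse = ""))
}

# Minimal annotation: one chromosome, exon 10..39 hosting a +strand CDS
# 13..39 (27 bp), flanked by intergenic and intronic blocks.
tiny_annotation <- function(len = 60) {
  regions <- tibble::tibble(
    chrom = "c1",
    start = c(1L, 10L, 40L, 50L),
    end = c(9L, 39L, 49L, len),
    region = c("intergenic", "exonic", "intronic", "intergenic")
  )
  cds <- tibble::tibble(chrom = "c1", start = 13L, end = 39L,
                        strand = "+", frame = 0L, cds_id = "CDSA")
  region_annotation(regions, cds, c(c1 = len))
}

# Independent dense per-cell metrics oracle.
metrics_oracle <- function(gbm) {
  m <- as.matrix(gbm$counts)
  out <- data.frame(barcode = rownames(m), n_umi = NA_integer_,
                    n_genes = NA_integer_, pct_mito = NA_real_)
  for (i in seq_len(nrow(m))) {
    tot <- sum(m[i, ])
    out$n_umi[i] <- tot
    out$n_genes[i] <- sum(m[i, ] > 0)
    out$pct_mito[i] <- if (tot > 0) 100 * sum(m[i, gbm$mito_mask]) / tot else 0
  }
  out
}
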