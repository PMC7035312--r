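# Readers and writers for the standard formats the pipeline touches:
# CellRanger-style MTX triplets, CB-tagged SAM, VCF, BED region annotations,
# population allele-frequency TSVs and FASTA references.

#' Read a CellRanger-style matrix triplet
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (optionally
#' `.gz`-compressed) in `dir`, with genes in MTX rows and barcodes in MTX
#' columns as CellRanger writes them; the result is transposed to the
#' package's barcodes-by-genes orientation. The mitochondrial mask is
#' derived from a gene-name prefix.
#'
#' @param dir Directory containing the triplet.
#' @param sample_id Sample name for the returned object.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @return A [gene_barcode_matrix()].
#' @export
read_matrix_triplet <- function(dir, sample_id = basename(dir),
                                mito_prefix = "MT-") {
  find1 <- function(stem) {
    for (f in file.path(dir, c(stem, paste0(stem, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    abort(sprintf("File '%s[.gz]' not found in '%s'.", stem, dir))
  }
  mtx <- find1("matrix.mtx")
  bc <- find1("barcodes.tsv")
  ft <- find1("features.tsv")
  m <- Matrix::readMM(if (endsWith(mtx, ".gz")) gzfile(mtx) else mtx)
  barcodes <- readr::read_lines(bc)
  features <- readr::read_tsv(ft, col_names = FALSE, col_types = readr::cols(.default = "c"))
  gene_ids <- features[[1]]
  gene_names <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes)) {
    abort(sprintf(
      "Dimension mismatch: matrix is %d x %d but '%s' has %d features and '%s' has %d barcodes.",
      nrow(m), ncol(m), basename(ft), length(gene_ids), basename(bc),
      length(barcodes)))
  }
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, gene_ids)
  gene_barcode_matrix(m, mito_mask = startsWith(gene_names, mito_prefix),
                      sample_id = sample_id)
}

#' Write a CellRanger-style matrix triplet
#'
#' @param gbm A [gene_barcode_matrix()].
#' @param dir Output directory (created if needed).
#' @param gzip Compress the three files.
#' @return `dir`, invisibly.
#' @export
write_matrix_triplet <- function(gbm, dir, gzip = FALSE) {
  stopifnot_gbm(gbm)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  mtx_plain <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(Matrix::t(gbm$counts), mtx_plain)
  if (gzip) {
    con <- gzfile(paste0(mtx_plain, ".gz"), "wb")
    writeLines(readLines(mtx_plain), con)
    close(con)
    unlink(mtx_plain)
  }
  readr::write_lines(barcodes_of(gbm), file.path(dir, paste0("barcodes.tsv", ext)))
  readr::write_tsv(
    tibble(id = genes_of(gbm), name = genes_of(gbm), type = "Gene Expression"),
    file.path(dir, paste0("features.tsv", ext)), col_names = FALSE)
  invisible(dir)
}

#' Write cell-barcoded alignments as SAM
#'
#' Single-end, single-block records with a `CB:Z` tag (omitted for untagged
#' reads), preceded by `@HD`/`@SQ` header lines. Records must already be
#' coordinate-sorted within chromosome (as the generator emits them).
#'
#' @param alignments Alignment tibble (`qname`, `chrom`, `pos`, `seq`,
#'   `qual`, `barcode`).
#' @param reference Named character vector or `DNAStringSet` (for `@SQ`
#'   lengths).
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_barcoded_sam <- function(alignments, reference, path) {
  reference <- as_reference_seqs(reference)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)))
  tag <- ifelse(is.na(alignments$barcode), "",
                paste0("\tCB:Z:", alignments$barcode))
  ord <- order(match(alignments$chrom, names(reference)), alignments$pos)
  a <- alignments[ord, , drop = FALSE]
  tag <- tag[ord]
  body <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s%s",
                  a$qname, a$chrom, a$pos, nchar(a$seq), a$seq, a$qual, tag)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read CB-tagged alignments from SAM or BAM
#'
#' SAM input is converted to BAM with \pkg{Rsamtools} and scanned with the
#' `CB` tag; reads without the tag get `NA` barcodes.
#'
#' @param path A `.sam` or `.bam` file.
#' @return Alignment tibble (`qname`, `chrom`, `pos`, `seq`, `qual`,
#'   `barcode`).
#' @export
read_barcoded_sam <- function(path) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq", "qual"), tag = "CB")
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  tibble(qname = r$qname, chrom = as.character(r$rname), pos = r$pos,
         seq = as.character(r$seq), qual = as.character(r$qual),
         barcode = as.character(r$tag$CB))
}

#' Write variant calls as VCF 4.2
#'
#' INFO carries `NCELLS` (supporting single cells) and `NCOV` (cells
#' covering the site) when present. A sidecar TSV of supporting barcodes
#' per variant is written when the calls carry a `supporting_barcodes`
#' list-column.
#'
#' @param calls Call tibble (at least `chrom`, `pos`, `ref`, `alt`,
#'   `qual`).
#' @param path Output `.vcf` path.
#' @param reference Optional reference for `##contig` header lines.
#' @param barcodes_path Optional path for the sidecar barcode TSV.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, reference = NULL, barcodes_path = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(reference)) {
      reference <- as_reference_seqs(reference)
      sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference))
    },
    '##INFO=<ID=NCELLS,Number=1,Type=Integer,Description="Supporting single cells">',
    '##INFO=<ID=NCOV,Number=1,Type=Integer,Description="Cells covering the site">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- if (all(c("supporting_cells", "total_cells_covered") %in% names(calls))) {
    sprintf("NCELLS=%d;NCOV=%d", calls$supporting_cells,
            calls$total_cells_covered)
  } else {
    rep(".", nrow(calls))
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt, calls$qual,
                  info)
  readr::write_lines(c(header, body), path)
  if (!is.null(barcodes_path) && "supporting_barcodes" %in% names(calls)) {
    sidecar <- purrr::map_dfr(seq_len(nrow(calls)), function(i) {
      tibble(chrom = calls$chrom[i], pos = calls$pos[i],
             barcode = unlist(calls$supporting_barcodes[[i]]) %||% character())
    })
    readr::write_tsv(sidecar, barcodes_path)
  }
  invisible(path)
}

#' Read variants from a VCF
#'
#' Extracts chrom/pos/ref/alt/qual plus the alternative-allele read depth:
#' from the second field of the first sample's `AD` (FORMAT) when present,
#' else from an `AD` or `NCELLS`-style INFO key is not attempted — calls
#' without depth get `NA`. Multi-allelic rows are split on the ALT comma
#' with the matching AD field.
#'
#' @param path A `.vcf` or `.vcf.gz` file.
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `qual`, `alt_depth`,
#'   `n_cells` (from INFO `NCELLS` when present).
#' @export
read_vcf_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), qual = numeric(), alt_depth = integer(),
                  n_cells = integer()))
  }
  alt_depth <- rep(NA_integer_, nrow(fix))
  if (nrow(v@gt) > 0 && "AD" %in% unlist(strsplit(v@gt[1, "FORMAT"], ":"))) {
    ad <- vcfR::extract.gt(v, element = "AD")[, 1]
    alt_depth <- suppressWarnings(
      as.integer(vapply(strsplit(ad, ","), function(x) x[2] %||% NA_character_,
                        character(1))))
  }
  nc <- suppressWarnings(
    as.integer(vcfR::extract.info(v, element = "NCELLS")))
  tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
         alt = fix$ALT, qual = suppressWarnings(as.numeric(fix$QUAL)),
         alt_depth = alt_depth,
         n_cells = if (length(nc) == nrow(fix)) nc else NA_integer_)
}

#' Write the region partition as BED
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so `start - 1` / `end` at the boundary. The region label goes in the
#' BED name column.
#'
#' @param annotation A [region_annotation()].
#' @param path Output `.bed` path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "region_annotation"))
  r <- annotation$regions
  readr::write_lines(sprintf("%s\t%d\t%d\t%s", r$chrom, r$start - 1L, r$end,
                             r$region), path)
  invisible(path)
}

#' Read a region partition from BED
#'
#' @param path BED file (chrom, 0-based start, end, region label).
#' @param chrom_lengths Named chromosome lengths (the partition is
#'   validated against them).
#' @param cds Optional CDS tibble to bundle into the annotation.
#' @return A [region_annotation()].
#' @export
read_regions_bed <- function(path, chrom_lengths, cds = tibble()) {
  b <- readr::read_tsv(path, col_names = c("chrom", "start0", "end", "region"),
                       col_types = "ciic")
  region_annotation(
    b |> mutate(start = .data$start0 + 1L) |>
      select("chrom", "start", "end", "region"),
    cds, chrom_lengths)
}

#' Read / write a population allele-frequency table
#'
#' Tab-separated `chrom`, `pos` (1-based), `ref`, `alt`, `af` — the shape
#' of a gnomAD site-frequency extract.
#'
#' @param path TSV path.
#' @return [read_popaf()]: the tibble; [write_popaf()]: `path`, invisibly.
#' @export
read_popaf <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", af = "d"))
}

#' @rdname read_popaf
#' @param popaf The allele-frequency tibble.
#' @export
write_popaf <- function(popaf, path) {
  readr::write_tsv(popaf, path)
  invisible(path)
}

#' Write / read the reference as FASTA
#'
#' @param reference Named character vector or `DNAStringSet`.
#' @param path FASTA path.
#' @return [write_reference_fasta()]: `path`, invisibly;
#'   [read_reference_fasta()]: named character vector.
#' @export
write_reference_fasta <- function(reference, path) {
  reference <- as_reference_seqs(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  as_reference_seqs(Biostrings::readDNAStringSet(path))
}
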