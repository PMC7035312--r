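# Per-cell SNV calling from cell-barcoded alignments. Sperm are haploid, so
# each cell carries exactly one allele per site; a transparent caller
# (majority base per cell, binomial-tail Phred site quality) replaces an
# external diploid caller and makes every number reproducible from the
# pileups alone.

as_reference_seqs <- function(reference) {
  if (is(reference, "DNAStringSet")) reference <- as.character(reference)
  if (!is.character(reference) || is.null(names(reference))) {
    abort("`reference` must be a named character vector or DNAStringSet.")
  }
  toupper(reference)
}

ref_base_at <- function(reference, chrom, pos) {
  reference <- as_reference_seqs(reference)
  bad <- !chrom %in% names(reference)
  if (any(bad)) abort(sprintf("Chromosome '%s' absent from the reference.", chrom[bad][1]))
  substr(reference[chrom], pos, pos) |> unname()
}

#' Regroup barcoded alignments by cell and drop low-read cells
#'
#' Reads carry their cell of origin in a `CB` barcode tag. This step tallies
#' reads per barcode, discards reads without a barcode, and removes every
#' cell with fewer than `min_reads_per_cell` reads (default 100; a cell with
#' exactly 100 reads is retained).
#'
#' @param alignments Alignment tibble, e.g. from [read_barcoded_sam()]:
#'   columns `chrom`, `pos` (1-based leftmost), `seq`, `qual`
#'   (Phred+33 string), `barcode` (`NA` when untagged).
#' @param min_reads_per_cell Read-count floor per cell.
#' @return A list: `reads` (alignments of retained cells), `cell_counts`
#'   (tibble `barcode`, `n_reads`, `retained`), `n_untagged` (reads
#'   discarded for missing barcode).
#' @export
regroup_by_barcode <- function(alignments, min_reads_per_cell = 100) {
  stopifnot(all(c("chrom", "pos", "seq", "qual", "barcode") %in% names(alignments)))
  tagged <- alignments[!is.na(alignments$barcode), , drop = FALSE]
  if (nrow(tagged) == 0) abort("No reads carry a CB barcode tag.")
  cell_counts <- tagged |>
    count(.data$barcode, name = "n_reads") |>
    mutate(retained = .data$n_reads >= min_reads_per_cell)
  keep <- cell_counts$barcode[cell_counts$retained]
  list(
    reads = tagged[tagged$barcode %in% keep, , drop = FALSE],
    cell_counts = cell_counts,
    n_untagged = nrow(alignments) - nrow(tagged)
  )
}

#' Build per-cell pileups from retained reads
#'
#' Expands every aligned base (contiguously aligned single-block reads) into
#' per-site, per-cell, per-base read counts, excluding bases whose Phred
#' quality is below `min_base_quality`.
#'
#' @param reads Alignment tibble (the `reads` element of
#'   [regroup_by_barcode()]).
#' @param reference Named character vector (or `DNAStringSet`) of chromosome
#'   sequences; alignments extending beyond a chromosome end are an error.
#' @param min_base_quality Phred floor for a base to be counted (default 13,
#'   about a 5% error probability).
#' @return A tibble `chrom`, `pos`, `barcode`, `base`, `n_reads`, one row
#'   per observed (site, cell, base) combination.
#' @export
build_pileups <- function(reads, reference, min_base_quality = 13) {
  reference <- as_reference_seqs(reference)
  if (nrow(reads) == 0) {
    return(tibble(chrom = character(), pos = integer(), barcode = character(),
                  base = character(), n_reads = integer()))
  }
  len <- nchar(reads$seq)
  if (any(nchar(reads$qual) != len)) {
    abort("Sequence and quality strings differ in length.")
  }
  ends <- reads$pos + len - 1L
  lim <- nchar(reference)[reads$chrom]
  if (anyNA(lim)) abort("Alignment chromosome absent from the reference.")
  if (any(ends > lim)) abort("Alignment extends beyond the reference end.")

  idx <- rep.int(seq_len(nrow(reads)), len)
  pos <- reads$pos[idx] + (sequence(len) - 1L)
  base <- strsplit(paste(reads$seq, collapse = ""), "", fixed = TRUE)[[1]]
  q <- utf8ToInt(paste(reads$qual, collapse = "")) - 33L

  ok <- q >= min_base_quality
  dt <- data.table::data.table(chrom = reads$chrom[idx][ok],
                               pos = as.integer(pos[ok]),
                               barcode = reads$barcode[idx][ok],
                               base = base[ok])
  cnt <- dt[, list(n_reads = .N), by = c("chrom", "pos", "barcode", "base")]
  data.table::setorder(cnt, chrom, pos, barcode, base)
  as_tibble(cnt)
}

#' Haploid per-cell variant calling
#'
#' A cell *supports* an alternative base at a site if it shows at least
#' `min_alt_reads_per_cell` reads of that base and the base is the cell's
#' unique majority base there (haploid cells carry one allele, so the
#' majority base is the cell's genotype). Each site with any non-reference
#' observation emits at most one call, for the alternative supported by the
#' most cells (ties broken by total alt reads, then alphabetically). Site
#' quality is the Phred-scaled binomial tail of seeing at least the observed
#' number of alt reads among all reads covering the site if every alt read
#' were a sequencing error to that specific base (probability
#' `error_rate / 3`), capped at `max_qual`.
#'
#' @param pileups Tibble from [build_pileups()].
#' @param reference Named character vector or `DNAStringSet`.
#' @param error_rate Per-base sequencing error probability (0 < e < 0.5).
#' @param min_alt_reads_per_cell Alt reads a cell needs to support a call.
#' @param max_qual Phred cap (the tail underflows to 0 when every read is
#'   alt and the error rate is tiny).
#' @return A tibble: `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `supporting_cells`, `total_cells_covered`, `alt_reads`, `total_reads`,
#'   and `supporting_barcodes` (list-column).
#' @export
call_cell_variants <- function(pileups, reference, error_rate = 0.001,
                               min_alt_reads_per_cell = 1, max_qual = 3000) {
  if (error_rate <= 0 || error_rate >= 0.5) {
    abort("`error_rate` must lie in (0, 0.5).")
  }
  reference <- as_reference_seqs(reference)
  if (nrow(pileups) == 0) return(empty_calls())
  p <- pileups |>
    arrange(.data$chrom, .data$pos, .data$barcode,
            desc(.data$n_reads), .data$base) |>
    mutate(ref = ref_base_at(reference, .data$chrom, .data$pos))

  # Vectorized (site, cell) genotyping on the sorted frame: the first row
  # of each (chrom, pos, barcode) run holds the cell's top base; a second
  # row with the same read count means a tie, i.e. no unique majority.
  cell_key <- paste(p$chrom, p$pos, p$barcode, sep = "\r")
  new_cell <- cell_key != c("", head(cell_key, -1))
  g <- cumsum(new_cell)
  top_base <- p$base[new_cell][g]
  next_in_cell <- c(!new_cell[-1], FALSE)
  next_n <- c(p$n_reads[-1], 0L)
  tie_at_first <- new_cell & next_in_cell & next_n == p$n_reads
  tie <- tie_at_first[new_cell][g]

  supports_row <- p$base != p$ref &
    p$n_reads >= min_alt_reads_per_cell &
    !tie & p$base == top_base

  alt_obs <- p |>
    mutate(supports = supports_row) |>
    filter(.data$base != .data$ref)
  if (nrow(alt_obs) == 0) return(empty_calls())

  site_key <- paste(p$chrom, p$pos, sep = "\r")
  site_reads <- rowsum(p$n_reads, site_key)
  site_cells <- rowsum(as.integer(new_cell), site_key)
  site_cov <- tibble(
    chrom = sub("\r.*", "", rownames(site_reads)),
    pos = as.integer(sub(".*\r", "", rownames(site_reads))),
    total_reads = as.integer(site_reads[, 1]),
    total_cells_covered = as.integer(site_cells[, 1])
  )

  per_alt <- alt_obs |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$base) |>
    summarise(
      supporting_cells = sum(.data$supports),
      alt_reads = sum(.data$n_reads),
      supporting_barcodes = list(sort(.data$barcode[.data$supports])),
      .groups = "drop"
    )

  best <- per_alt |>
    group_by(.data$chrom, .data$pos) |>
    arrange(desc(.data$supporting_cells), desc(.data$alt_reads), .data$base,
            .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    rename(alt = "base")

  best |>
    left_join(site_cov, by = c("chrom", "pos")) |>
    mutate(qual = pmin(
      max_qual,
      -10 * pbinom(.data$alt_reads - 1, .data$total_reads, error_rate / 3,
                   lower.tail = FALSE, log.p = TRUE) / log(10))) |>
    select("chrom", "pos", "ref", "alt", "qual", "supporting_cells",
           "total_cells_covered", "alt_reads", "total_reads",
           "supporting_barcodes") |>
    arrange(.data$chrom, .data$pos)
}

empty_calls <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), qual = numeric(), supporting_cells = integer(),
         total_cells_covered = integer(), alt_reads = integer(),
         total_reads = integer(), supporting_barcodes = list())
}

#' Quality and cell-support call filtering
#'
#' Keeps calls with `qual >= min_qual` and `supporting_cells >= min_cells`.
#' Defaults are quality 20 and 10 cells; `stringent = TRUE` raises the cell
#' floor to 100 to suppress residual false positives.
#'
#' @param calls Tibble from [call_cell_variants()].
#' @param min_qual Phred quality floor (strictly below is removed).
#' @param min_cells Minimum supporting single cells.
#' @param stringent Use the 100-cell stringent preset.
#' @return The retained calls.
#' @export
filter_calls <- function(calls, min_qual = 20, min_cells = 10,
                         stringent = FALSE) {
  if (stringent) min_cells <- 100
  calls |>
    filter(.data$qual >= min_qual, .data$supporting_cells >= min_cells)
}

#' Coding-consequence classification
#'
#' Labels each call by genomic region and, inside a coding sequence,
#' replaces the reference base in its codon (reverse-complementing on the
#' minus strand), translates both codons under the standard genetic code and
#' reports synonymous / non-synonymous.
#'
#' @param calls Variant tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param annotation A [region_annotation()] (regions partition + CDS table).
#' @param reference Named character vector or `DNAStringSet`.
#' @return The calls with columns `region`, `coding_effect`
#'   (`synonymous` / `non_synonymous` / `non_coding`), `ref_aa`, `alt_aa`.
#' @export
classify_consequence <- function(calls, annotation, reference) {
  reference <- as_reference_seqs(reference)
  stopifnot(inherits(annotation, "region_annotation"))
  validate_cds(annotation$cds, reference)
  labelled <- classify_regions(calls, annotation)$variants

  out <- labelled |>
    mutate(coding_effect = "non_coding", ref_aa = NA_character_,
           alt_aa = NA_character_)
  cds <- annotation$cds
  for (i in seq_len(nrow(out))) {
    hit <- cds |>
      filter(.data$chrom == out$chrom[i], .data$start <= out$pos[i],
             .data$end >= out$pos[i])
    if (nrow(hit) == 0) next
    eff <- codon_effect(out$chrom[i], out$pos[i], out$ref[i], out$alt[i],
                        cds[cds$cds_id == hit$cds_id[1], , drop = FALSE],
                        reference)
    out$coding_effect[i] <- eff$effect
    out$ref_aa[i] <- eff$ref_aa
    out$alt_aa[i] <- eff$alt_aa
  }
  out
}

# Mutate and translate the codon containing (chrom, pos) in one CDS. The
# CDS may span several intervals; its sense-strand sequence is the
# genomic-order concatenation (reverse-complemented for minus strand).
codon_effect <- function(chrom, pos, ref, alt, cds_intervals, reference) {
  cds_intervals <- cds_intervals |> arrange(.data$start)
  genomic <- paste(substr(rep(reference[chrom], nrow(cds_intervals)),
                          cds_intervals$start, cds_intervals$end),
                   collapse = "")
  if (nchar(genomic) %% 3 != 0) {
    abort(sprintf("CDS '%s' length %d is not divisible by 3.",
                  cds_intervals$cds_id[1], nchar(genomic)))
  }
  if (ref_base_at(reference, chrom, pos) != ref) {
    abort(sprintf("Reference mismatch at %s:%d (variant ref '%s').",
                  chrom, pos, ref))
  }
  strand <- cds_intervals$strand[1]
  # 1-based offset of pos along the genomic-order concatenation
  off <- 0L
  for (j in seq_len(nrow(cds_intervals))) {
    if (pos >= cds_intervals$start[j] && pos <= cds_intervals$end[j]) {
      off <- off + (pos - cds_intervals$start[j] + 1L)
      break
    }
    off <- off + (cds_intervals$end[j] - cds_intervals$start[j] + 1L)
  }
  sense <- genomic
  pos_in_cds <- off
  sense_alt <- alt
  if (strand == "-") {
    sense <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genomic)))
    pos_in_cds <- nchar(genomic) - off + 1L
    sense_alt <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  }
  codon_i <- (pos_in_cds - 1L) %/% 3L
  within <- (pos_in_cds - 1L) %% 3L + 1L
  codon <- substr(sense, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mutated <- codon
  substr(mutated, within, within) <- sense_alt
  ref_aa <- as.character(Biostrings::GENETIC_CODE[codon])
  alt_aa <- as.character(Biostrings::GENETIC_CODE[mutated])
  list(effect = if (identical(ref_aa, alt_aa)) "synonymous" else "non_synonymous",
       ref_aa = ref_aa, alt_aa = alt_aa)
}
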