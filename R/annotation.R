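#' Genomic region annotation with CDS intervals
#'
#' Bundles a region partition (every base of every chromosome labelled
#' exactly one of `exonic` / `intronic` / `intergenic`), a table of coding
#' sequences with strand and frame, and the chromosome lengths. All
#' coordinates are 1-based inclusive; BED input is converted at the
#' file-reading boundary.
#'
#' @param regions Tibble `chrom`, `start`, `end`, `region`; per chromosome
#'   the intervals must tile `[1, chrom_length]` without gaps or overlaps.
#' @param cds Tibble `chrom`, `start`, `end`, `strand` (`+`/`-`), `frame`
#'   (0/1/2 bases to skip to the first full codon), `cds_id`. A CDS may span
#'   several intervals sharing a `cds_id`.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(regions, cds, chrom_lengths) {
  stopifnot(all(c("chrom", "start", "end", "region") %in% names(regions)))
  if (!all(regions$region %in% c("exonic", "intronic", "intergenic"))) {
    abort("Region labels must be exonic, intronic or intergenic.")
  }
  regions <- regions |> arrange(.data$chrom, .data$start)
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, ]
    if (!ch %in% names(chrom_lengths)) {
      abort(sprintf("Chromosome '%s' has no length.", ch))
    }
    expected_starts <- c(1L, head(r$end, -1) + 1L)
    if (r$start[1] != 1L || r$end[nrow(r)] != chrom_lengths[[ch]] ||
        any(r$start != expected_starts)) {
      abort(sprintf("Regions do not tile chromosome '%s' exactly.", ch))
    }
  }
  if (nrow(cds) > 0) {
    stopifnot(all(c("chrom", "start", "end", "strand", "frame", "cds_id") %in% names(cds)))
    check_cds_frames(cds)
  }
  structure(list(regions = regions, cds = as_tibble(cds),
                 chrom_lengths = chrom_lengths),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat(sprintf("<region_annotation> %d chromosomes (%s bp), %d region intervals, %d CDS intervals\n",
              length(x$chrom_lengths), format(sum(x$chrom_lengths), big.mark = ","),
              nrow(x$regions), nrow(x$cds)))
  invisible(x)
}

# Overlapping CDS intervals on the same strand must imply the same codon
# phase at every shared base; check the leftmost shared base of each pair.
check_cds_frames <- function(cds) {
  phase_at <- function(row, p) {
    if (row$strand == "+") (p - row$start - row$frame) %% 3
    else (row$end - p - row$frame) %% 3
  }
  for (ch in unique(cds$chrom)) {
    cc <- cds[cds$chrom == ch, ]
    if (nrow(cc) < 2) next
    for (i in seq_len(nrow(cc) - 1)) {
      for (j in seq(i + 1, nrow(cc))) {
        if (cc$strand[i] != cc$strand[j]) next
        if (cc$cds_id[i] == cc$cds_id[j]) next
        lo <- max(cc$start[i], cc$start[j])
        hi <- min(cc$end[i], cc$end[j])
        if (lo > hi) next
        if (phase_at(cc[i, ], lo) != phase_at(cc[j, ], lo)) {
          abort(sprintf(
            "Overlapping CDS '%s' and '%s' on strand %s disagree on frame at %s:%d.",
            cc$cds_id[i], cc$cds_id[j], cc$strand[i], ch, lo))
        }
      }
    }
  }
  invisible(cds)
}

validate_cds <- function(cds, reference) {
  if (nrow(cds) == 0) return(invisible(cds))
  lens <- cds |>
    group_by(.data$cds_id) |>
    summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop")
  bad <- lens$cds_id[lens$len %% 3 != 0]
  if (length(bad) > 0) {
    abort(sprintf("CDS '%s' length is not divisible by 3.", bad[1]))
  }
  invisible(cds)
}
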