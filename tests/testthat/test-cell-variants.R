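test_that("barcode regrouping enforces the 100-read floor at its exact boundary", {
  reads <- make_reads(
    chrom = "c1",
    pos = rep(1, 99 + 100 + 3),
    seq = rep("ACGT", 202),
    barcode = c(rep("CELL99", 99), rep("CELL100", 100), rep(NA, 3))
  )
  grp <- regroup_by_barcode(reads, min_reads_per_cell = 100)
  expect_false("CELL99" %in% grp$reads$barcode)
  expect_true("CELL100" %in% grp$reads$barcode)
  expect_equal(grp$n_untagged, 3)
  # partition: dropped + retained + untagged = total
  n_dropped <- sum(grp$cell_counts$n_reads[!grp$cell_counts$retained])
  expect_equal(n_dropped + nrow(grp$reads) + grp$n_untagged, nrow(reads))

  expect_error(regroup_by_barcode(make_reads("c1", 1, "AC", NA_character_)),
               "CB")
})

test_that("per-barcode read counts equal a brute-force tally", {
  withr::with_seed(13, {
    bcs <- sample(c(sprintf("BC%d", 1:6), NA), 200, replace = TRUE)
  })
  reads <- make_reads("c1", rep(1, 200), rep("AAAA", 200), bcs)
  grp <- regroup_by_barcode(reads, min_reads_per_cell = 1)
  tally <- table(bcs[!is.na(bcs)])
  expect_equal(setNames(grp$cell_counts$n_reads, grp$cell_counts$barcode),
               setNames(as.integer(tally), names(tally))[grp$cell_counts$barcode])
})

test_that("pileups count bases per site and cell, honouring the quality floor", {
  ref <- tiny_reference()
  # single read A at pos 5 (reference c1[5] is irrelevant for counting)
  one <- make_reads("c1", 5, "A", "BC1")
  p <- build_pileups(one, ref, min_base_quality = 13)
  expect_equal(nrow(p), 1)
  expect_equal(p$pos, 5L)
  expect_equal(p$base, "A")
  expect_equal(p$n_reads, 1L)

  # second base below the floor is excluded: qual "!" is Phred 0
  low <- make_reads("c1", 5, "AC", "BC1", qual = "F!")
  p2 <- build_pileups(low, ref, min_base_quality = 13)
  expect_equal(p2$pos, 5L)

  expect_error(build_pileups(make_reads("c1", 59, "ACGT", "BC1"), ref),
               "beyond")
})

test_that("pileups equal a dense per-position loop on random alignments", {
  ref <- tiny_reference()
  withr::with_seed(17, {
    n <- 120
    chrom <- sample(names(ref), n, replace = TRUE)
    pos <- sample(1:50, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
    }, character(1))
    bcs <- sample(sprintf("BC%d", 1:5), n, replace = TRUE)
  })
  reads <- make_reads(chrom, pos, seqs, bcs)
  p <- build_pileups(reads, ref, min_base_quality = 0)

  oracle <- list()
  for (i in seq_len(nrow(reads))) {
    for (k in 1:8) {
      key <- paste(reads$chrom[i], reads$pos[i] + k - 1, reads$barcode[i],
                   substr(reads$seq[i], k, k))
      oracle[[key]] <- (oracle[[key]] %||% 0L) + 1L
    }
  }
  got <- setNames(p$n_reads, paste(p$chrom, p$pos, p$barcode, p$base))
  expect_equal(length(got), length(oracle))
  expect_equal(as.integer(got[names(oracle)]), as.integer(unlist(oracle)))
})

test_that("the haploid caller scores sites by the binomial-tail Phred formula", {
  ref <- c(c1 = strrep("A", 20))
  # 5 reads, all alt G at pos 10, one cell
  reads <- make_reads("c1", rep(10, 5), rep("G", 5), rep("BC1", 5))
  p <- build_pileups(reads, ref)
  calls <- call_cell_variants(p, ref, error_rate = 0.001)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt, "G")
  expect_equal(calls$supporting_cells, 1L)
  # k = n = 5 at error 0.001: -10*log10((0.001/3)^5)
  expect_equal(calls$qual, -10 * 5 * log10(0.001 / 3), tolerance = 1e-8)

  # the Phred cap engages when the tail underflows
  many <- make_reads("c1", rep(10, 400), rep("G", 400), rep("BC1", 400))
  capped <- call_cell_variants(build_pileups(many, ref), ref,
                               error_rate = 0.001)
  expect_equal(capped$qual, 3000)

  # no alternative observation, no call
  refonly <- make_reads("c1", rep(10, 5), rep("A", 5), rep("BC1", 5))
  expect_equal(nrow(call_cell_variants(build_pileups(refonly, ref), ref,
                                       error_rate = 0.001)), 0)
})

test_that("cell support requires the alt to be the cell's unique majority base", {
  ref <- c(c1 = strrep("A", 20))
  # BC1: 3 G vs 1 A -> supports; BC2: 1 G vs 3 A -> covers, no support;
  # BC3: 2 G vs 2 A tie -> no support
  reads <- dplyr::bind_rows(
    make_reads("c1", rep(10, 4), c("G", "G", "G", "A"), rep("BC1", 4)),
    make_reads("c1", rep(10, 4), c("G", "A", "A", "A"), rep("BC2", 4)),
    make_reads("c1", rep(10, 4), c("G", "G", "A", "A"), rep("BC3", 4))
  )
  calls <- call_cell_variants(build_pileups(reads, ref), ref,
                              error_rate = 0.01)
  expect_equal(calls$supporting_cells, 1L)
  expect_equal(calls$supporting_barcodes[[1]], "BC1")
  expect_equal(calls$total_cells_covered, 3L)
  expect_equal(calls$alt_reads, 6L)
  expect_equal(calls$total_reads, 12L)
})

test_that("call filtering applies the quality-20 and 10/100-cell rules at their boundaries", {
  mk <- function(qual, cells) {
    tibble::tibble(chrom = "c1", pos = 1L, ref = "A", alt = "G",
                   qual = qual, supporting_cells = cells,
                   total_cells_covered = cells + 5L)
  }
  expect_equal(nrow(filter_calls(mk(19.9, 50))), 0)
  expect_equal(nrow(filter_calls(mk(20, 50))), 1)
  expect_equal(nrow(filter_calls(mk(30, 9))), 0)
  expect_equal(nrow(filter_calls(mk(30, 10))), 1)
  expect_equal(nrow(filter_calls(mk(30, 99), stringent = TRUE)), 0)
  expect_equal(nrow(filter_calls(mk(30, 100), stringent = TRUE)), 1)
})

test_that("a planted variant is recovered with support equal to its retained carriers", {
  design <- cohort_design(seed = 3)
  ref <- synthetic_reference(design)
  rb <- substr(ref["chr1"], 4000, 4000)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  al <- simulate_barcoded_alignments(
    design, planted_variant("chr1", 4000, rb, alt, 0.15),
    reads_per_cell = list(mean = 130, size = 5), n_cells = 120,
    per_base_error = 0)
  grp <- regroup_by_barcode(al$alignments)
  calls <- call_cell_variants(build_pileups(grp$reads, ref), ref,
                              error_rate = 0.001)
  retained <- grp$cell_counts$barcode[grp$cell_counts$retained]
  retained_carriers <- intersect(al$truth$barcode, retained)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$supporting_cells, length(retained_carriers))
  expect_setequal(calls$supporting_barcodes[[1]], retained_carriers)
})

test_that("codon classification matches the standard genetic code on both strands", {
  # plus strand: CDS 13..39 on c1 = ACGT repeats; c1[13..15] = "ACGT..."[13..15]
  ann <- tiny_annotation()
  ref <- tiny_reference()
  # codon 1 of CDSA is bases 13-15: "ACG" (c1 = ACGTACGT...)
  # third position G -> A gives ACA: Thr -> Thr synonymous
  syn <- classify_consequence(
    tibble::tibble(chrom = "c1", pos = 15L, ref = "G", alt = "A"),
    ann, ref)
  expect_equal(syn$region, "exonic")
  expect_equal(syn$coding_effect, "synonymous")
  expect_equal(syn$ref_aa, "T")
  # second position C -> T gives ATG: Thr -> Met non-synonymous
  nonsyn <- classify_consequence(
    tibble::tibble(chrom = "c1", pos = 14L, ref = "C", alt = "T"),
    ann, ref)
  expect_equal(nonsyn$coding_effect, "non_synonymous")
  expect_equal(nonsyn$alt_aa, "M")

  # intronic and intergenic variants are non-coding
  intr <- classify_consequence(
    tibble::tibble(chrom = "c1", pos = 45L, ref = "A", alt = "G"), ann, ref)
  expect_equal(intr$region, "intronic")
  expect_equal(intr$coding_effect, "non_coding")

  # reference mismatch is an error
  expect_error(classify_consequence(
    tibble::tibble(chrom = "c1", pos = 15L, ref = "T", alt = "A"), ann, ref),
    "mismatch")
})

test_that("minus-strand classification equals the reverse-complement construct on plus", {
  # one 9-bp CDS, minus strand, on a fixed sequence
  seq_fwd <- "TTTAGCCATGGCATTTAGC"       # length 19; CDS at 6..14
  ref_minus <- c(cm = seq_fwd)
  regions <- tibble::tibble(chrom = "cm", start = c(1L, 6L, 15L),
                            end = c(5L, 14L, 19L),
                            region = c("intergenic", "exonic", "intergenic"))
  cds_minus <- tibble::tibble(chrom = "cm", start = 6L, end = 14L,
                              strand = "-", frame = 0L, cds_id = "M1")
  ann_minus <- region_annotation(regions, cds_minus, c(cm = 19L))

  # the same construct reverse-complemented, CDS on plus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
  ref_plus <- c(cp = rc)
  cds_plus <- tibble::tibble(chrom = "cp", start = 6L, end = 14L,
                             strand = "+", frame = 0L, cds_id = "P1")
  regions_plus <- regions |> dplyr::mutate(chrom = "cp")
  ann_plus <- region_annotation(regions_plus, cds_plus, c(cp = 19L))

  for (pos in 6:14) {
    ref_b <- substr(seq_fwd, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref_b)) {
      res_m <- classify_consequence(
        tibble::tibble(chrom = "cm", pos = pos, ref = ref_b, alt = alt),
        ann_minus, ref_minus)
      mirror_pos <- 19L - pos + 1L
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      res_p <- classify_consequence(
        tibble::tibble(chrom = "cp", pos = mirror_pos,
                       ref = comp[[ref_b]], alt = comp[[alt]]),
        ann_plus, ref_plus)
      expect_equal(res_m$coding_effect, res_p$coding_effect)
      expect_equal(res_m$ref_aa, res_p$ref_aa)
      expect_equal(res_m$alt_aa, res_p$alt_aa)
    }
  }
})

test_that("random CDS variants agree with a whole-protein translation oracle", {
  translate_oracle <- function(cds_seq) {
    as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                       no.init.codon = TRUE))
  }
  withr::with_seed(23, {
    for (rep in 1:6) {
      L <- sample(c(9L, 12L, 15L), 1)
      cds_seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = "")
      flank <- 4L
      full <- paste0(strrep("A", flank), cds_seq, strrep("A", flank))
      strand <- sample(c("+", "-"), 1)
      genome_seq <- if (strand == "+") full else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(full)))
      total <- nchar(genome_seq)
      ref <- setNames(genome_seq, "cz")
      regions <- tibble::tibble(chrom = "cz",
                                start = c(1L, flank + 1L, flank + L + 1L),
                                end = c(flank, flank + L, total),
                                region = c("intergenic", "exonic", "intergenic"))
      cds <- tibble::tibble(chrom = "cz", start = flank + 1L,
                            end = flank + L, strand = strand, frame = 0L,
                            cds_id = "Z")
      ann <- region_annotation(regions, cds, c(cz = total))

      pos <- sample((flank + 1L):(flank + L), 1)
      ref_b <- substr(genome_seq, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1)
      res <- classify_consequence(
        tibble::tibble(chrom = "cz", pos = pos, ref = ref_b, alt = alt),
        ann, ref)

      # oracle: translate the full CDS before and after the genomic edit
      mutated_genome <- genome_seq
      substr(mutated_genome, pos, pos) <- alt
      get_cds <- function(g) {
        s <- substr(g, flank + 1L, flank + L)
        if (strand == "-") {
          s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        }
        s
      }
      prot_before <- translate_oracle(get_cds(genome_seq))
      prot_after <- translate_oracle(get_cds(mutated_genome))
      expect_equal(res$coding_effect,
                   if (prot_before == prot_after) "synonymous" else "non_synonymous")
      diff_at <- which(strsplit(prot_before, "")[[1]] != strsplit(prot_after, "")[[1]])
      if (length(diff_at) == 1) {
        expect_equal(res$alt_aa, substr(prot_after, diff_at, diff_at))
      }
    }
  })
})

test_that("a CDS whose length is not a multiple of three is rejected", {
  regions <- tibble::tibble(chrom = "c1", start = c(1L, 10L, 20L),
                            end = c(9L, 19L, 60L),
                            region = c("intergenic", "exonic", "intergenic"))
  cds <- tibble::tibble(chrom = "c1", start = 10L, end = 17L,  # 8 bp
                        strand = "+", frame = 0L, cds_id = "BAD")
  ann <- region_annotation(regions, cds, c(c1 = 60L))
  expect_error(classify_consequence(
    tibble::tibble(chrom = "c1", pos = 12L, ref = substr(tiny_reference()["c1"], 12, 12),
                   alt = "A"), ann, tiny_reference()),
    "divisible by 3")
})
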