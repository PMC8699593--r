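# Coordinate arithmetic, strand handling and batch annotation, cross-checked
# against the full-CDS translation oracle in helper-fixtures.R.

test_that("codon_range arithmetic on a plus-strand single-CDS gene", {
  toy <- toy_plus_gene()
  # CDS 101-160, phase 0: position 107 starts codon 3
  cr <- codon_range(107L, toy$model)
  expect_equal(cr$positions, 107:109)
  expect_equal(cr$ranges, data.frame(start = 107L, end = 109L))
  expect_equal(cr$offset, 1L)
  expect_equal(cr$protein_position, 3L)
  # position 103 is the third base of codon 1
  cr2 <- codon_range(103L, toy$model)
  expect_equal(cr2$positions, 101:103)
  expect_equal(cr2$offset, 3L)
  expect_equal(cr2$protein_position, 1L)
  # outside the CDS -> classed noncoding condition
  expect_error(codon_range(50L, toy$model), class = "argskew_noncoding")
  expect_error(codon_range(161L, toy$model), class = "argskew_noncoding")
})

test_that("phase shifts the codon frame and routes overhang bases noncoding", {
  toy <- toy_plus_gene()
  shifted <- gene_model("TOY", "chr1", "+", 101L, 160L, phase = 2L)
  # the first two CDS bases precede the first complete codon
  expect_error(codon_range(101L, shifted), class = "argskew_noncoding")
  expect_error(codon_range(102L, shifted), class = "argskew_noncoding")
  cr <- codon_range(103L, shifted)
  expect_equal(cr$positions, 103:105)
  expect_equal(cr$protein_position, 1L)
  # trailing partial codon (58 usable bases -> 19 codons, 1 leftover)
  expect_error(codon_range(160L, shifted), class = "argskew_noncoding")
})

test_that("fetch_codon reads in translation order and honors strand", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTAGTT"))
  expect_equal(fetch_codon(ref, "chr1", 3:5, "+"), "CGT")
  # minus strand: positions given in translation order (descending)
  expect_equal(fetch_codon(ref, "chr1", 5:3, "-"), "ACG")
  # round trip: reading the mirrored positions on the revcomp genome
  rc <- Biostrings::DNAStringSet(c(
    chr1 = as.character(Biostrings::reverseComplement(ref[[1]]))))
  L <- 9L
  expect_equal(fetch_codon(rc, "chr1", L - (3:5) + 1L, "-"),
               fetch_codon(ref, "chr1", 3:5, "+"))
  expect_error(fetch_codon(ref, "chr1", 8:10, "+"), "bounds")
  expect_error(fetch_codon(ref, "chr2", 3:5, "+"), "not in reference")
})

test_that("annotate_record reproduces the canonical CGA>CAA glutamine event", {
  # gene whose 4th codon is CGA
  cds <- paste0("ATGAAA", "CCC", "CGA", "GGGTTT")
  toy <- toy_plus_gene(cds = cds)
  pos <- toy$cds_start + 10L  # middle base (G) of the CGA codon
  rec <- data.frame(gene_symbol = "TOY", sample_id = "S1",
                    chromosome = "chr1", position = pos,
                    wt_allele = "G", mut_allele = "A",
                    stringsAsFactors = FALSE)
  ann <- annotate_record(rec, toy$reference, toy$models)
  expect_equal(ann$ref_codon, "CGA")
  expect_equal(ann$alt_codon, "CAA")
  expect_equal(ann$ref_aa, "R")
  expect_equal(ann$alt_aa, "Q")
  expect_equal(ann$functional_class, "missense")
  expect_equal(ann$protein_position, 4L)
  expect_true(ann$is_transition)
})

test_that("a minus-strand gene with plus-strand triplet TCG mirrors the CGA event", {
  # plus strand: pad(6) TCG TTT CAT pad; gene on minus strand, CDS = revcomp
  # of the plus segment; revcomp(TCG) = CGA is the LAST codon in translation
  # order, so prepend codons to keep it in frame. Layout (plus strand):
  # [ATGCAT][TCG] = revcomp CDS of CGA-ATG-CAT... build explicitly:
  cds_translation_order <- c("ATG", "CCC", "CGA")  # minus-strand CDS
  cds <- paste(cds_translation_order, collapse = "")
  plus_segment <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cds)))  # "TCGGGGCAT"
  expect_equal(substr(plus_segment, 1, 3), "TCG")
  chrom <- paste0("AAAAAA", plus_segment, "AAAAAA")
  ref <- Biostrings::DNAStringSet(c(chr1 = chrom))
  model <- gene_model("MIR", "chr1", "-", 7L, 7L + 8L)
  # CGA sits at plus positions 7-9 (TCG); its middle genomic base is C;
  # plus-strand C>T is coding-strand G>A at codon position 2 -> CAA
  rec <- data.frame(gene_symbol = "MIR", sample_id = "S1",
                    chromosome = "chr1", position = 8L,
                    wt_allele = "C", mut_allele = "T",
                    stringsAsFactors = FALSE)
  ann <- annotate_record(rec, ref, list(MIR = model))
  expect_equal(ann$ref_codon, "CGA")
  expect_equal(ann$alt_codon, "CAA")
  expect_equal(ann$alt_aa, "Q")
  expect_equal(ann$protein_position, 3L)
  expect_equal(ann$codon_pos, 2L)
})

test_that("codons spanning an intron are mapped as two sub-ranges and annotated correctly", {
  # exon1 = ATG CCC C | intron(10) | exon2 = GA GGG TTT ; codon 3 = CGA
  exon1 <- "ATGCCCC"
  intron <- "GTAAAAAAAG"
  exon2 <- "GAGGGTTT"
  chrom <- paste0(strrep("A", 20), exon1, intron, exon2, strrep("A", 20))
  ref <- Biostrings::DNAStringSet(c(chr1 = chrom))
  e1s <- 21L; e1e <- e1s + nchar(exon1) - 1L
  e2s <- e1e + nchar(intron) + 1L; e2e <- e2s + nchar(exon2) - 1L
  model <- gene_model("SPL", "chr1", "+", c(e1s, e2s), c(e1e, e2e))
  cr <- codon_range(e1e, model)  # the C just before the intron
  expect_equal(nrow(cr$ranges), 2)
  expect_equal(cr$positions, c(e1e, e2s, e2s + 1L))
  expect_equal(cr$protein_position, 3L)
  # mutate the first base of the split codon: CGA -> TGA (nonsense)
  rec <- data.frame(gene_symbol = "SPL", sample_id = "S1",
                    chromosome = "chr1", position = e1e,
                    wt_allele = "C", mut_allele = "T",
                    stringsAsFactors = FALSE)
  ann <- annotate_record(rec, ref, list(SPL = model))
  expect_equal(ann$ref_codon, "CGA")
  expect_equal(ann$alt_codon, "TGA")
  expect_equal(ann$functional_class, "nonsense")
  # matches the full-CDS translation oracle
  ora <- oracle_event(chrom, list(starts = c(e1s, e2s), ends = c(e1e, e2e),
                                  strand = "+", phase = 0L), e1e, "T")
  expect_equal(ann$protein_position, ora$protein_position)
  expect_equal(ann$alt_aa, ora$alt_aa)
})

test_that("record streams are exhaustive: annotated + noncoding + mismatched = input", {
  toy <- toy_plus_gene()
  recs <- data.frame(
    gene_symbol = c("TOY", "TOY", "TOY", "GHOST", "TOY"),
    sample_id = paste0("S", 1:5),
    chromosome = c("chr1", "chr1", "chr1", "chr1", "chr9"),
    position = c(110L, 50L, 115L, 120L, 110L),
    wt_allele = c(substr(toy$cds, 10, 10), "A", "N", "A", "A"),
    mut_allele = c("A", "C", "A", "G", "G"),
    stringsAsFactors = FALSE
  )
  # make record 1 a real mutation (wt matches reference), 3 a mismatch
  ref15 <- substr(toy$cds, 15, 15)
  recs$wt_allele[3] <- setdiff(c("C", "G"), ref15)[1]  # wrong vs reference
  recs$mut_allele[3] <- setdiff(c("A", "T"), recs$wt_allele[3])[1]
  recs$mut_allele[1] <- setdiff(c("A", "C"), recs$wt_allele[1])[1]
  res <- NULL
  expect_warning(res <- annotate_mutations(recs, toy$reference, toy$models),
                 "does not match")
  expect_equal(unname(res$counts["input"]), 5L)
  expect_equal(unname(res$counts["annotated"] + res$counts["noncoding"] +
                        res$counts["mismatched"]), 5L)
  expect_equal(res$counts[["mismatched"]], 1L)
  expect_setequal(res$noncoding$reason,
                  c("outside_cds", "no_gene_model", "wrong_chromosome"))
})

test_that("protein-change strings are checked and discordances flagged", {
  cds <- paste0("ATGAAA", "CGA", "GGGTTT")
  toy <- toy_plus_gene(cds = cds)
  pos <- toy$cds_start + 7L  # middle of CGA, protein position 3
  recs <- data.frame(
    gene_symbol = "TOY", sample_id = c("S1", "S2"), chromosome = "chr1",
    position = pos, wt_allele = "G", mut_allele = "A",
    mutation_aa = c("p.R3Q", "p.R3H"),  # second is wrong
    stringsAsFactors = FALSE
  )
  res <- annotate_mutations(recs, toy$reference, toy$models)
  expect_equal(res$annotated$discordant, c(FALSE, TRUE))
})

test_that("strand mirror: the same gene on the revcomp genome yields identical events", {
  set.seed(11)
  toy <- toy_plus_gene()
  chrom <- as.character(toy$reference[[1]])
  L <- nchar(chrom)
  rc_ref <- Biostrings::DNAStringSet(c(
    chr1 = as.character(Biostrings::reverseComplement(toy$reference[[1]]))))
  mir_model <- gene_model("TOY", "chr1", "-",
                          L - (toy$cds_start + nchar(toy$cds) - 1L) + 1L,
                          L - toy$cds_start + 1L)
  for (i in 1:20) {
    pos <- sample(seq(toy$cds_start, toy$cds_start + nchar(toy$cds) - 1L), 1)
    wt <- substr(chrom, pos, pos)
    mut <- sample(setdiff(c("A", "C", "G", "T"), wt), 1)
    rec <- data.frame(gene_symbol = "TOY", sample_id = "S1",
                      chromosome = "chr1", position = pos,
                      wt_allele = wt, mut_allele = mut,
                      stringsAsFactors = FALSE)
    mir <- rec
    mir$position <- L - pos + 1L
    mir$wt_allele <- complement_bases(wt)
    mir$mut_allele <- complement_bases(mut)
    a <- annotate_record(rec, toy$reference, toy$models)
    b <- annotate_record(mir, rc_ref, list(TOY = mir_model))
    cols <- c("ref_codon", "alt_codon", "codon_pos", "ref_aa", "alt_aa",
              "functional_class", "protein_position")
    expect_equal(a[, cols], b[, cols])
  }
})

test_that("annotation equals the full-CDS translation oracle on simulated genes", {
  cfg <- simulation_config(n_genes = 12, codons_per_gene = 25,
                           fraction_minus_strand = 0.5,
                           intron_fraction = 0.5, n_samples = 40,
                           mutations_per_sample = 8,
                           noncoding_fraction = 0, seed = 303)
  ref <- generate_reference(cfg)
  study <- simulate_mutations(ref, cfg)
  res <- annotate_mutations(study$records, ref$reference, ref$models)
  expect_equal(res$counts[["mismatched"]], 0L)
  chrom <- as.character(ref$reference[[1]])
  ann <- res$annotated
  for (i in seq_len(nrow(ann))) {
    model <- ref$models[[ann$gene_symbol[i]]]
    iv <- model$intervals
    ora <- oracle_event(chrom,
                        list(starts = iv$start, ends = iv$end,
                             strand = model$strand, phase = model$phase),
                        ann$position[i], ann$mut_allele[i])
    if (ora$silent) {
      expect_equal(ann$functional_class[i], "synonymous")
      expect_equal(ora$wt[ann$protein_position[i]], ann$ref_aa[i])
    } else {
      expect_equal(ann$protein_position[i], ora$protein_position)
      expect_equal(ann$ref_aa[i], ora$ref_aa)
      expect_equal(ann$alt_aa[i], ora$alt_aa)
    }
  }
})

test_that("mutation CSV writing and reading round-trips", {
  cfg <- simulation_config(n_genes = 4, codons_per_gene = 20, n_samples = 10,
                           mutations_per_sample = 5, seed = 9)
  res <- simulate_study(cfg, dir = withr::local_tempdir())
  back <- read_mutations(res$paths[["csv"]])
  expect_equal(back, res$study$records, ignore_attr = TRUE)
})

test_that("deduplication keys on sample, chromosome, position and alt allele", {
  df <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2"), chromosome = "chr1",
    position = c(10L, 10L, 10L, 10L),
    mut_allele = c("A", "A", "T", "A"), stringsAsFactors = FALSE
  )
  expect_equal(nrow(deduplicate_records(df)), 3)
})
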