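# Simulator: determinism, construction invariants, usage recovery, skew
# injection guarantees, and end-to-end identity against the manifest.

small_cfg <- function(seed, ...) {
  simulation_config(n_genes = 8, codons_per_gene = 30, n_samples = 40,
                    mutations_per_sample = 8, seed = seed, ...)
}

test_that("identical seed and config give byte-identical artifacts", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- simulate_study(small_cfg(17), dir = d1)
  r2 <- simulate_study(small_cfg(17), dir = d2)
  for (f in c("reference.fa", "genes.gff3", "mutations.csv",
              "manifest.json")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  # a different seed changes the mutation table
  r3 <- simulate_study(small_cfg(18))
  expect_false(identical(r1$study$records, r3$study$records))
})

test_that("gene construction invariants hold", {
  cfg <- simulation_config(n_genes = 12, codons_per_gene = 40,
                           fraction_minus_strand = 0.5,
                           intron_fraction = 0.4, n_samples = 10,
                           mutations_per_sample = 2, seed = 4)
  ref <- generate_reference(cfg)
  # CDS lengths divisible by 3 (including the stop codon)
  for (m in ref$models) {
    expect_equal(m$cds_length %% 3L, 0L)
  }
  # stated strand mix and at least one intron gene
  expect_equal(sum(ref$genes$strand == "-"), 6)
  expect_gte(sum(ref$genes$has_intron), 1)
  # an intron gene has a codon spanning the boundary (two sub-ranges)
  g <- ref$genes$gene[ref$genes$has_intron][1]
  model <- ref$models[[g]]
  iv <- model$intervals
  boundary_pos <- if (model$strand == "+") iv$end[1] else iv$start[1]
  cr <- codon_range(boundary_pos, model)
  expect_equal(nrow(cr$ranges), 2)
  # site index agrees with the written FASTA
  d <- withr::local_tempdir()
  write_reference(ref, file.path(d, "ref.fa"), file.path(d, "genes.gff3"))
  fa <- read_reference(file.path(d, "ref.fa"))
  chrom <- as.character(fa[[1]])
  expect_equal(substring(chrom, ref$sites$gpos, ref$sites$gpos),
               ref$sites$plus_base)
  # and the GFF3 round-trips into equivalent models
  models2 <- read_gene_models(file.path(d, "genes.gff3"))
  for (g in names(ref$models)) {
    expect_equal(models2[[g]]$intervals, ref$models[[g]]$intervals,
                 label = g)
    expect_equal(models2[[g]]$strand, ref$models[[g]]$strand)
    expect_equal(models2[[g]]$phase, ref$models[[g]]$phase)
  }
})

test_that("all genes go plus-strand when fraction_minus_strand is 0", {
  cfg <- small_cfg(5, fraction_minus_strand = 0)
  ref <- generate_reference(cfg)
  expect_true(all(ref$genes$strand == "+"))
  d <- withr::local_tempdir()
  write_reference(ref, file.path(d, "r.fa"), file.path(d, "g.gff3"))
  gff <- readLines(file.path(d, "g.gff3"))
  cds <- gff[grepl("\tCDS\t", gff)]
  expect_true(all(vapply(strsplit(cds, "\t"), `[`, "", 7) == "+"))
})

test_that("emitted arginine codons follow the usage weights within 3 SE", {
  cfg <- simulation_config(n_genes = 10, codons_per_gene = 1000,
                           arg_codon_fraction = 0.08, n_samples = 10,
                           mutations_per_sample = 2, seed = 23)
  ref <- generate_reference(cfg)
  arg_sites <- ref$sites[ref$sites$codon %in% ARGININE_CODONS &
                           ref$sites$offset == 1L, ]
  n <- nrow(arg_sites)
  expect_gt(n, 500)  # ~800 expected from 10,000 codons at 8%
  usage <- default_arginine_usage()
  obs <- table(factor(arg_sites$codon, levels = names(usage)))
  for (cd in names(usage)) {
    p <- usage[[cd]]
    expect_lt(abs(100 * obs[[cd]] / n - 100 * p), 3 * binom_se_pct(p, n))
  }
})

test_that("every emitted record matches the reference base at its position", {
  res <- simulate_study(small_cfg(29), dir = withr::local_tempdir())
  fa <- read_reference(res$paths[["fasta"]])
  chrom <- as.character(fa[[1]])
  recs <- res$study$records
  expect_equal(substring(chrom, recs$position, recs$position),
               recs$wt_allele)
  # hence zero reference mismatches downstream
  ann <- annotate_mutations(recs, fa, read_gene_models(res$paths[["gff3"]]))
  expect_equal(ann$counts[["mismatched"]], 0L)
})

test_that("a point-mass C>T signature only emits C>T (plus strand)", {
  sig <- setNames(rep(0, 12), BASE_CHANGES_12)
  sig["C>T"] <- 1
  cfg <- small_cfg(31, signature = sig, noncoding_fraction = 0.3)
  study <- simulate_study(cfg)$study
  bg <- study$truth[study$truth$provenance == "background", ]
  expect_true(all(bg$wt_allele == "C" & bg$mut_allele == "T"))
  # on minus-strand genes that change reads G>A on the coding strand
  minus <- bg[bg$gene_strand == "-" & bg$functional_class != "noncoding", ]
  if (nrow(minus)) {
    sp <- base_change_spectrum(minus, "coding", split12 = TRUE)
    expect_equal(sp$count[sp$category == "G>A"], nrow(minus))
  }
})

test_that("skew injection honors fraction and carrier guarantees", {
  cfg <- simulation_config(
    n_genes = 10, codons_per_gene = 60, arg_codon_fraction = 0.2,
    n_samples = 100, mutations_per_sample = 10, seed = 41,
    skew_specs = list(skew_spec("GENE002", "Q", 0.7, 30)))
  study <- simulate_study(cfg)$study
  sk <- study$manifest$skewed_genes
  expect_equal(sk$gene, "GENE002")
  expect_gte(sk$realized_fraction, 0.7)
  expect_lte(sk$realized_fraction, 0.85)  # balancing keeps it near target
  expect_gte(sk$carrier_samples, 30)
  # carriers are distinct samples carrying the dominant change
  dom <- study$truth[study$truth$provenance == "skew_dominant", ]
  expect_gte(length(unique(dom$sample_id)), 30)
  expect_true(all(dom$alt_aa == "Q"))
})

test_that("an unreachable skew target fails fast and names the reachable set", {
  # phenylalanine is not reachable from any arginine codon by a single
  # base change, so this fails regardless of the gene's codon composition
  cfg <- small_cfg(43,
                   skew_specs = list(skew_spec("GENE001", "F", 0.7, 10)))
  ref <- generate_reference(cfg)
  expect_error(simulate_mutations(ref, cfg), "reachable")
})

test_that("the pipeline reproduces the manifest exactly on emitted data", {
  cfg <- simulation_config(
    n_genes = 10, codons_per_gene = 60, arg_codon_fraction = 0.15,
    n_samples = 80, mutations_per_sample = 12, seed = 53,
    skew_specs = list(skew_spec("GENE004", "K", 0.8, 25)))
  res <- simulate_study(cfg, dir = withr::local_tempdir())
  man <- res$study$manifest
  fa <- read_reference(res$paths[["fasta"]])
  models <- read_gene_models(res$paths[["gff3"]])
  recs <- read_mutations(res$paths[["csv"]])
  expect_equal(nrow(recs), man$n_records)
  ann <- annotate_mutations(recs, fa, models)
  expect_equal(ann$counts[["annotated"]], man$n_coding)
  expect_equal(ann$counts[["noncoding"]], man$n_noncoding)
  expect_equal(ann$counts[["mismatched"]], 0L)
  # per-gene arginine outcome counts match the manifest exactly
  arg <- ann$annotated[ann$annotated$ref_aa == "R", ]
  outcome <- ifelse(arg$functional_class == "synonymous", "silent",
                    ifelse(arg$functional_class == "nonsense", "stop",
                           arg$alt_aa))
  obs <- as.data.frame(table(gene = arg$gene_symbol, outcome = outcome),
                       stringsAsFactors = FALSE)
  obs <- obs[obs$Freq > 0, ]
  names(obs)[3] <- "count"
  key <- function(d) paste(d$gene, d$outcome)
  expect_setequal(key(obs), key(man$gene_residue_counts))
  m <- match(key(obs), key(man$gene_residue_counts))
  expect_equal(obs$count, man$gene_residue_counts$count[m])
  # and the injected skew is recovered by the detector
  rep1 <- detect_skewed_genes(ann$annotated, min_samples = 20)
  expect_true("GENE004" %in% rep1$gene_symbol)
  expect_equal(rep1$dominant_residue[rep1$gene_symbol == "GENE004"], "K")
})
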