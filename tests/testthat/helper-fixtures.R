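# Shared fixtures: tiny hand-built references/genes, an annotated-record
# factory for skew tests, and the full-CDS translation oracle used to
# cross-check the codon-arithmetic annotation path.

# A plus-strand toy locus: 100 bp pad, then a single-CDS gene at 101-160.
toy_plus_gene <- function(cds = NULL, pad = 100L) {
  set.seed(42)
  if (is.null(cds)) {
    # 20 codons, no stops in frame
    codons <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                             c("TAA", "TAG", "TGA")), 20, replace = TRUE)
    cds <- paste(codons, collapse = "")
  }
  pad_seq <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                   collapse = "")
  tail_seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                    collapse = "")
  chrom <- paste0(pad_seq, cds, tail_seq)
  reference <- Biostrings::DNAStringSet(c(chr1 = chrom))
  model <- gene_model("TOY", "chr1", "+", pad + 1L, pad + nchar(cds), 0L)
  list(reference = reference, model = model, models = list(TOY = model),
       cds = cds, cds_start = pad + 1L)
}

# Full-CDS translation oracle: rebuilds the (possibly mutated) CDS from the
# raw interval description and translates it with Biostrings. Independent of
# the package's per-codon coordinate arithmetic.
oracle_protein <- function(chrom_seq, starts, ends, strand, phase = 0L,
                           mutate_pos = NULL, mutate_to = NULL) {
  s <- chrom_seq
  if (!is.null(mutate_pos)) {
    substr(s, mutate_pos, mutate_pos) <- mutate_to
  }
  o <- order(starts)
  segs <- substring(s, starts[o], ends[o])
  cds <- paste(segs, collapse = "")
  if (strand == "-") {
    cds <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds)))
  }
  usable <- 3L * ((nchar(cds) - phase) %/% 3L)
  cds <- substr(cds, phase + 1L, phase + usable)
  # no.init.codon: plain table-1 translation (no Met at alt initiators)
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     no.init.codon = TRUE))
}

# Diff wild-type vs mutant translation; returns NULL when identical, else
# (protein_position, ref_aa, alt_aa) of the single difference.
oracle_event <- function(chrom_seq, model_df, mutate_pos, mutate_to) {
  wt <- oracle_protein(chrom_seq, model_df$starts, model_df$ends,
                       model_df$strand, model_df$phase)
  mut <- oracle_protein(chrom_seq, model_df$starts, model_df$ends,
                        model_df$strand, model_df$phase,
                        mutate_pos, mutate_to)
  wt_v <- strsplit(wt, "")[[1]]
  mut_v <- strsplit(mut, "")[[1]]
  d <- which(wt_v != mut_v)
  if (length(d) == 0) {
    return(list(protein_position = NA_integer_, ref_aa = NA_character_,
                alt_aa = NA_character_, silent = TRUE, wt = wt_v))
  }
  list(protein_position = d[1], ref_aa = wt_v[d[1]], alt_aa = mut_v[d[1]],
       silent = FALSE, wt = wt_v)
}

# Lookup: for a target residue, one arginine codon change that produces it
# (plus-strand gene representation). Built from the package's enumeration so
# skew-test records are internally consistent.
arg_change_for <- function(target) {
  ev <- substitution_space(ARGININE_CODONS)$events
  hit <- ev[ev$functional_class == "missense" & ev$alt_aa == target, ]
  if (nrow(hit) == 0) stop("no arginine change produces ", target)
  # prefer the transition route (the canonical C>T / G>A chemistry)
  hit <- hit[order(!hit$is_transition), ]
  h <- hit[1, ]
  list(ref_codon = h$ref_codon, codon_pos = h$codon_pos,
       wt = h$ref_base, mut = h$alt_base, alt_codon = h$alt_codon)
}

# Annotated-record factory for skew/spectra/control tests: plus-strand gene,
# one row per (sample, target-residue) pair. Positions are synthesized so
# records at the same codon share a genomic position (hotspot-like).
make_arg_records <- function(gene, targets, samples = NULL,
                             chromosome = "chr1") {
  if (is.null(samples)) samples <- sprintf("S%04d", seq_along(targets))
  stopifnot(length(samples) == length(targets))
  gene_block <- 1000L * (sum(utf8ToInt(gene)) %% 50L)  # keep genes apart
  rows <- lapply(seq_along(targets), function(i) {
    ch <- arg_change_for(targets[i])
    pos <- 1000L + gene_block +
      match(targets[i], c("C", "Q", "H", "W", "K", "L", "P",
                          "S", "G", "M", "T", "I")) * 10L +
      ch$codon_pos
    data.frame(
      gene_symbol = gene, sample_id = samples[i], chromosome = chromosome,
      position = pos, gene_strand = "+", wt_allele = ch$wt,
      mut_allele = ch$mut, ref_codon = ch$ref_codon,
      alt_codon = ch$alt_codon, codon_pos = ch$codon_pos, ref_aa = "R",
      alt_aa = targets[i], functional_class = "missense",
      is_transition = is_transition(ch$wt, ch$mut),
      protein_position = 10L, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Records with only the fields spectra need, from base-change labels.
records_from_changes <- function(changes, strand = "+") {
  data.frame(
    wt_allele = substr(changes, 1, 1),
    mut_allele = substr(changes, 3, 3),
    gene_strand = rep_len(strand, length(changes)),
    stringsAsFactors = FALSE
  )
}

binom_se_pct <- function(p, n) 100 * sqrt(p * (1 - p) / n)

# One gene's worth of missense arginine records: n_dom records toward `dom`
# carried by dom_samples distinct samples (extra records recycle the first
# sample), plus n_other records toward `other`, each from its own sample.
skew_gene <- function(gene, n_dom, n_other, dom = "H", other = "Q",
                      dom_samples = n_dom) {
  dom_ids <- c(sprintf("D%04d", seq_len(dom_samples)),
               rep("D0001", max(0, n_dom - dom_samples)))
  # recycled sample ids need distinct positions or they deduplicate away
  recs_dom <- make_arg_records(gene, rep(dom, n_dom), dom_ids)
  recs_dom$position <- recs_dom$position + seq_len(n_dom)
  recs_oth <- make_arg_records(gene, rep(other, n_other),
                               sprintf("O%04d", seq_len(n_other)))
  recs_oth$position <- recs_oth$position + seq_len(n_other)
  rbind(recs_dom, recs_oth)
}
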