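# Synthetic study generator: a reference chromosome, GFF3 gene models and a
# COSMIC-like mutation table with known signature, codon usage, strand
# placement and injected per-gene substitution skews, plus a ground-truth
# manifest. Everything is driven by one seed; identical config + seed gives
# byte-identical outputs.

#' Default 12-category mutational signature
#'
#' A C>T / G>A dominated signature qualitatively matching the pan-cancer
#' substitution spectrum: the two deamination-style transitions carry 28%
#' each, the remaining transitions (A>G, T>C) 7% each, and the eight
#' transversions share the remaining 30% equally. Categories are expressed
#' on the genomic plus strand.
#'
#' @return named numeric vector over [BASE_CHANGES_12], summing to 1.
#' @export
default_signature <- function() {
  w <- setNames(rep(0.30 / 8, 12), BASE_CHANGES_12)
  w["C>T"] <- 0.28
  w["G>A"] <- 0.28
  w["A>G"] <- 0.07
  w["T>C"] <- 0.07
  w
}

#' Specify an injected arginine substitution skew
#'
#' @param gene gene symbol (must exist in the generated reference).
#' @param target_residue 1-letter residue the skew drives toward; must be
#'   reachable by a single-base missense change from the gene's arginine
#'   codons.
#' @param fraction dominant fraction to realize (0-1, exclusive); the
#'   generator guarantees the realized fraction is at least this.
#' @param n_carriers number of distinct carrier samples for the dominant
#'   substitution.
#' @return a `skew_spec` list.
#' @export
skew_spec <- function(gene, target_residue, fraction, n_carriers) {
  stopifnot(is.character(gene), length(gene) == 1,
            target_residue %in% setdiff(unique(Biostrings::GENETIC_CODE),
                                        "*"),
            fraction > 0, fraction < 1, n_carriers >= 1)
  structure(list(gene = gene, target_residue = target_residue,
                 fraction = fraction, n_carriers = as.integer(n_carriers)),
            class = "skew_spec")
}

#' Build a simulation configuration
#'
#' Defines the synthetic study: gene layout, arginine codon usage, the
#' 12-category background signature, sample count and per-sample mutation
#' load, the noncoding fraction, and any injected gene skews. All weight
#' vectors are normalised; the seed is mandatory and drives every random
#' choice downstream.
#'
#' @param n_genes number of genes on the synthetic chromosome.
#' @param codons_per_gene sense codons per gene (a stop codon is appended).
#' @param arg_codon_fraction fraction of sense codons that are arginine
#'   codons (default 0.08, near the human proteome arginine frequency).
#' @param fraction_minus_strand fraction of genes placed on the minus
#'   strand.
#' @param intron_fraction fraction of genes given an intron that splits a
#'   codon (at least one gene when positive).
#' @param arginine_codon_usage named weights over the six arginine codons;
#'   default [default_arginine_usage()].
#' @param signature named weights over [BASE_CHANGES_12] (genomic plus
#'   strand); default [default_signature()].
#' @param n_samples number of tumor samples.
#' @param mutations_per_sample Poisson mean of per-sample mutation counts.
#' @param noncoding_fraction fraction of mutations placed outside CDS.
#' @param skew_specs list of [skew_spec()]s.
#' @param intergenic intergenic gap length (bp).
#' @param chromosome synthetic chromosome name.
#' @param seed integer seed (mandatory).
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 30, codons_per_gene = 100,
                              arg_codon_fraction = 0.08,
                              fraction_minus_strand = 0.4,
                              intron_fraction = 0.3,
                              arginine_codon_usage = default_arginine_usage(),
                              signature = default_signature(),
                              n_samples = 300, mutations_per_sample = 15,
                              noncoding_fraction = 0.3,
                              skew_specs = list(),
                              intergenic = 300,
                              chromosome = "chrS1",
                              seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("seed is mandatory", call. = FALSE)
  }
  stopifnot(n_genes >= 1, codons_per_gene >= 5,
            arg_codon_fraction >= 0, arg_codon_fraction <= 1,
            fraction_minus_strand >= 0, fraction_minus_strand <= 1,
            intron_fraction >= 0, intron_fraction <= 1,
            n_samples >= 1, mutations_per_sample > 0,
            noncoding_fraction >= 0, noncoding_fraction < 1,
            intergenic >= 50)
  if (!setequal(names(arginine_codon_usage), ARGININE_CODONS)) {
    stop("arginine_codon_usage must be named over the six arginine codons",
         call. = FALSE)
  }
  if (!setequal(names(signature), BASE_CHANGES_12)) {
    stop("signature must be named over the 12 base-change categories",
         call. = FALSE)
  }
  if (any(arginine_codon_usage < 0) || any(signature < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  for (sp in skew_specs) {
    if (!inherits(sp, "skew_spec")) {
      stop("skew_specs must be a list of skew_spec() objects", call. = FALSE)
    }
    if (sp$n_carriers > n_samples) {
      stop("skew spec for ", sp$gene, " needs more carriers than samples",
           call. = FALSE)
    }
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    codons_per_gene = as.integer(codons_per_gene),
    arg_codon_fraction = arg_codon_fraction,
    fraction_minus_strand = fraction_minus_strand,
    intron_fraction = intron_fraction,
    arginine_codon_usage =
      arginine_codon_usage[ARGININE_CODONS] / sum(arginine_codon_usage),
    signature = signature[BASE_CHANGES_12] / sum(signature),
    n_samples = as.integer(n_samples),
    mutations_per_sample = mutations_per_sample,
    noncoding_fraction = noncoding_fraction,
    skew_specs = skew_specs,
    intergenic = as.integer(intergenic),
    chromosome = chromosome,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate the synthetic reference and gene models
#'
#' Lays `n_genes` non-overlapping genes on one synthetic chromosome. Each
#' gene's CDS is built codon by codon: arginine codons (drawn from the usage
#' weights) at the configured fraction, all other sense codons uniformly,
#' and a terminal stop. A configured fraction of genes sits on the minus
#' strand (the plus-strand locus sequence is the reverse complement of the
#' coding sequence), and a fraction carries an intron placed mid-codon, so
#' one codon spans the intron boundary and the second CDS segment has
#' non-zero phase.
#'
#' @param config a [simulation_config()].
#' @return list of class `"synthetic_reference"`: `reference`
#'   ([Biostrings::DNAStringSet]), `models` (named [gene_model()] list),
#'   `genes` (data.frame: gene, strand, has_intron, n_codons), `sites`
#'   (data.frame indexing every CDS base: gene, gpos, cds position, codon
#'   index, in-codon offset, codon, plus-strand base, mutable flag),
#'   `codons` (per-gene codon vectors), `gff3_lines`, `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  other_codons <- sort(setdiff(
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"],
    ARGININE_CODONS))
  minus_genes <- sample.int(n, round(n * config$fraction_minus_strand))
  n_intron <- if (config$intron_fraction > 0) {
    max(1L, round(n * config$intron_fraction))
  } else 0L
  intron_genes <- if (n_intron > 0) sample.int(n, n_intron) else integer(0)

  chrom_parts <- list(.random_dna(100L))
  cursor <- 101L
  genes <- list()
  models <- list()
  codons_by_gene <- list()
  site_parts <- list()
  gff3 <- c("##gff-version 3")

  for (i in seq_len(n)) {
    g <- sprintf("GENE%03d", i)
    strand <- if (i %in% minus_genes) "-" else "+"
    k <- config$codons_per_gene
    is_arg <- runif(k) < config$arg_codon_fraction
    codons <- character(k)
    if (any(is_arg)) {
      codons[is_arg] <- sample(ARGININE_CODONS, sum(is_arg), replace = TRUE,
                               prob = config$arginine_codon_usage)
    }
    if (any(!is_arg)) {
      codons[!is_arg] <- sample(other_codons, sum(!is_arg), replace = TRUE)
    }
    codons <- c(codons, "TAA")
    cds_seq <- paste(codons, collapse = "")
    cds_len <- nchar(cds_seq)

    has_intron <- i %in% intron_genes
    if (has_intron) {
      # cut one base into a mid-gene codon so the codon spans the intron
      j <- max(2L, k %/% 2L)
      l1 <- 3L * (j - 1L) + 1L
      intron_seq <- paste0("GT", .random_dna(56L), "AG")
      li <- nchar(intron_seq)
      tx_seq <- paste0(substr(cds_seq, 1L, l1), intron_seq,
                       substr(cds_seq, l1 + 1L, cds_len))
      l2 <- cds_len - l1
      phase2 <- (3L - l1 %% 3L) %% 3L
    } else {
      tx_seq <- cds_seq
      l1 <- cds_len
      li <- 0L
      l2 <- 0L
      phase2 <- 0L
    }
    locus_seq <- if (strand == "+") tx_seq else reverse_complement(tx_seq)
    s <- cursor
    L <- nchar(locus_seq)

    if (has_intron) {
      if (strand == "+") {
        starts <- c(s, s + l1 + li)
        ends <- c(s + l1 - 1L, s + L - 1L)
        phases <- c(0L, phase2)  # genomic order = transcription order
      } else {
        starts <- c(s, s + l2 + li)
        ends <- c(s + l2 - 1L, s + L - 1L)
        phases <- c(phase2, 0L)  # rightmost interval is transcription-first
      }
    } else {
      starts <- s
      ends <- s + L - 1L
      phases <- 0L
    }
    model <- gene_model(g, config$chromosome, strand, starts, ends, 0L)
    models[[g]] <- model

    gff3 <- c(gff3,
      paste(config$chromosome, "argskew", "gene", s, s + L - 1L, ".",
            strand, ".", sprintf("ID=%s;Name=%s", g, g), sep = "\t"),
      vapply(seq_along(starts), function(q) {
        paste(config$chromosome, "argskew", "CDS", starts[q], ends[q], ".",
              strand, phases[q],
              sprintf("ID=cds-%s-%d;Parent=%s.t1;gene_id=%s", g, q, g, g),
              sep = "\t")
      }, character(1)))

    cds_pos <- seq_len(cds_len)
    gpos <- map_cds_to_genomic(cds_pos, model)
    codon_idx <- (cds_pos - 1L) %/% 3L + 1L
    offset <- (cds_pos - 1L) %% 3L + 1L
    codon_str <- codons[codon_idx]
    coding_base <- substring(cds_seq, cds_pos, cds_pos)
    plus_base <- if (strand == "-") complement_bases(coding_base) else {
      coding_base
    }
    site_parts[[g]] <- data.frame(
      gene = g, gpos = gpos, cds_pos = cds_pos, codon_idx = codon_idx,
      offset = offset, codon = codon_str, plus_base = plus_base,
      strand = strand, mutable = codon_str != "TAA",
      stringsAsFactors = FALSE
    )

    genes[[g]] <- data.frame(gene = g, strand = strand,
                             has_intron = has_intron, n_codons = k,
                             start = s, end = s + L - 1L,
                             stringsAsFactors = FALSE)
    chrom_parts[[length(chrom_parts) + 1L]] <- locus_seq
    chrom_parts[[length(chrom_parts) + 1L]] <- .random_dna(config$intergenic)
    cursor <- s + L + config$intergenic
  }

  chrom_seq <- paste(unlist(chrom_parts), collapse = "")
  reference <- Biostrings::DNAStringSet(setNames(chrom_seq,
                                                 config$chromosome))
  structure(list(
    reference = reference,
    models = models,
    genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
    sites = do.call(rbind, c(site_parts, list(make.row.names = FALSE))),
    codons = codons_by_gene_fill(models, site_parts),
    gff3_lines = gff3,
    config = config
  ), class = "synthetic_reference")
}

# per-gene codon vectors recovered from the site index (single source)
codons_by_gene_fill <- function(models, site_parts) {
  lapply(site_parts, function(d) {
    d$codon[d$offset == 1L]
  })
}

.sample_from <- function(x, n) {
  x[sample.int(length(x), n, replace = TRUE)]
}

# records df skeleton from a site-index subset plus alleles/samples
.coding_records <- function(sites_rows, sample_id, alt_plus, chromosome,
                            provenance) {
  coding_alt <- ifelse(sites_rows$strand == "-",
                       complement_bases(alt_plus), alt_plus)
  alt_codon <- sites_rows$codon
  substr(alt_codon, sites_rows$offset, sites_rows$offset) <- coding_alt
  ref_aa <- translate_codon(sites_rows$codon)
  alt_aa <- translate_codon(alt_codon)
  cls <- classify_substitution(ref_aa, alt_aa)
  data.frame(
    gene_symbol = sites_rows$gene,
    transcript_id = paste0(sites_rows$gene, ".t1"),
    sample_id = sample_id,
    chromosome = chromosome,
    position = sites_rows$gpos,
    gene_strand = sites_rows$strand,
    wt_allele = sites_rows$plus_base,
    mut_allele = alt_plus,
    mutation_aa = sprintf("p.%s%d%s", ref_aa, sites_rows$codon_idx, alt_aa),
    mutation_class = ifelse(cls == "synonymous", "coding silent", cls),
    ref_codon = sites_rows$codon,
    alt_codon = alt_codon,
    codon_pos = sites_rows$offset,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    functional_class = cls,
    protein_position = sites_rows$codon_idx,
    provenance = provenance,
    stringsAsFactors = FALSE
  )
}

#' Simulate a COSMIC-like mutation table with ground truth
#'
#' Draws per-sample mutation counts from a Poisson, assigns each mutation a
#' base-change category from the configured signature (genomic plus-strand
#' orientation) and a position uniformly among the reference sites carrying
#' the category's source base — coding sites (stop codons excluded) or
#' noncoding sites according to the configured noncoding fraction. Injected
#' skews then place the specific codon changes that yield each spec's
#' target residue in the stated number of distinct carrier samples, with
#' balancing other-residue records so the realized dominant fraction is at
#' least (and close to) the requested one. Records are de-duplicated on
#' `(sample_id, chromosome, position, mut_allele)`.
#'
#' All alleles are reported on the genomic plus strand. The returned truth
#' table gives, for every emitted record, the construction-level codon
#' annotation and provenance (`background`, `skew_dominant`,
#' `skew_balance`); the manifest aggregates it and matches the emitted
#' table exactly.
#'
#' @param ref a `"synthetic_reference"` from [generate_reference()].
#' @param config a [simulation_config()]; defaults to the one inside `ref`.
#' @return list of class `"synthetic_study"`: `records` (the mutation table,
#'   internal column names as in [read_mutations()]), `truth` (records plus
#'   construction annotation), `manifest` (list: record counts, realized
#'   background signature counts, per-gene arginine outcome counts, realized
#'   skews).
#' @export
simulate_mutations <- function(ref, config = ref$config) {
  stopifnot(inherits(ref, "synthetic_reference"))
  set.seed(config$seed + 1L)
  chromosome <- config$chromosome
  chrom_seq <- as.character(ref$reference[[chromosome]])
  chrom_len <- nchar(chrom_seq)
  sites <- ref$sites
  mutable <- sites[sites$mutable, , drop = FALSE]
  nc_pos <- setdiff(seq_len(chrom_len), sites$gpos)
  nc_base <- substring(chrom_seq, nc_pos, nc_pos)
  coding_idx_by_base <- split(seq_len(nrow(mutable)), mutable$plus_base)
  nc_idx_by_base <- split(seq_along(nc_pos), nc_base)

  samples <- sprintf("S%04d", seq_len(config$n_samples))
  n_per_sample <- stats::rpois(config$n_samples, config$mutations_per_sample)
  sample_id <- rep(samples, n_per_sample)
  N <- length(sample_id)
  noncoding <- stats::runif(N) < config$noncoding_fraction
  category <- .sample_weighted(BASE_CHANGES_12, N, config$signature)
  src <- substr(category, 1, 1)
  alt <- substr(category, 3, 3)

  parts <- list()
  for (b in DNA_BASES) {
    sel <- !noncoding & src == b
    if (any(sel)) {
      rows <- mutable[.sample_from(coding_idx_by_base[[b]], sum(sel)), ,
                      drop = FALSE]
      parts[[paste0("c", b)]] <- .coding_records(
        rows, sample_id[sel], alt[sel], chromosome, "background")
    }
    seln <- noncoding & src == b
    if (any(seln)) {
      pos <- nc_pos[.sample_from(nc_idx_by_base[[b]], sum(seln))]
      parts[[paste0("n", b)]] <- data.frame(
        gene_symbol = "", transcript_id = "", sample_id = sample_id[seln],
        chromosome = chromosome, position = pos, gene_strand = "+",
        wt_allele = b, mut_allele = alt[seln], mutation_aa = "",
        mutation_class = "noncoding", ref_codon = NA_character_,
        alt_codon = NA_character_, codon_pos = NA_integer_,
        ref_aa = NA_character_, alt_aa = NA_character_,
        functional_class = "noncoding", protein_position = NA_integer_,
        provenance = "background", stringsAsFactors = FALSE
      )
    }
  }
  truth <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  truth <- deduplicate_records(truth)

  for (sp in config$skew_specs) {
    truth <- .inject_skew(truth, sp, ref, samples, chromosome)
  }
  truth <- deduplicate_records(truth)
  rownames(truth) <- NULL

  record_cols <- c("gene_symbol", "transcript_id", "sample_id", "chromosome",
                   "position", "gene_strand", "wt_allele", "mut_allele",
                   "mutation_aa", "mutation_class")
  records <- truth[, record_cols]
  manifest <- .build_manifest(truth, config)
  structure(list(records = records, truth = truth, manifest = manifest),
            class = "synthetic_study")
}

.sample_weighted <- function(values, n, weights) {
  values[sample.int(length(values), n, replace = TRUE, prob = weights)]
}

# dominant/other single-base missense changes toward/away from a target
# residue over a gene's arginine codon instances
.arg_change_table <- function(ref, gene) {
  gs <- ref$sites[ref$sites$gene == gene &
                    ref$sites$codon %in% ARGININE_CODONS, , drop = FALSE]
  if (nrow(gs) == 0) return(NULL)
  out <- list()
  for (cd in unique(gs$codon)) {
    ev <- enumerate_substitutions(cd)
    ev <- ev[ev$functional_class == "missense", , drop = FALSE]
    inst <- gs[gs$codon == cd, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      site <- inst[inst$offset == ev$codon_pos[r], , drop = FALSE]
      site$coding_alt <- ev$alt_base[r]
      site$target <- ev$alt_aa[r]
      out[[length(out) + 1L]] <- site
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.inject_skew <- function(truth, sp, ref, samples, chromosome) {
  changes <- .arg_change_table(ref, sp$gene)
  if (is.null(changes)) {
    stop("skew spec for gene ", sp$gene,
         ": gene has no arginine codons", call. = FALSE)
  }
  dom <- changes[changes$target == sp$target_residue, , drop = FALSE]
  if (nrow(dom) == 0) {
    stop("skew spec for gene ", sp$gene, ": residue ", sp$target_residue,
         " is unreachable by missense change; reachable: ",
         paste(sort(unique(changes$target)), collapse = ", "),
         call. = FALSE)
  }
  other <- changes[changes$target != sp$target_residue, , drop = FALSE]
  key_of <- function(d) paste(d$sample_id, d$chromosome, d$position,
                              d$mut_allele, sep = "\r")
  make_recs <- function(rows, sample_ids, provenance) {
    alt_plus <- ifelse(rows$strand == "-",
                       complement_bases(rows$coding_alt), rows$coding_alt)
    .coding_records(rows, sample_ids, alt_plus, chromosome, provenance)
  }
  add_noncolliding <- function(truth, pool_rows, n, provenance) {
    added <- 0L
    guard <- 0L
    while (added < n && guard < 50L) {
      guard <- guard + 1L
      need <- n - added
      rows <- pool_rows[.sample_from(seq_len(nrow(pool_rows)), need), ,
                        drop = FALSE]
      recs <- make_recs(rows, .sample_from(samples, need), provenance)
      new <- !(key_of(recs) %in% key_of(truth)) & !duplicated(key_of(recs))
      recs <- recs[new, , drop = FALSE]
      if (nrow(recs)) {
        truth <- rbind(truth, recs)
        added <- added + nrow(recs)
      }
    }
    truth
  }

  # carriers: distinct samples, each with one dominant-change record
  carriers <- samples[sample.int(length(samples), sp$n_carriers)]
  rows <- dom[.sample_from(seq_len(nrow(dom)), sp$n_carriers), , drop = FALSE]
  recs <- make_recs(rows, carriers, "skew_dominant")
  recs <- recs[!(key_of(recs) %in% key_of(truth)), , drop = FALSE]
  truth <- rbind(truth, recs)

  gene_stats <- function(truth) {
    d <- truth[truth$gene_symbol == sp$gene &
                 !is.na(truth$ref_aa) & truth$ref_aa == "R" &
                 truth$functional_class == "missense", , drop = FALSE]
    c(t = sum(d$alt_aa == sp$target_residue),
      o = sum(d$alt_aa != sp$target_residue))
  }
  for (iter in 1:20) {
    st <- gene_stats(truth)
    frac <- if (sum(st) == 0) 0 else st[["t"]] / sum(st)
    if (frac < sp$fraction) {
      need <- ceiling((sp$fraction * sum(st) - st["t"]) / (1 - sp$fraction))
      truth <- add_noncolliding(truth, dom, need, "skew_dominant")
    } else {
      surplus <- floor(st["t"] * (1 - sp$fraction) / sp$fraction) - st["o"]
      if (surplus > 0 && nrow(other) > 0) {
        truth <- add_noncolliding(truth, other, surplus, "skew_balance")
      }
      break
    }
  }
  truth
}

.build_manifest <- function(truth, config) {
  background <- truth[truth$provenance == "background", , drop = FALSE]
  sig_counts <- table(factor(paste0(background$wt_allele, ">",
                                    background$mut_allele),
                             levels = BASE_CHANGES_12))
  arg <- truth[!is.na(truth$ref_aa) & truth$ref_aa == "R", , drop = FALSE]
  outcome <- ifelse(arg$functional_class == "synonymous", "silent",
                    ifelse(arg$functional_class == "nonsense", "stop",
                           arg$alt_aa))
  gene_residue <- if (nrow(arg)) {
    as.data.frame(table(gene = arg$gene_symbol, outcome = outcome),
                  stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), outcome = character(0),
               Freq = integer(0))
  }
  gene_residue <- gene_residue[gene_residue$Freq > 0, , drop = FALSE]
  names(gene_residue)[3] <- "count"
  rownames(gene_residue) <- NULL

  skews <- lapply(config$skew_specs, function(sp) {
    d <- arg[arg$gene_symbol == sp$gene &
               arg$functional_class == "missense", , drop = FALSE]
    t_n <- sum(d$alt_aa == sp$target_residue)
    data.frame(
      gene = sp$gene, target_residue = sp$target_residue,
      requested_fraction = sp$fraction,
      realized_fraction = if (nrow(d)) t_n / nrow(d) else NA_real_,
      carrier_samples =
        length(unique(d$sample_id[d$alt_aa == sp$target_residue])),
      n_injected = sum(truth$provenance == "skew_dominant" &
                         truth$gene_symbol == sp$gene),
      stringsAsFactors = FALSE
    )
  })
  list(
    seed = config$seed,
    n_records = nrow(truth),
    n_coding = sum(truth$functional_class != "noncoding"),
    n_noncoding = sum(truth$functional_class == "noncoding"),
    signature_counts = setNames(as.integer(sig_counts), BASE_CHANGES_12),
    gene_residue_counts = gene_residue,
    skewed_genes = if (length(skews)) {
      do.call(rbind, c(skews, list(make.row.names = FALSE)))
    } else NULL
  )
}

#' Write the synthetic reference as FASTA + GFF3
#'
#' @param ref a `"synthetic_reference"`.
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(ref, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(ref$reference, fasta_path)
  writeLines(ref$gff3_lines, gff3_path)
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Write a mutation table as COSMIC-like CSV
#'
#' Columns: `GENE_SYMBOL, TRANSCRIPT, SAMPLE_ID, CHROMOSOME, GENOME_START,
#' STRAND, WT_ALLELE, MUT_ALLELE, MUTATION_AA, MUTATION_CLASS`.
#'
#' @param records data.frame with the internal column names (as produced by
#'   [simulate_mutations()] or [read_mutations()]).
#' @param path output CSV.
#' @return `records`, invisibly.
#' @export
write_mutation_csv <- function(records, path) {
  out <- data.frame(
    GENE_SYMBOL = records$gene_symbol,
    TRANSCRIPT = records$transcript_id,
    SAMPLE_ID = records$sample_id,
    CHROMOSOME = records$chromosome,
    GENOME_START = records$position,
    STRAND = records$gene_strand,
    WT_ALLELE = records$wt_allele,
    MUT_ALLELE = records$mut_allele,
    MUTATION_AA = records$mutation_aa,
    MUTATION_CLASS = records$mutation_class,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(records)
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest the manifest list from [simulate_mutations()].
#' @param path output JSON.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [generate_reference()] + [simulate_mutations()],
#' optionally writing FASTA, GFF3, mutation CSV and manifest to a
#' directory.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed); `NULL` for in-memory
#'   only.
#' @return list with `reference` (the `"synthetic_reference"`), `study`
#'   (the `"synthetic_study"`) and, when written, `paths`.
#' @export
simulate_study <- function(config, dir = NULL) {
  ref <- generate_reference(config)
  study <- simulate_mutations(ref, config)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      fasta = file.path(dir, "reference.fa"),
      gff3 = file.path(dir, "genes.gff3"),
      csv = file.path(dir, "mutations.csv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_reference(ref, paths["fasta"], paths["gff3"])
    write_mutation_csv(study$records, paths["csv"])
    write_manifest(study$manifest, paths["manifest"])
  }
  list(reference = ref, study = study, paths = paths)
}
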