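#' Construct a gene model from CDS intervals
#'
#' A gene model is the minimal description needed to map a genomic position
#' into a coding-sequence position: chromosome, strand, and the ordered CDS
#' intervals (1-based inclusive, genomic coordinates) with the phase of the
#' first interval in translation order. Intervals are stored in transcription
#' order: ascending genomic start for `+` genes, descending for `-` genes.
#'
#' @param gene_symbol gene name.
#' @param chromosome sequence name the intervals live on.
#' @param strand `"+"` or `"-"`.
#' @param starts,ends integer vectors of CDS interval bounds (1-based,
#'   inclusive, any order; must not overlap).
#' @param phase bases to skip at the translation-order start of the first
#'   interval before the first complete codon (GFF3 phase, 0-2).
#' @return object of class `"gene_model"`.
#' @export
gene_model <- function(gene_symbol, chromosome, strand, starts, ends,
                       phase = 0L) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1,
            strand %in% c("+", "-"), phase %in% 0:2, all(ends >= starts))
  o <- order(starts)
  starts <- as.integer(starts[o])
  ends <- as.integer(ends[o])
  if (length(starts) > 1 &&
      any(starts[-1] <= ends[-length(ends)])) {
    stop("CDS intervals overlap for gene ", gene_symbol, call. = FALSE)
  }
  if (strand == "-") {  # transcription order runs right to left
    starts <- rev(starts)
    ends <- rev(ends)
  }
  len <- ends - starts + 1L
  model <- list(
    gene_symbol = gene_symbol,
    chromosome = chromosome,
    strand = strand,
    intervals = data.frame(start = starts, end = ends, length = len,
                           cum_before = cumsum(c(0L, len[-length(len)]))),
    phase = as.integer(phase),
    cds_length = sum(len)
  )
  class(model) <- "gene_model"
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s%s): %d CDS interval(s), %d bp, phase %d\n",
              x$gene_symbol, x$chromosome, x$strand, nrow(x$intervals),
              x$cds_length, x$phase))
  invisible(x)
}

# genomic position -> 1-based CDS coordinate in transcription order;
# NA where the position falls outside every interval. Vectorised.
map_genomic_to_cds <- function(positions, model) {
  out <- rep(NA_integer_, length(positions))
  iv <- model$intervals
  for (i in seq_len(nrow(iv))) {
    inside <- !is.na(positions) & positions >= iv$start[i] &
      positions <= iv$end[i]
    if (!any(inside)) next
    off <- if (model$strand == "+") {
      positions[inside] - iv$start[i] + 1L
    } else {
      iv$end[i] - positions[inside] + 1L
    }
    out[inside] <- iv$cum_before[i] + off
  }
  out
}

# 1-based CDS coordinate -> genomic position. Vectorised; errors on
# out-of-range input (internal misuse, not user data).
map_cds_to_genomic <- function(cds_pos, model) {
  if (any(cds_pos < 1 | cds_pos > model$cds_length)) {
    stop("CDS coordinate out of range", call. = FALSE)
  }
  iv <- model$intervals
  idx <- findInterval(cds_pos - 1L, iv$cum_before)
  off <- cds_pos - iv$cum_before[idx]
  if (model$strand == "+") iv$start[idx] + off - 1L else iv$end[idx] - off + 1L
}

.noncoding_error <- function(msg) {
  structure(
    class = c("argskew_noncoding", "error", "condition"),
    list(message = msg, call = NULL)
  )
}

#' Locate the codon containing a genomic position
#'
#' Maps a genomic position into its gene model and returns the three genomic
#' coordinates (translation order) of the codon containing it, the in-codon
#' offset and the protein position. A codon may span an intron boundary, in
#' which case its genomic coordinates form two sub-ranges.
#'
#' Positions inside the model's span but outside its CDS intervals — or in a
#' phase overhang / trailing partial codon — raise a condition of class
#' `"argskew_noncoding"` so callers can route the record to the noncoding
#' stream rather than drop it.
#'
#' @param position 1-based genomic position.
#' @param model a [gene_model()].
#' @return list with `positions` (3 genomic coordinates in translation
#'   order), `ranges` (data.frame of 1 or 2 contiguous genomic sub-ranges),
#'   `offset` (position within the codon, 1-3) and `protein_position`.
#' @export
codon_range <- function(position, model) {
  cds <- map_genomic_to_cds(position, model)
  if (is.na(cds)) {
    stop(.noncoding_error(sprintf(
      "position %d is non-coding for gene %s", position, model$gene_symbol)))
  }
  coding <- cds - model$phase
  n_codons <- (model$cds_length - model$phase) %/% 3L
  if (coding < 1L || coding > n_codons * 3L) {
    stop(.noncoding_error(sprintf(
      "position %d falls in a partial codon of gene %s", position,
      model$gene_symbol)))
  }
  protein_position <- (coding - 1L) %/% 3L + 1L
  offset <- (coding - 1L) %% 3L + 1L
  codon_cds <- (protein_position - 1L) * 3L + model$phase + 1:3
  gpos <- map_cds_to_genomic(codon_cds, model)
  gsorted <- sort(gpos)
  brk <- which(diff(gsorted) > 1L)
  rng_start <- gsorted[c(1L, brk + 1L)]
  rng_end <- gsorted[c(brk, length(gsorted))]
  list(
    positions = gpos,
    ranges = data.frame(start = rng_start, end = rng_end),
    offset = offset,
    protein_position = protein_position
  )
}

#' Read a reference FASTA
#'
#' @param path FASTA file. Sequence names are truncated at the first
#'   whitespace.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  ref
}

#' Read gene models from GFF3
#'
#' Collects `CDS` features, grouped by gene symbol (taken from the
#' `gene_id` attribute, falling back to `Parent` / `ID`). Phase is taken
#' from the GFF3 phase column of the translation-order first CDS feature.
#' If a gene symbol carries several transcripts, the first model
#' encountered wins, with a warning.
#'
#' @param path GFF3 file with CDS features.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) stop("no CDS features in ", path, call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  gene <- if ("gene_id" %in% names(mc)) {
    as.character(mc$gene_id)
  } else if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) sub("\\..*$", "", as.character(p)[1]),
           character(1))
  } else {
    as.character(mc$ID)
  }
  df <- data.frame(
    gene = gene,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    phase = as.integer(mc$phase),
    stringsAsFactors = FALSE
  )
  models <- list()
  for (g in unique(df$gene)) {
    d <- df[df$gene == g, ]
    if (length(unique(d$strand)) > 1 || length(unique(d$chromosome)) > 1) {
      warning("gene ", g, " has inconsistent CDS features; using the first ",
              "chromosome/strand set")
      d <- d[d$chromosome == d$chromosome[1] & d$strand == d$strand[1], ]
    }
    first_phase <- if (d$strand[1] == "+") {
      d$phase[which.min(d$start)]
    } else {
      d$phase[which.max(d$end)]
    }
    if (is.na(first_phase)) first_phase <- 0L
    models[[g]] <- gene_model(g, d$chromosome[1], d$strand[1],
                              d$start, d$end, first_phase)
  }
  models
}

#' Fetch a codon from the reference
#'
#' Reads the bases at the given genomic positions (translation order) and,
#' for minus-strand genes, complements them so the returned triplet is the
#' codon as translated.
#'
#' @param reference a [Biostrings::DNAStringSet].
#' @param chromosome sequence name.
#' @param positions the 3 genomic positions in translation order (e.g. from
#'   [codon_range()]); a plus-strand codon's positions ascend, a
#'   minus-strand codon's descend.
#' @param strand `"+"` or `"-"`.
#' @return 3-character codon string in translation order.
#' @export
fetch_codon <- function(reference, chromosome, positions, strand = "+") {
  if (!chromosome %in% names(reference)) {
    stop("chromosome ", chromosome, " not in reference", call. = FALSE)
  }
  seqlen <- length(reference[[chromosome]])
  if (any(positions < 1 | positions > seqlen)) {
    stop("codon positions out of reference bounds", call. = FALSE)
  }
  s <- as.character(reference[[chromosome]])
  bases <- substring(s, positions, positions)
  if (!all(bases %in% DNA_BASES)) {
    stop("non-ACGT base in reference at requested positions", call. = FALSE)
  }
  if (strand == "-") bases <- complement_bases(bases)
  paste(bases, collapse = "")
}

.parse_protein_change <- function(x) {
  m <- regmatches(x, regexec("^p\\.([A-Z*])([0-9]+)([A-Z*=])$", x))[[1]]
  if (length(m) == 0) return(NULL)
  list(ref_aa = m[2], protein_position = as.integer(m[3]),
       alt_aa = if (m[4] == "=") m[2] else m[4])
}

#' Annotate a batch of point mutations to codon-level events
#'
#' The workhorse of the pipeline: each mutation record (plus-strand alleles,
#' 1-based genomic position) is mapped through its gene model into a
#' codon-level substitution event. Alleles are complemented exactly once,
#' here, for minus-strand genes. Records are routed into three exhaustive,
#' non-overlapping streams:
#'
#' * `annotated` — in-CDS records with a matching reference base, annotated
#'   with `ref_codon`, `alt_codon`, `codon_pos`, `ref_aa`, `alt_aa`,
#'   `functional_class`, `is_transition`, `protein_position`,
#'   `codon_start`/`codon_end` and (when the input carried a protein-change
#'   string such as `p.R132H`) a `discordant` flag.
#' * `noncoding` — records with no gene model, on the wrong chromosome for
#'   their model, or outside its CDS intervals (`reason` column).
#' * `mismatched` — records whose `wt_allele` disagrees with the reference
#'   base at their position; excluded from analysis, counted, warned about.
#'
#' @param records data.frame with columns `gene_symbol`, `sample_id`,
#'   `chromosome`, `position`, `wt_allele`, `mut_allele` and optionally
#'   `mutation_aa`.
#' @param reference a [Biostrings::DNAStringSet].
#' @param models named list of [gene_model()]s.
#' @return list of class `"annotated_mutations"` with elements `annotated`,
#'   `noncoding`, `mismatched` (data.frames) and `counts` (named integer
#'   vector: input, annotated, noncoding, mismatched).
#' @export
annotate_mutations <- function(records, reference, models) {
  required <- c("gene_symbol", "sample_id", "chromosome", "position",
                "wt_allele", "mut_allele")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  records$position <- as.integer(records$position)
  records$wt_allele <- toupper(records$wt_allele)
  records$mut_allele <- toupper(records$mut_allele)
  if (any(records$wt_allele == records$mut_allele)) {
    stop("wt_allele equals mut_allele in some records", call. = FALSE)
  }
  records$.row <- seq_len(n)

  chrom_cache <- new.env(parent = emptyenv())
  get_chrom <- function(chrom) {
    if (!exists(chrom, envir = chrom_cache)) {
      if (!chrom %in% names(reference)) return(NULL)
      assign(chrom, as.character(reference[[chrom]]), envir = chrom_cache)
    }
    get(chrom, envir = chrom_cache)
  }

  ann_parts <- list()
  nc_parts <- list()
  mm_parts <- list()

  for (g in unique(records$gene_symbol)) {
    rec <- records[records$gene_symbol == g, , drop = FALSE]
    model <- if (!is.na(g) && nzchar(g)) models[[g]] else NULL
    if (is.null(model)) {
      rec$reason <- "no_gene_model"
      nc_parts[[length(nc_parts) + 1L]] <- rec
      next
    }
    off_chrom <- rec$chromosome != model$chromosome
    if (any(off_chrom)) {
      bad <- rec[off_chrom, , drop = FALSE]
      bad$reason <- "wrong_chromosome"
      nc_parts[[length(nc_parts) + 1L]] <- bad
      rec <- rec[!off_chrom, , drop = FALSE]
      if (nrow(rec) == 0) next
    }
    cds <- map_genomic_to_cds(rec$position, model)
    coding <- cds - model$phase
    n_codons <- (model$cds_length - model$phase) %/% 3L
    in_cds <- !is.na(cds) & coding >= 1L & coding <= n_codons * 3L
    if (any(!in_cds)) {
      bad <- rec[!in_cds, , drop = FALSE]
      bad$reason <- ifelse(is.na(cds[!in_cds]), "outside_cds", "partial_codon")
      nc_parts[[length(nc_parts) + 1L]] <- bad
      rec <- rec[in_cds, , drop = FALSE]
      coding <- coding[in_cds]
      if (nrow(rec) == 0) next
    }
    seq_chr <- get_chrom(model$chromosome)
    if (is.null(seq_chr)) {
      stop("chromosome ", model$chromosome, " missing from reference",
           call. = FALSE)
    }
    ref_at_pos <- substring(seq_chr, rec$position, rec$position)
    mism <- ref_at_pos != rec$wt_allele
    if (any(mism)) {
      bad <- rec[mism, , drop = FALSE]
      bad$reference_base <- ref_at_pos[mism]
      mm_parts[[length(mm_parts) + 1L]] <- bad
      rec <- rec[!mism, , drop = FALSE]
      coding <- coding[!mism]
      if (nrow(rec) == 0) next
    }
    protein_position <- (coding - 1L) %/% 3L + 1L
    offset <- (coding - 1L) %% 3L + 1L
    # genomic positions of all three codon bases, translation order
    p1 <- map_cds_to_genomic((protein_position - 1L) * 3L + model$phase + 1L,
                             model)
    p2 <- map_cds_to_genomic((protein_position - 1L) * 3L + model$phase + 2L,
                             model)
    p3 <- map_cds_to_genomic((protein_position - 1L) * 3L + model$phase + 3L,
                             model)
    b1 <- substring(seq_chr, p1, p1)
    b2 <- substring(seq_chr, p2, p2)
    b3 <- substring(seq_chr, p3, p3)
    if (model$strand == "-") {
      b1 <- complement_bases(b1)
      b2 <- complement_bases(b2)
      b3 <- complement_bases(b3)
    }
    ref_codon <- paste0(b1, b2, b3)
    alt_base_coding <- if (model$strand == "-") {
      complement_bases(rec$mut_allele)
    } else {
      rec$mut_allele
    }
    alt_codon <- ref_codon
    substr(alt_codon, offset, offset) <- alt_base_coding
    rec$gene_strand <- model$strand
    rec$ref_codon <- ref_codon
    rec$alt_codon <- alt_codon
    rec$codon_pos <- offset
    rec$ref_aa <- translate_codon(ref_codon)
    rec$alt_aa <- translate_codon(alt_codon)
    rec$functional_class <- classify_substitution(rec$ref_aa, rec$alt_aa)
    rec$is_transition <- is_transition(rec$wt_allele, rec$mut_allele)
    rec$protein_position <- protein_position
    rec$codon_start <- pmin(p1, p3)
    rec$codon_end <- pmax(p1, p3)
    if ("mutation_aa" %in% names(rec)) {
      rec$discordant <- vapply(seq_len(nrow(rec)), function(i) {
        pc <- .parse_protein_change(rec$mutation_aa[i])
        if (is.null(pc)) return(NA)
        !(pc$ref_aa == rec$ref_aa[i] && pc$alt_aa == rec$alt_aa[i] &&
            pc$protein_position == rec$protein_position[i])
      }, logical(1))
    } else {
      rec$discordant <- NA
    }
    ann_parts[[length(ann_parts) + 1L]] <- rec
  }

  bind <- function(parts) {
    if (length(parts) == 0) return(NULL)
    out <- do.call(rbind, parts)
    out <- out[order(out$.row), , drop = FALSE]
    rownames(out) <- NULL
    out$.row <- NULL
    out
  }
  annotated <- bind(ann_parts)
  noncoding <- bind(nc_parts)
  mismatched <- bind(mm_parts)
  counts <- c(input = n,
              annotated = if (is.null(annotated)) 0L else nrow(annotated),
              noncoding = if (is.null(noncoding)) 0L else nrow(noncoding),
              mismatched = if (is.null(mismatched)) 0L else nrow(mismatched))
  if (counts["mismatched"] > 0) {
    warning(counts["mismatched"],
            " record(s) excluded: wt_allele does not match the reference",
            call. = FALSE)
  }
  structure(list(annotated = annotated, noncoding = noncoding,
                 mismatched = mismatched, counts = counts),
            class = "annotated_mutations")
}

#' @export
print.annotated_mutations <- function(x, ...) {
  cat(sprintf(
    "annotated_mutations: %d in = %d annotated + %d noncoding + %d mismatched\n",
    x$counts["input"], x$counts["annotated"], x$counts["noncoding"],
    x$counts["mismatched"]))
  invisible(x)
}

#' Annotate a single mutation record
#'
#' Convenience wrapper over [annotate_mutations()] for one record. Noncoding
#' positions raise an `"argskew_noncoding"` condition; reference mismatches
#' raise an error.
#'
#' @param record one-row data.frame (or list coercible to one) with the
#'   columns of [annotate_mutations()].
#' @inheritParams annotate_mutations
#' @return one-row annotated data.frame.
#' @export
annotate_record <- function(record, reference, models) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  res <- suppressWarnings(annotate_mutations(record, reference, models))
  if (!is.null(res$mismatched) && nrow(res$mismatched) > 0) {
    stop("wt_allele '", record$wt_allele, "' does not match reference base '",
         res$mismatched$reference_base[1], "' at position ", record$position,
         call. = FALSE)
  }
  if (!is.null(res$noncoding) && nrow(res$noncoding) > 0) {
    stop(.noncoding_error(sprintf(
      "position %d is non-coding (%s)", record$position,
      res$noncoding$reason[1])))
  }
  res$annotated
}

#' Read a COSMIC-like mutation CSV
#'
#' Expects the column set written by [write_mutation_csv()]:
#' `GENE_SYMBOL, TRANSCRIPT, SAMPLE_ID, CHROMOSOME, GENOME_START, STRAND,
#' WT_ALLELE, MUT_ALLELE, MUTATION_AA, MUTATION_CLASS`. Returns the
#' internal lowercase representation used throughout the package.
#'
#' @param path CSV file.
#' @return data.frame with columns `gene_symbol`, `transcript_id`,
#'   `sample_id`, `chromosome`, `position`, `gene_strand`, `wt_allele`,
#'   `mut_allele`, `mutation_aa`, `mutation_class`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  lookup <- c(GENE_SYMBOL = "gene_symbol", TRANSCRIPT = "transcript_id",
              SAMPLE_ID = "sample_id", CHROMOSOME = "chromosome",
              GENOME_START = "position", STRAND = "gene_strand",
              WT_ALLELE = "wt_allele", MUT_ALLELE = "mut_allele",
              MUTATION_AA = "mutation_aa", MUTATION_CLASS = "mutation_class")
  missing_cols <- setdiff(names(lookup), names(df))
  if (length(missing_cols)) {
    stop("mutation CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  names(df) <- lookup[names(df)]
  df$position <- as.integer(df$position)
  df
}

#' De-duplicate mutation records
#'
#' COSMIC-style exports can list one mutation in several rows (one per
#' transcript or study). The counting unit throughout the package is the
#' unique event `(sample_id, chromosome, position, mut_allele)`; this keeps
#' the first row of each duplicate group.
#'
#' @param records mutation data.frame.
#' @return de-duplicated data.frame.
#' @export
deduplicate_records <- function(records) {
  key <- paste(records$sample_id, records$chromosome, records$position,
               records$mut_allele, sep = "\r")
  records[!duplicated(key), , drop = FALSE]
}

#' Write annotated mutations as TSV
#'
#' @param annotated the `annotated` data.frame from [annotate_mutations()].
#' @param path output file.
#' @return `annotated`, invisibly.
#' @export
write_annotated <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(annotated)
}
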