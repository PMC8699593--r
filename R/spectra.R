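# Frequency tables over base changes, codons and residue outcomes.
# All percentages are kept at full precision internally; rounding happens
# only at serialization.

.spectrum_table <- function(counts, categories) {
  counts <- counts[categories]
  counts[is.na(counts)] <- 0L
  total <- sum(counts)
  if (total == 0) {
    warning("empty input: spectrum has no records", call. = FALSE)
    pct <- rep(NA_real_, length(categories))
  } else {
    pct <- 100 * counts / total
  }
  structure(
    data.frame(category = categories, count = as.integer(counts),
               percentage = pct, stringsAsFactors = FALSE,
               row.names = NULL),
    total = total, class = c("spectrum_table", "data.frame"))
}

# ordered base change labels for a record set, in the requested orientation.
# coding orientation complements both alleles for minus-strand genes so the
# change reads as it does on the coding (sense) strand.
.change_labels <- function(records, orientation = c("coding", "genomic")) {
  orientation <- match.arg(orientation)
  ref <- toupper(records$wt_allele)
  alt <- toupper(records$mut_allele)
  if (orientation == "coding") {
    if (!"gene_strand" %in% names(records) ||
        any(is.na(records$gene_strand))) {
      stop("coding orientation needs a gene_strand column without NAs",
           call. = FALSE)
    }
    minus <- records$gene_strand == "-"
    ref[minus] <- complement_bases(ref[minus])
    alt[minus] <- complement_bases(alt[minus])
  }
  paste0(ref, ">", alt)
}

#' Base-change spectrum of a record set
#'
#' Tabulates the single-base substitution categories of a set of mutation
#' records, either strand-resolved (12 ordered categories, `A>C` ... `T>G`)
#' or folded onto the six pyrimidine-centric classes COSMIC reports (each
#' purine-initiated change is counted with its reverse complement).
#'
#' @param records data.frame with `wt_allele`, `mut_allele` and, for coding
#'   orientation, `gene_strand`.
#' @param orientation `"coding"` (default; alleles re-expressed on the coding
#'   strand of each record's gene) or `"genomic"` (plus-strand alleles as
#'   given).
#' @param split12 if `TRUE` (default) report 12 categories, else the 6
#'   folded classes.
#' @return a `spectrum_table` data.frame (`category`, `count`,
#'   `percentage`), with the total count in `attr(, "total")`.
#' @export
base_change_spectrum <- function(records, orientation = c("coding", "genomic"),
                                 split12 = TRUE) {
  orientation <- match.arg(orientation)
  labels <- if (nrow(records) == 0) character(0) else {
    .change_labels(records, orientation)
  }
  counts <- table(factor(labels, levels = BASE_CHANGES_12))
  tab <- setNames(as.integer(counts), names(counts))
  if (!split12) {
    folded <- setNames(integer(length(BASE_CHANGES_6)), BASE_CHANGES_6)
    for (cat12 in BASE_CHANGES_12) {
      ref <- substr(cat12, 1, 1)
      alt <- substr(cat12, 3, 3)
      key <- if (ref %in% PYRIMIDINES) cat12 else {
        paste0(complement_bases(ref), ">", complement_bases(alt))
      }
      folded[key] <- folded[key] + tab[cat12]
    }
    return(.spectrum_table(folded, BASE_CHANGES_6))
  }
  .spectrum_table(tab, BASE_CHANGES_12)
}

#' Fold a 12-category spectrum onto the 6 COSMIC classes
#'
#' @param spectrum a 12-category `spectrum_table` from
#'   [base_change_spectrum()].
#' @return a 6-category `spectrum_table`; folding conserves the total count.
#' @export
fold_spectrum <- function(spectrum) {
  stopifnot(identical(spectrum$category, BASE_CHANGES_12))
  tab <- setNames(spectrum$count, spectrum$category)
  folded <- setNames(integer(6), BASE_CHANGES_6)
  for (cat12 in BASE_CHANGES_12) {
    ref <- substr(cat12, 1, 1)
    alt <- substr(cat12, 3, 3)
    key <- if (ref %in% PYRIMIDINES) cat12 else {
      paste0(complement_bases(ref), ">", complement_bases(alt))
    }
    folded[key] <- folded[key] + tab[cat12]
  }
  .spectrum_table(folded, BASE_CHANGES_6)
}

#' Strand-specific C>T and G>A frequencies
#'
#' Splits the genomic-orientation C>T and G>A transition counts by the strand
#' of the mutated gene and reports per-strand frequencies (count over all
#' records on that gene strand) plus their ratio. Under a mutational process
#' with no transcriptional strand bias the ratio is ~1 for both categories.
#'
#' @param records data.frame with `wt_allele`, `mut_allele`, `gene_strand`.
#' @return data.frame with one row per category (`C>T`, `G>A`):
#'   plus/minus-strand counts, per-strand frequencies (%), and
#'   `ratio` = plus frequency / minus frequency (NA when undefined).
#' @export
strand_spectrum <- function(records) {
  if (nrow(records) == 0) {
    warning("empty input: strand spectrum has no records", call. = FALSE)
  }
  labels <- if (nrow(records) == 0) character(0) else {
    .change_labels(records, "genomic")
  }
  strand <- factor(records$gene_strand, levels = c("+", "-"))
  n_plus <- sum(strand == "+", na.rm = TRUE)
  n_minus <- sum(strand == "-", na.rm = TRUE)
  out <- do.call(rbind, lapply(c("C>T", "G>A"), function(cat) {
    cp <- sum(labels == cat & strand == "+", na.rm = TRUE)
    cm <- sum(labels == cat & strand == "-", na.rm = TRUE)
    fp <- if (n_plus > 0) 100 * cp / n_plus else NA_real_
    fm <- if (n_minus > 0) 100 * cm / n_minus else NA_real_
    data.frame(category = cat, plus_count = cp, minus_count = cm,
               plus_freq = fp, minus_freq = fm,
               ratio = if (!is.na(fm) && fm > 0) fp / fm else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-codon share of arginine mutations versus genome codon usage
#'
#' For records whose reference residue is arginine, computes the share each
#' of the six codons contributes to the observed mutations, next to a
#' reference (non-cancer) codon-usage column — the comparison behind
#' "which codons are mutated more often than their usage predicts".
#'
#' @param records annotated records (needs `ref_aa`, `ref_codon`); rows with
#'   `ref_aa != "R"` are dropped.
#' @param usage named numeric vector of usage weights over the six arginine
#'   codons (normalised internally). Defaults to
#'   [default_arginine_usage()].
#' @return data.frame: `codon`, `mutation_count`, `mutation_share_pct`,
#'   `usage_pct`.
#' @export
arginine_codon_shares <- function(records, usage = default_arginine_usage()) {
  records <- records[records$ref_aa == "R", , drop = FALSE]
  if (nrow(records) == 0) {
    warning("empty input: no arginine records", call. = FALSE)
  }
  usage <- usage[ARGININE_CODONS]
  usage <- usage / sum(usage)
  counts <- table(factor(records$ref_codon, levels = ARGININE_CODONS))
  total <- sum(counts)
  data.frame(
    codon = ARGININE_CODONS,
    mutation_count = as.integer(counts),
    mutation_share_pct = if (total > 0) 100 * as.integer(counts) / total
                         else NA_real_,
    usage_pct = 100 * as.numeric(usage),
    stringsAsFactors = FALSE
  )
}

#' Default arginine codon usage weights
#'
#' A qualitative human (non-cancer) usage profile for the six arginine
#' codons: AGA, AGG, CGG and CGC each around 20%, CGA and CGT around 10%.
#' Used as the reference column of [arginine_codon_shares()] and as the
#' simulator default; override with measured usage where available.
#'
#' @return named numeric vector over the six codons, summing to 1.
#' @export
default_arginine_usage <- function() {
  c(AGA = 0.20, AGG = 0.20, CGA = 0.10, CGG = 0.20, CGT = 0.10, CGC = 0.20)
}

#' Amino-acid substitution outcomes by source arginine codon
#'
#' Cross-tabulates arginine records by source codon (rows: the six arginine
#' codons) and outcome (columns: each observed target residue, plus
#' `silent` for synonymous and `stop` for nonsense changes). Percentages are
#' of the grand total. A companion 12-category nucleotide-change spectrum of
#' the same records (the "grand total" row) is attached.
#'
#' @param records annotated records; rows with `ref_aa != "R"` are dropped.
#' @param orientation orientation for the companion nucleotide spectrum.
#' @return list of class `"aa_by_codon"`: `counts` and `percentages`
#'   (matrices, 6 x outcomes), `nucleotide_changes` (a `spectrum_table`),
#'   `total`.
#' @export
aa_by_source_codon <- function(records, orientation = c("coding", "genomic")) {
  orientation <- match.arg(orientation)
  records <- records[records$ref_aa == "R", , drop = FALSE]
  if (nrow(records) == 0) {
    warning("empty input: no arginine records", call. = FALSE)
  }
  outcome <- ifelse(records$functional_class == "synonymous", "silent",
                    ifelse(records$functional_class == "nonsense", "stop",
                           records$alt_aa))
  residues <- sort(setdiff(unique(outcome), c("silent", "stop")))
  levels <- c(residues, "silent", "stop")
  counts <- table(factor(records$ref_codon, levels = ARGININE_CODONS),
                  factor(outcome, levels = levels))
  counts <- matrix(as.integer(counts), nrow = length(ARGININE_CODONS),
                   dimnames = list(ARGININE_CODONS, levels))
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts * NA_real_
  nuc <- suppressWarnings(
    base_change_spectrum(records, orientation = orientation, split12 = TRUE))
  structure(list(counts = counts, percentages = pct,
                 nucleotide_changes = nuc, total = total),
            class = "aa_by_codon")
}

#' @export
print.aa_by_codon <- function(x, ...) {
  cat("Arginine substitution outcomes by source codon (counts):\n")
  print(x$counts)
  invisible(x)
}

#' Transition enrichment: arginine vs all-coding vs noncoding
#'
#' Compares the C>T and G>A shares across three record streams: arginine
#' records, all coding records and noncoding records. Coding streams are
#' tabulated in coding orientation, the noncoding stream (which has no gene
#' strand) in genomic orientation. Two aggregate rows are included: the sum
#' of the C>T and G>A shares, and the share of all transitions.
#'
#' @param arginine_records,coding_records annotated coding records.
#' @param noncoding_records records routed noncoding by
#'   [annotate_mutations()].
#' @return data.frame with one row per category (`C>T`, `G>A`,
#'   `C>T + G>A`, `all transitions`) and columns for each stream's
#'   percentage plus the ratios arginine/coding and coding/noncoding (NA
#'   with a warning when a stream is empty).
#' @export
transition_enrichment <- function(arginine_records, coding_records,
                                  noncoding_records) {
  pct_of <- function(records, orientation) {
    n <- nrow(records)
    if (n == 0) {
      return(c(`C>T` = NA_real_, `G>A` = NA_real_,
               `C>T + G>A` = NA_real_, `all transitions` = NA_real_))
    }
    labels <- .change_labels(records, orientation)
    ti <- is_transition(toupper(records$wt_allele),
                        toupper(records$mut_allele))
    c(`C>T` = 100 * sum(labels == "C>T") / n,
      `G>A` = 100 * sum(labels == "G>A") / n,
      `C>T + G>A` = 100 * sum(labels %in% c("C>T", "G>A")) / n,
      `all transitions` = 100 * sum(ti) / n)
  }
  empty <- c(arginine = nrow(arginine_records) == 0,
             coding = nrow(coding_records) == 0,
             noncoding = nrow(noncoding_records) == 0)
  if (any(empty)) {
    warning("empty stream(s): ", paste(names(empty)[empty], collapse = ", "),
            "; ratios reported as NA", call. = FALSE)
  }
  a <- pct_of(arginine_records, "coding")
  k <- pct_of(coding_records, "coding")
  nc <- pct_of(noncoding_records, "genomic")
  out <- data.frame(
    category = names(a),
    arginine_pct = as.numeric(a),
    coding_pct = as.numeric(k),
    noncoding_pct = as.numeric(nc),
    arginine_vs_coding = as.numeric(ifelse(!is.na(k) & k > 0, a / k,
                                           NA_real_)),
    coding_vs_noncoding = as.numeric(ifelse(!is.na(nc) & nc > 0, k / nc,
                                            NA_real_)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Write a spectrum-like data.frame as TSV
#'
#' Numeric columns are rounded to 2 decimals at serialization only.
#'
#' @param x data.frame.
#' @param path output file.
#' @return `x`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1)) & !vapply(y, is.integer, logical(1))
  y[num] <- lapply(y[num], round, digits = 2)
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
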