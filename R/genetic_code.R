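#' argskew: codon-level somatic mutation spectra and arginine skew detection
#'
#' Somatic cancer genomes carry a strong C>T / G>A transition signature.
#' Because four of the six arginine codons begin with C and all six carry an
#' internal G, this nucleotide-level signature funnels arginine codons toward
#' a small set of substitution outcomes (histidine, cysteine, glutamine,
#' tryptophan) before any selection at the protein level acts. This package
#' provides the machinery to quantify that funnel on any mutation table:
#' exhaustive enumeration of a codon family's single-nucleotide substitution
#' space, codon-level annotation of genomic SNVs, base-change and amino-acid
#' substitution spectra with coding/silent/noncoding controls, and detection
#' of genes whose arginine substitutions are skewed toward one residue.
#'
#' @importFrom Biostrings GENETIC_CODE
#' @importFrom stats rpois runif setNames
#' @importFrom utils read.csv write.table
#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' The six arginine codons
#'
#' Arginine is six-fold degenerate under the standard genetic code: AGA, AGG,
#' CGA, CGG, CGT and CGC all encode it (DNA alphabet).
#'
#' @format Character vector of length 6.
#' @export
ARGININE_CODONS <- c("AGA", "AGG", "CGA", "CGG", "CGT", "CGC")

#' The 12 ordered single-base substitution categories
#'
#' All ordered pairs of distinct DNA bases, written `"X>Y"`. The six
#' pyrimidine-centric classes used by COSMIC are obtained by folding each
#' purine-initiated change onto its reverse complement (see
#' [fold_spectrum()]).
#'
#' @format Character vector of length 12.
#' @export
BASE_CHANGES_12 <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                     "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' The 6 pyrimidine-centric substitution classes
#' @format Character vector of length 6.
#' @export
BASE_CHANGES_6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.valid_codon <- function(codon) {
  is.character(codon) && length(codon) == 1L && !is.na(codon) &&
    nchar(codon) == 3L &&
    all(strsplit(codon, "")[[1]] %in% DNA_BASES)
}

.check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || is.na(codon)) {
    stop("codon must be a single character string", call. = FALSE)
  }
  codon <- toupper(codon)
  if (!.valid_codon(codon)) {
    stop("invalid codon '", codon, "': must be 3 bases over A/C/G/T",
         call. = FALSE)
  }
  codon
}

#' Complement DNA bases
#'
#' @param x character vector of bases or sequences (A/C/G/T).
#' @return complemented vector, same shape.
#' @export
complement_bases <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

#' Reverse complement a DNA string
#' @param x character vector of DNA sequences.
#' @return reverse complement of each element.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_bases(s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Translate codons under the standard genetic code
#'
#' Uses NCBI translation table 1 (the standard code); stop codons return
#' `"*"`. Input is normalised to uppercase DNA.
#'
#' @param codon character vector of 3-base DNA codons.
#' @return character vector of 1-letter residues (`"*"` for stops).
#' @examples
#' translate_codon(c("CGG", "TGA", "TGG"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !vapply(codon, .valid_codon, logical(1))
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a base substitution as transition or transversion
#'
#' A transition swaps within the purines (A,G) or within the pyrimidines
#' (C,T); everything else is a transversion. 4 of the 12 ordered base changes
#' are transitions.
#'
#' @param ref_base,alt_base single bases (vectorised, equal length).
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_base_change("C", "T")
#' classify_base_change("C", "G")
#' @export
classify_base_change <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  if (length(ref_base) != length(alt_base)) {
    stop("ref_base and alt_base must have equal length", call. = FALSE)
  }
  if (!all(ref_base %in% DNA_BASES) || !all(alt_base %in% DNA_BASES)) {
    stop("bases must be in {A,C,G,T}", call. = FALSE)
  }
  if (any(ref_base == alt_base)) {
    stop("ref and alt base must differ", call. = FALSE)
  }
  ifelse(is_transition(ref_base, alt_base), "transition", "transversion")
}

#' @rdname classify_base_change
#' @return `is_transition()`: logical vector.
#' @export
is_transition <- function(ref_base, alt_base) {
  (ref_base %in% PURINES & alt_base %in% PURINES) |
    (ref_base %in% PYRIMIDINES & alt_base %in% PYRIMIDINES)
}

#' Enumerate all single-nucleotide substitutions of a codon
#'
#' Every codon admits exactly 9 single-base substitutions (3 positions x 3
#' alternative bases). Each is classified as synonymous, missense or nonsense
#' and flagged as transition/transversion. Order is deterministic: codon
#' position ascending, then alternative base alphabetical.
#'
#' @param codon a single 3-base DNA codon.
#' @return data.frame with 9 rows and columns `ref_codon`, `codon_pos`,
#'   `ref_base`, `alt_base`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `functional_class`, `is_transition`.
#' @examples
#' enumerate_substitutions("CGA")  # includes CGA>TGA, a nonsense change
#' @export
enumerate_substitutions <- function(codon) {
  codon <- .check_codon(codon)
  bases <- strsplit(codon, "")[[1]]
  ref_aa <- translate_codon(codon)
  rows <- lapply(1:3, function(pos) {
    alts <- setdiff(DNA_BASES, bases[pos])
    alt_codons <- vapply(alts, function(a) {
      b <- bases
      b[pos] <- a
      paste(b, collapse = "")
    }, character(1))
    data.frame(
      ref_codon = codon,
      codon_pos = pos,
      ref_base = bases[pos],
      alt_base = alts,
      alt_codon = unname(alt_codons),
      stringsAsFactors = FALSE
    )
  })
  ev <- do.call(rbind, rows)
  ev$ref_aa <- ref_aa
  ev$alt_aa <- translate_codon(ev$alt_codon)
  ev$functional_class <- classify_substitution(ev$ref_aa, ev$alt_aa)
  ev$is_transition <- is_transition(ev$ref_base, ev$alt_base)
  rownames(ev) <- NULL
  ev
}

#' Classify a codon change by its protein-level effect
#'
#' @param ref_aa,alt_aa 1-letter residues (`"*"` = stop).
#' @return `"synonymous"`, `"missense"` or `"nonsense"`. A change creating a
#'   stop from a sense codon is nonsense; stop-to-stop is synonymous.
#' @export
classify_substitution <- function(ref_aa, alt_aa) {
  ifelse(ref_aa == alt_aa, "synonymous",
         ifelse(alt_aa == "*", "nonsense", "missense"))
}

#' Summarise the substitution space of a codon family
#'
#' Aggregates [enumerate_substitutions()] over a family of codons (typically
#' all synonymous codons of one residue). For arginine's six codons the space
#' holds 54 changes: 18 synonymous, 34 missense reaching 12 distinct
#' residues, and 2 nonsense.
#'
#' @param codons non-empty character vector of codons.
#' @return object of class `"substitution_space"`: a list with `events` (the
#'   row-bound enumeration), `total_changes`, `synonymous`, `missense`,
#'   `nonsense`, `distinct_target_aas` and `target_aa_counts` (named integer
#'   vector over missense target residues, excluding stops and the source
#'   residues).
#' @examples
#' substitution_space(ARGININE_CODONS)
#' @export
substitution_space <- function(codons) {
  if (length(codons) == 0) {
    stop("codons must be a non-empty vector", call. = FALSE)
  }
  codons <- vapply(codons, .check_codon, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(codons)) {
    stop("duplicate codons in family", call. = FALSE)
  }
  events <- do.call(rbind, lapply(codons, enumerate_substitutions))
  source_aas <- unique(events$ref_aa)
  missense <- events[events$functional_class == "missense", ]
  targets <- missense$alt_aa[!(missense$alt_aa %in% c("*", source_aas))]
  tab <- table(factor(targets, levels = sort(unique(targets))))
  out <- list(
    codons = codons,
    events = events,
    total_changes = nrow(events),
    synonymous = sum(events$functional_class == "synonymous"),
    missense = sum(events$functional_class == "missense"),
    nonsense = sum(events$functional_class == "nonsense"),
    distinct_target_aas = length(tab),
    target_aa_counts = setNames(as.integer(tab), names(tab))
  )
  class(out) <- "substitution_space"
  out
}

#' @export
print.substitution_space <- function(x, ...) {
  cat("Single-nucleotide substitution space of {",
      paste(x$codons, collapse = ", "), "}\n", sep = "")
  cat(sprintf("  total changes: %d (synonymous %d, missense %d, nonsense %d)\n",
              x$total_changes, x$synonymous, x$missense, x$nonsense))
  cat(sprintf("  distinct missense target residues: %d\n",
              x$distinct_target_aas))
  cat("  targets:",
      paste(sprintf("%s=%d", names(x$target_aa_counts), x$target_aa_counts),
            collapse = " "), "\n")
  invisible(x)
}

#' Synonymous codons of a residue
#'
#' Scans the standard code table; arginine returns its six codons.
#'
#' @param residue 1-letter residue (or `"*"` for stop codons).
#' @return character vector of codons, alphabetical.
#' @export
synonymous_codons <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L)
  sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == residue])
}

#' Residues with first-position synonymous substitutions
#'
#' Brute-force scan of the 61 sense codons for single-base changes at codon
#' position 1 that preserve the residue. Only arginine and leucine qualify
#' under the standard code — both have a six-codon family spanning two
#' first-base blocks.
#'
#' @return sorted character vector of residues.
#' @examples
#' first_position_synonymous_residues()  # "L" "R"
#' @export
first_position_synonymous_residues <- function() {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  hits <- vapply(sense, function(cd) {
    ev <- enumerate_substitutions(cd)
    any(ev$codon_pos == 1 & ev$functional_class == "synonymous")
  }, logical(1))
  sort(unique(unname(Biostrings::GENETIC_CODE[sense[hits]])))
}

#' Codons of a residue admitting first-position synonymous changes
#'
#' @param residue 1-letter residue, default `"R"`.
#' @return character vector of qualifying codons (for arginine: AGA, AGG,
#'   CGA, CGG).
#' @export
first_position_synonymous_codons <- function(residue = "R") {
  fam <- synonymous_codons(residue)
  fam[vapply(fam, function(cd) {
    ev <- enumerate_substitutions(cd)
    any(ev$codon_pos == 1 & ev$functional_class == "synonymous")
  }, logical(1))]
}

#' Write the substitution table of a codon family as TSV
#'
#' One row per single-base change (54 rows for arginine), columns
#' `ref_codon`, `codon_pos`, `ref_base`, `alt_base`, `alt_codon`, `ref_aa`,
#' `alt_aa`, `functional_class`, `is_transition`.
#'
#' @param path output file path.
#' @param codons codon family; defaults to the six arginine codons.
#' @return the events data.frame, invisibly.
#' @export
write_substitution_table <- function(path, codons = ARGININE_CODONS) {
  sp <- substitution_space(codons)
  utils::write.table(sp$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sp$events)
}
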