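# Control tables: per-residue percentages over all coding point mutations,
# over silent mutations only, and the 12-category base-change percentages
# of noncoding records.

.control_table <- function(kind, categories, counts) {
  counts <- counts[categories]
  counts[is.na(counts)] <- 0L
  denom <- sum(counts)
  if (denom == 0) {
    warning("empty input: ", kind, " control has no records", call. = FALSE)
    pct <- rep(NA_real_, length(categories))
  } else {
    pct <- 100 * counts / denom
  }
  structure(
    data.frame(category = categories, count = as.integer(counts),
               percentage = pct, stringsAsFactors = FALSE, row.names = NULL),
    control_kind = kind, denominator = denom,
    class = c("control_table", "data.frame"))
}

.aa_levels <- function() sort(setdiff(unique(Biostrings::GENETIC_CODE), "*"))

#' Coding control: residue outcome percentages over all coding mutations
#'
#' Each coding point mutation is attributed to the residue it resulted in:
#' the new residue for missense changes, the unchanged residue for silent
#' changes, and a separate `stop` category for nonsense changes. The
#' denominator is all coding point mutations.
#'
#' @param records annotated coding records (need `ref_aa`, `alt_aa`,
#'   `functional_class`).
#' @return `control_table` data.frame (`category`, `count`, `percentage`)
#'   over the 20 residues plus `stop`; denominator in
#'   `attr(, "denominator")`.
#' @export
coding_control <- function(records) {
  outcome <- if (nrow(records) == 0) character(0) else {
    ifelse(records$functional_class == "nonsense", "stop", records$alt_aa)
  }
  levels <- c(.aa_levels(), "stop")
  counts <- table(factor(outcome, levels = levels))
  .control_table("coding", levels, setNames(as.integer(counts), levels))
}

#' Silent coding control: residue percentages over silent mutations only
#'
#' Restricted to synonymous records; each is attributed to its (unchanged)
#' residue. The denominator is all silent mutations.
#'
#' @inheritParams coding_control
#' @return `control_table` over the 20 residues.
#' @export
silent_control <- function(records) {
  silent <- records[records$functional_class == "synonymous", , drop = FALSE]
  outcome <- if (nrow(silent) == 0) character(0) else silent$ref_aa
  levels <- .aa_levels()
  counts <- table(factor(outcome, levels = levels))
  .control_table("silent_coding", levels,
                 setNames(as.integer(counts), levels))
}

#' Noncoding control: base-change percentages of noncoding mutations
#'
#' The 12-category base-change spectrum of records that fall outside any
#' CDS, in genomic (plus-strand) orientation; the denominator is all
#' noncoding point mutations.
#'
#' @param records noncoding records (need `wt_allele`, `mut_allele`).
#' @return `control_table` over the 12 base-change categories.
#' @export
noncoding_control <- function(records) {
  sp <- suppressWarnings(
    base_change_spectrum(records, orientation = "genomic", split12 = TRUE))
  .control_table("noncoding", sp$category, setNames(sp$count, sp$category))
}

#' Write a control table as TSV
#'
#' @param x a `control_table`.
#' @param path output file.
#' @return `x`, invisibly.
#' @export
write_control <- function(x, path) {
  write_spectrum(x, path)
}
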