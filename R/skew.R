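# Detection of genes whose arginine substitutions are skewed toward one
# residue: >= min_fraction of the gene's missense arginine substitutions
# yield the same residue, carried by >= min_samples distinct tumor samples.

#' Dominant nucleotide change of a record set
#'
#' The most frequent of the 12 base-change categories (coding orientation)
#' among the given records, with its fraction of all the records. Ties are
#' broken lexicographically and flagged.
#'
#' @param records annotated records of one gene.
#' @return list with `category`, `fraction` (0-1), `tie` (logical).
#' @export
dominant_nt_change <- function(records) {
  if (nrow(records) == 0) {
    return(list(category = NA_character_, fraction = NA_real_, tie = NA))
  }
  sp <- base_change_spectrum(records, orientation = "coding", split12 = TRUE)
  best <- max(sp$count)
  winners <- sp$category[sp$count == best]  # categories pre-sorted
  list(category = winners[1], fraction = best / sum(sp$count),
       tie = length(winners) > 1)
}

#' Detect genes with a skewed arginine substitution bias
#'
#' A gene is called *skewed* when at least `min_fraction` of its missense
#' arginine substitutions produce one and the same residue, and at least
#' `min_samples` distinct samples carry that dominant substitution.
#' Synonymous and nonsense records are excluded from the denominator (they
#' produce no substituted residue). Records are de-duplicated on
#' `(sample_id, chromosome, position, mut_allele)` before counting.
#'
#' For each gene the report carries the per-target counts for the four
#' recurrent outcomes (C, Q, H, W) and all others pooled, the dominant
#' residue and its fraction, the dominant nucleotide change (12 categories,
#' coding orientation) and its fraction, the number of distinct samples
#' supporting the dominant residue, the total distinct samples with any
#' missense arginine substitution in the gene, and a driver flag from the
#' supplied list.
#'
#' @param records annotated records; rows with `ref_aa != "R"` are dropped.
#' @param min_fraction minimum dominant-residue fraction (default 0.60).
#' @param min_samples minimum distinct samples carrying the dominant
#'   substitution (default 40).
#' @param driver_genes character vector of driver gene symbols (optional).
#' @param verbose if `TRUE`, return all genes with their verdicts; default
#'   returns only the skewed genes.
#' @return data.frame sorted by dominant residue then gene symbol, one row
#'   per (qualifying) gene.
#' @export
detect_skewed_genes <- function(records, min_fraction = 0.60,
                                min_samples = 40,
                                driver_genes = character(0),
                                verbose = FALSE) {
  stopifnot(min_fraction > 0, min_fraction <= 1, min_samples >= 0)
  cols <- c("gene_symbol", "sample_id", "chromosome", "position",
            "mut_allele", "ref_aa", "alt_aa", "functional_class")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- deduplicate_records(records)
  arg <- records[records$ref_aa == "R" &
                   records$functional_class == "missense", , drop = FALSE]
  if (nrow(arg) == 0) {
    return(.empty_skew_report())
  }
  rows <- lapply(sort(unique(arg$gene_symbol)), function(g) {
    d <- arg[arg$gene_symbol == g, , drop = FALSE]
    counts <- sort(table(d$alt_aa), decreasing = TRUE)
    total <- nrow(d)
    best <- max(counts)
    winners <- sort(names(counts)[counts == best])
    dominant <- winners[1]
    tie <- length(winners) > 1
    supporting <- length(unique(d$sample_id[d$alt_aa == dominant]))
    nt <- dominant_nt_change(d)
    resid_count <- function(r) sum(d$alt_aa == r)
    data.frame(
      gene_symbol = g,
      n_missense = total,
      count_C = resid_count("C"), count_Q = resid_count("Q"),
      count_H = resid_count("H"), count_W = resid_count("W"),
      count_other = total - resid_count("C") - resid_count("Q") -
        resid_count("H") - resid_count("W"),
      dominant_residue = dominant,
      dominant_fraction = best / total,
      dominant_nt_change = nt$category,
      dominant_nt_fraction = nt$fraction,
      supporting_samples = supporting,
      total_samples = length(unique(d$sample_id)),
      tie = tie,
      is_skewed = !tie && best / total >= min_fraction &&
        supporting >= min_samples,
      is_driver = g %in% driver_genes,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  report <- report[order(report$dominant_residue, report$gene_symbol), ,
                   drop = FALSE]
  rownames(report) <- NULL
  if (!verbose) {
    report <- report[report$is_skewed, , drop = FALSE]
    rownames(report) <- NULL
  }
  report
}

.empty_skew_report <- function() {
  data.frame(
    gene_symbol = character(0), n_missense = integer(0),
    count_C = integer(0), count_Q = integer(0), count_H = integer(0),
    count_W = integer(0), count_other = integer(0),
    dominant_residue = character(0), dominant_fraction = numeric(0),
    dominant_nt_change = character(0), dominant_nt_fraction = numeric(0),
    supporting_samples = integer(0), total_samples = integer(0),
    tie = logical(0), is_skewed = logical(0), is_driver = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Read a driver-gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' skipped.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_driver_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write the skew report as TSV
#'
#' Fractions are serialized as percentages with 2 decimals.
#'
#' @param report data.frame from [detect_skewed_genes()].
#' @param path output file.
#' @return `report`, invisibly.
#' @export
write_skew_report <- function(report, path) {
  out <- report
  out$dominant_fraction <- round(100 * out$dominant_fraction, 2)
  out$dominant_nt_fraction <- round(100 * out$dominant_nt_fraction, 2)
  names(out)[names(out) == "dominant_fraction"] <- "dominant_pct"
  names(out)[names(out) == "dominant_nt_fraction"] <- "dominant_nt_pct"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
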