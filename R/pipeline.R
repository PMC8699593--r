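# Pipeline orchestration: each stage reads its inputs, writes TSV artifacts
# into the output directory and logs record counts to stderr. `all` composes
# the individual stages; a thin command-line wrapper lives in
# inst/scripts/argskew.R.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory for stage artifacts.
#' @param fasta,gff3,mutations_csv input paths (required by the annotate
#'   and downstream stages; written by the simulate stage).
#' @param driver_list optional path to a driver-gene list (one symbol per
#'   line).
#' @param orientation base-change orientation for figure-facing spectra:
#'   `"coding"` (default) or `"genomic"`.
#' @param min_fraction,min_samples skew thresholds (defaults 0.60 and 40).
#' @param seed integer seed for the simulate stage.
#' @param sim optional list of [simulation_config()] overrides for the
#'   simulate stage.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir, fasta = NULL, gff3 = NULL,
                       mutations_csv = NULL, driver_list = NULL,
                       orientation = c("coding", "genomic"),
                       min_fraction = 0.60, min_samples = 40,
                       seed = NULL, sim = list()) {
  orientation <- match.arg(orientation)
  stopifnot(min_fraction > 0, min_fraction <= 1, min_samples >= 0)
  structure(list(out_dir = out_dir, fasta = fasta, gff3 = gff3,
                 mutations_csv = mutations_csv, driver_list = driver_list,
                 orientation = orientation, min_fraction = min_fraction,
                 min_samples = min_samples, seed = seed, sim = sim),
            class = "run_config")
}

#' Read a plain key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognised keys match the arguments of [run_config()]; numeric values
#' are coerced.
#'
#' @param path config file.
#' @return named list suitable for `do.call(run_config, ...)`.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  out <- setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  for (k in c("min_fraction", "min_samples", "seed")) {
    if (k %in% names(out)) out[[k]] <- as.numeric(out[[k]])
  }
  out
}

.stage_log <- function(...) message("[argskew] ", sprintf(...))

#' Run one pipeline stage (or all of them)
#'
#' Stages: `space` (write the arginine substitution-space TSV; needs no
#' inputs), `simulate` (generate the synthetic study into `out_dir`),
#' `annotate` (CSV + FASTA + GFF3 -> annotated/noncoding/mismatched TSVs),
#' `spectrum` (figure-analogue TSVs: codon shares, 12-category spectrum,
#' strand spectrum, amino-acid-by-codon matrix, transition enrichment),
#' `controls` (coding/silent/noncoding control TSVs), `skew` (the skew
#' report), and `all` (simulate when no mutation CSV is given, then every
#' analysis stage in order). Counts in and out of each stage go to stderr.
#'
#' @param name stage name.
#' @param config a [run_config()].
#' @return named character vector of written artifact paths, invisibly.
#' @export
run_subcommand <- function(name = c("space", "simulate", "annotate",
                                    "spectrum", "controls", "skew", "all"),
                           config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(name,
    space = .stage_space(config),
    simulate = .stage_simulate(config),
    annotate = .stage_annotate(config),
    spectrum = .stage_spectrum(config),
    controls = .stage_controls(config),
    skew = .stage_skew(config),
    all = .stage_all(config)
  )
}

#' @rdname run_subcommand
#' @export
run_pipeline <- function(config) run_subcommand("all", config)

.stage_space <- function(config) {
  path <- file.path(config$out_dir, "arginine_substitution_space.tsv")
  events <- write_substitution_table(path)
  .stage_log("space: wrote %d substitution events to %s", nrow(events), path)
  invisible(c(space = path))
}

.stage_simulate <- function(config) {
  if (is.null(config$seed)) stop("simulate stage needs a seed", call. = FALSE)
  sim_args <- config$sim
  sim_args$seed <- config$seed
  sc <- do.call(simulation_config, sim_args)
  res <- simulate_study(sc, config$out_dir)
  .stage_log("simulate: %d genes, %d records (%d coding, %d noncoding)",
             sc$n_genes, res$study$manifest$n_records,
             res$study$manifest$n_coding, res$study$manifest$n_noncoding)
  invisible(res$paths)
}

.require_inputs <- function(config, keys) {
  for (k in keys) {
    if (is.null(config[[k]]) || !file.exists(config[[k]])) {
      stop("missing input for this stage: ", k, call. = FALSE)
    }
  }
}

.default_inputs <- function(config) {
  # fall back to the simulate stage's artifacts in out_dir
  if (is.null(config$fasta)) {
    config$fasta <- file.path(config$out_dir, "reference.fa")
  }
  if (is.null(config$gff3)) {
    config$gff3 <- file.path(config$out_dir, "genes.gff3")
  }
  if (is.null(config$mutations_csv)) {
    config$mutations_csv <- file.path(config$out_dir, "mutations.csv")
  }
  config
}

.stage_annotate <- function(config) {
  config <- .default_inputs(config)
  .require_inputs(config, c("fasta", "gff3", "mutations_csv"))
  reference <- read_reference(config$fasta)
  models <- read_gene_models(config$gff3)
  records <- read_mutations(config$mutations_csv)
  res <- suppressWarnings(annotate_mutations(records, reference, models))
  .stage_log("annotate: %d in = %d annotated + %d noncoding + %d mismatched",
             res$counts["input"], res$counts["annotated"],
             res$counts["noncoding"], res$counts["mismatched"])
  paths <- c(annotated = file.path(config$out_dir, "annotated.tsv"),
             noncoding = file.path(config$out_dir, "noncoding.tsv"),
             mismatched = file.path(config$out_dir, "mismatched.tsv"))
  empty <- function(x) if (is.null(x)) data.frame() else x
  write_annotated(empty(res$annotated), paths["annotated"])
  write_annotated(empty(res$noncoding), paths["noncoding"])
  write_annotated(empty(res$mismatched), paths["mismatched"])
  invisible(paths)
}

.read_stage_tsv <- function(config, file) {
  path <- file.path(config$out_dir, file)
  if (!file.exists(path)) {
    stop("missing ", file, "; run the annotate stage first", call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (k in intersect(c("position", "codon_pos", "protein_position"),
                      names(df))) {
    df[[k]] <- as.integer(df[[k]])
  }
  df
}

.stage_spectrum <- function(config) {
  ann <- .read_stage_tsv(config, "annotated.tsv")
  nc <- .read_stage_tsv(config, "noncoding.tsv")
  ann <- deduplicate_records(ann)
  nc <- deduplicate_records(nc)
  arg <- ann[ann$ref_aa == "R", , drop = FALSE]
  paths <- c(fig1b = file.path(config$out_dir, "fig1b.tsv"),
             fig2a = file.path(config$out_dir, "fig2a.tsv"),
             fig2b = file.path(config$out_dir, "fig2b.tsv"),
             fig3 = file.path(config$out_dir, "fig3_matrix.tsv"),
             enrichment = file.path(config$out_dir, "enrichment.tsv"))
  write_spectrum(suppressWarnings(arginine_codon_shares(arg)),
                 paths["fig1b"])
  write_spectrum(
    suppressWarnings(base_change_spectrum(ann, config$orientation, TRUE)),
    paths["fig2a"])
  write_spectrum(suppressWarnings(strand_spectrum(ann)), paths["fig2b"])
  mat <- suppressWarnings(aa_by_source_codon(arg, config$orientation))
  mat_df <- as.data.frame.matrix(mat$counts)
  mat_df <- cbind(source_codon = rownames(mat$counts), mat_df)
  utils::write.table(mat_df, paths["fig3"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_spectrum(suppressWarnings(transition_enrichment(arg, ann, nc)),
                 paths["enrichment"])
  .stage_log("spectrum: %d coding, %d arginine, %d noncoding records",
             nrow(ann), nrow(arg), nrow(nc))
  invisible(paths)
}

.stage_controls <- function(config) {
  ann <- deduplicate_records(.read_stage_tsv(config, "annotated.tsv"))
  nc <- deduplicate_records(.read_stage_tsv(config, "noncoding.tsv"))
  paths <- c(coding = file.path(config$out_dir, "coding_control.tsv"),
             silent = file.path(config$out_dir, "silent_control.tsv"),
             noncoding = file.path(config$out_dir, "noncoding_control.tsv"))
  write_control(suppressWarnings(coding_control(ann)), paths["coding"])
  write_control(suppressWarnings(silent_control(ann)), paths["silent"])
  write_control(suppressWarnings(noncoding_control(nc)), paths["noncoding"])
  .stage_log("controls: %d coding, %d noncoding records", nrow(ann),
             nrow(nc))
  invisible(paths)
}

.stage_skew <- function(config) {
  ann <- .read_stage_tsv(config, "annotated.tsv")
  drivers <- if (!is.null(config$driver_list)) {
    read_driver_genes(config$driver_list)
  } else character(0)
  report <- detect_skewed_genes(ann, min_fraction = config$min_fraction,
                                min_samples = config$min_samples,
                                driver_genes = drivers)
  path <- file.path(config$out_dir, "skew_report.tsv")
  write_skew_report(report, path)
  .stage_log("skew: %d skewed gene(s)", nrow(report))
  invisible(c(skew = path))
}

.stage_all <- function(config) {
  paths <- .stage_space(config)
  have_csv <- !is.null(config$mutations_csv) &&
    file.exists(config$mutations_csv)
  if (!have_csv) {
    paths <- c(paths, .stage_simulate(config))
  }
  c(paths,
    .stage_annotate(config),
    .stage_spectrum(config),
    .stage_controls(config),
    .stage_skew(config))
}
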