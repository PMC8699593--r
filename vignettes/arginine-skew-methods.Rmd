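---
title: "Codon-level mutation spectra and arginine substitution skews: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-level mutation spectra and arginine substitution skews: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Somatic mutation catalogues report point mutations as genomic events:
chromosome, position, reference and alternate allele on the plus strand.
Most questions about protein-level consequences, however, live at the codon
level: which codon was hit, at which of its three positions, and which
residue the change produced. `argskew` closes that gap for the analysis of
*arginine substitution bias* — the long-standing observation that arginine
is the most frequently substituted residue in tumors, with outcomes heavily
concentrated on histidine, cysteine, glutamine and tryptophan.

The mechanistic reading is a two-stage ("sequential") selection process.
First, the dominant somatic mutational signature — C>T transitions and
their G>A mirror, largely from deamination of methylated CpG — acts at the
nucleotide level. Because four of the six arginine codons (CGA, CGG, CGT,
CGC) start with C and all six carry a G at the second position, this
signature canalizes arginine codons toward a small set of reachable
outcomes before any selection on the protein acts. Second, purifying
selection at the amino-acid level removes outcomes that are not tolerated,
sharpening the skew. The package quantifies the first stage exactly (it is
pure genetic-code combinatorics plus counting) and provides the detection
machinery for per-gene skews; it deliberately models no selection itself.

## The substitution space of a codon family

Any codon admits exactly 9 single-nucleotide substitutions (3 positions ×
3 alternative bases). For the six arginine codons this gives a 54-change
space which `substitution_space()` enumerates and classifies exhaustively:
18 synonymous changes, 34 missense changes reaching 12 distinct residues,
and 2 nonsense changes (both from CGA>TGA-type events). Two structural
facts about this space matter downstream:

* Arginine (with leucine) is one of only two residues whose codon family
  spans two first-base blocks (AGR and CGN), so first-position changes can
  be synonymous — for AGA, AGG, CGA and CGG.
* The transition routes out of the CGN codons are asymmetric: first-position
  C>T yields Trp (CGG), Cys (CGT, CGC) or stop (CGA); second-position G>A
  yields His (CGT, CGC) or Gln (CGA, CGG). This is the combinatorial core of
  the canalization argument.

All classification is against the standard genetic code (NCBI table 1,
DNA alphabet), taken from `Biostrings::GENETIC_CODE` as the single source
of truth. Base-change labels are always derived from the code itself; for
example AGA>ATA is a G>T change, whatever residue bookkeeping might
suggest. Event order is deterministic (position ascending, then alternate
base alphabetical) so exported tables are byte-stable.

## Codon-level annotation

`annotate_mutations()` maps each record through a gene model (ordered CDS
intervals with GFF3 phase) into a codon-level event:

1. The genomic position is converted to a coding-sequence coordinate in
   transcription order; the phase of the first interval is subtracted, so
   bases in a phase overhang or a trailing partial codon are routed to the
   noncoding stream rather than mis-framed.
2. The containing codon's three genomic coordinates are recovered — as two
   sub-ranges when the codon spans an intron boundary — and its bases read
   from the reference, complemented for minus-strand genes so the triplet
   is in translation order.
3. Alleles in the input are always plus-strand; they are complemented
   exactly once, here, for minus-strand genes. This single conversion point
   is a deliberate design guard against double-complement bugs.
4. The alternate codon is built by substituting at the in-codon offset and
   classified (synonymous / missense / nonsense, transition flag) by the
   genetic-code module.

Records are partitioned into three exhaustive streams — annotated,
noncoding (no model, wrong chromosome, outside CDS), and reference-mismatch
(excluded, counted, warned about, never fatal: heterogeneous catalogue
exports routinely contain a few such rows). The count identity
`input = annotated + noncoding + mismatched` is asserted in the tests.
When the input carries a protein-change string (`p.R132H` style) it is
compared against the computed event and discordances are flagged rather
than silently trusted.

The annotation path is validated against an independent oracle that
re-translates the *entire* wild-type and mutant CDS with
`Biostrings::translate` and diffs the two proteins — a deliberately
different route from the per-codon arithmetic. The validation suite runs
this on 1000 generated genes with mixed strands and intron-split codons
(the whole check runs in seconds at these sizes).

Transcript handling is minimal by design: one model per gene symbol, first
wins with a warning. Isoform selection, indels, MNVs and splice effects are
out of scope.

## Spectra and controls

`base_change_spectrum()` tabulates the 12 ordered base changes (`A>C` …
`T>G`) or, folded, the 6 pyrimidine-centric classes used by mutation
catalogues; folding sums each purine-initiated category with its reverse
complement and conserves totals. Two orientations are supported, because a
mutation table fixes alleles to the genomic plus strand while codon logic
lives on the coding strand:

* **coding** (default for figure-facing outputs): alleles of minus-strand
  genes are complemented, so categories align with the codon chemistry
  (a CGA>CAA event is G>A regardless of gene strand);
* **genomic**: alleles as given, the natural frame for noncoding records
  and for strand-bias questions.

`strand_spectrum()` reports per-gene-strand C>T and G>A frequencies and
their ratio — a transcriptional strand-bias statistic that should sit at 1
under a strand-symmetric mutational process. `arginine_codon_shares()`
compares each arginine codon's share of observed mutations against a
reference codon-usage profile; the packaged default is a qualitative human
profile (AGA, AGG, CGG, CGC ≈ 20% each; CGA, CGT ≈ 10%) and should be
replaced by measured usage when available. `aa_by_source_codon()` is the
central cross-table: source codon × outcome (target residues, plus explicit
`silent` and `stop` columns), with a companion 12-category nucleotide
spectrum of the same records.

Three control tables mirror standard practice: a **coding control** (every
coding point mutation attributed to the residue it *resulted in*; silent
records keep their own residue, nonsense records go to a separate `stop`
category — the most literal reading of "mutations that resulted in that
residue"; attributing by source residue instead was considered and
rejected), a **silent coding control** (synonymous records only), and a
**noncoding control** (12-category spectrum of records outside any CDS).
`transition_enrichment()` compares C>T and G>A shares across the arginine,
all-coding and noncoding streams, and reports both the `C>T + G>A`
aggregate and the all-transitions aggregate, since "transition enrichment"
is quoted both ways in the literature.

Percentages are kept at full precision internally and rounded to two
decimals only at serialization.

## Skew detection

A gene is called *skewed* when at least 60% of its missense arginine
substitutions produce one and the same residue, supported by at least 40
distinct samples. Three readings of this criterion were genuinely open and
are fixed as follows:

* **Denominator**: missense arginine records only. Synonymous and nonsense
  changes produce no substituted residue, so "substitutions produced one
  amino acid" cannot count them.
* **Supporting samples**: distinct samples carrying the *dominant-residue*
  substitution, since the support requirement qualifies the skew itself.
  The total number of samples with any missense arginine record in the
  gene is also reported, so the alternative reading remains computable.
* **Ties**: an exact tie for the dominant residue is never skewed (two
  residues at 60% each is arithmetically impossible; at any tie each
  candidate is at most 50%). The lexicographically first residue is
  reported for determinism and the tie is flagged.

Counting is per unique event `(sample, chromosome, position, alt allele)` —
catalogue exports can list one mutation several times (per transcript or
study), and de-duplicating is the conservative choice. Both thresholds are
exposed (`min_fraction`, `min_samples`) and the report carries the dominant
nucleotide change (12 categories, coding orientation) with its fraction,
per-target counts for the four recurrent outcomes, and a driver flag taken
from a user-supplied gene list (driver classification itself is an input,
not a computation).

## The synthetic study generator

`simulation_config()` + `simulate_study()` produce a fully self-contained
study — reference FASTA, GFF3 gene models, a COSMIC-like mutation CSV and a
ground-truth manifest — so every pipeline stage is testable without
external downloads. The generator emulates:

* **Gene structure**: non-overlapping genes on one synthetic chromosome
  (default 30 genes × 100 sense codons plus a stop), a configurable
  fraction on the minus strand (default 0.4), and a fraction with an
  intron placed mid-codon (default 0.3), so phase handling and intron-split
  codons are always exercised. Arginine codons are seeded at 8% of sense
  codons (near the human proteome's arginine frequency) with usage drawn
  from the default profile above; other positions draw uniformly from the
  remaining sense codons.
* **Mutation load**: per-sample counts are Poisson (default mean 15 over
  300 samples) — the simplest defensible count model; real tumor loads are
  heavy-tailed, which this deliberately does not capture.
* **Signature**: a 12-category plus-strand signature; the default places
  28% each on C>T and G>A, 7% on the other two transitions, and spreads 30%
  over the eight transversions, matching the qualitative shape of
  pan-cancer spectra. A category is realized only at reference sites
  carrying its source base, so emitted records always match the reference
  (zero mismatches downstream, asserted in tests). Because categories are
  drawn first and sites second, the realized category distribution is
  exactly multinomial in the signature — which is what makes the
  recovery tests sharp.
* **Injected skews**: each `skew_spec(gene, residue, fraction, carriers)`
  places the specific codon change that yields the target residue in the
  stated number of distinct carrier samples, then adds balancing
  other-residue records (or further dominant records) until the realized
  dominant fraction is at least, and close to, the requested one. A spec
  targeting a residue unreachable from the gene's arginine codons fails
  fast, naming the reachable set. The manifest records realized fractions
  and carrier counts exactly as emitted.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: trinucleotide (96-channel) context, tissue- or
replication-timing-dependent signature variation, transcriptional strand
asymmetry, selection of any kind, transcript isoforms, indels, and
realistic gene/intergenic architecture. In particular, under the default
signature roughly half of simulated arginine missense outcomes land on
His/Cys/Gln/Trp (recomputed by `scripts/acceptance.R` as
`arg_top4_residue_share_pct`): the nucleotide signature alone canalizes
strongly, but the >75% concentration reported in real tumors requires the
amino-acid-level selection this simulator intentionally omits. The gap
between those two numbers is the quantity the two-stage model attributes
to purifying selection.

## Numerical and validation choices

* Seeds are mandatory; one seed drives reference construction and (offset
  by one) mutation placement. Identical config + seed gives byte-identical
  FASTA, GFF3, CSV and manifest.
* Recovery tests compare sampled percentages to their targets within 3
  binomial standard errors — strict enough to catch systematic errors,
  loose enough to be seed-robust.
* Validation problem sizes were chosen to make those standard errors
  small at desk scale: 100,000 records for signature and strand-balance
  recovery; 20 seeded replicates of ~78,000 records (25 genes, 1200
  samples) for skew recovery, with a uniform signature so background genes
  have no residue skew of their own and sensitivity/false positives are
  well defined against the manifest; 1000 genes for the translation-oracle
  equivalence check.
* Empty inputs yield empty tables with a warning (or an empty report), not
  errors; degenerate streams in ratio tables produce `NA` ratios with a
  flag.

## Limitations

Beyond the simulator's stated non-goals: the skew criterion is a threshold
rule, not a significance test (no multiple-testing control — by design, to
keep the detector faithful to the published criterion); per-tissue
stratification is absent because the input schema carries no tissue field;
and the mutation CSV dialect is a minimal mirror of a catalogue export, so
richer exports must be mapped to it before use.
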