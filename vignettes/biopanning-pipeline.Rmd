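---
title: "Biopanning display-library sequence analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biopanning display-library sequence analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopanr)
```

## The problem

Bacterial surface-display biopanning screens a library of ~10^10 cells,
each displaying a random 15-mer peptide on an engineered outer-membrane
scaffold (eCPX), for binders to a target surface such as gold. After each
sorting round the enriched population is amplicon-sequenced: the display
peptide's coding region sits between fixed nucleotide anchors — a
precursor (`GGCCAGTCTGGCCAG`, translating to GQSGQ) and a postcursor
(`GGCTCGAGC`, translating to GSS) — inside an Illumina-style read. The
analysis questions are: which reads carry an intact displayed peptide,
how does the amino-acid composition of the displayed population shift
from round to round, and which residues, fragments and whole sequences
dominate the enriched pool. A companion set of statistics characterizes
the magnetophoretic sorting device itself from colony counts.

This package implements that pipeline end to end, together with a seeded
synthetic read generator. The experiment's own reads are not publicly
deposited, so the generator is not a convenience but the package's
measurement instrument: it produces libraries with *known* composition,
length mixture and corruption rates, and every downstream stage is
validated by how accurately it recovers those knowns.

## Insert extraction and validity classes

For each read, extraction searches the forward sequence for the first
precursor occurrence, then for the first postcursor occurrence after it,
and takes the substring strictly between them. If the forward strand has
no such anchor pair the reverse complement is searched (disable with
`anchor_config(search_both_strands = FALSE)`); a read matching both ways
is resolved as forward. Matching is exact by default; `max_mismatches`
relaxes it per anchor, which switches the matcher from fixed-string
search to `Biostrings::vmatchPattern`.

Each read receives exactly one validity class, decided in a fixed
priority order:

| class | condition |
|---|---|
| `no_anchor` | no precursor/postcursor pair on either strand |
| `blank` | empty insert (anchors adjacent) |
| `frame_shift` | insert length not a multiple of 3 |
| `stop_codon` | in-frame stop in the translation |
| `unknown_residue` | untranslatable codon (e.g. containing N) |
| `valid` | everything else; the peptide is reported |

Stop codons outrank unknown residues when both occur. Translation uses
the standard codon table via `Biostrings::translate` with
`no.init.codon = TRUE`: the default initiator handling would silently
turn a leading TTG or CTG codon into methionine, which is wrong for an
internal insert. Only valid peptides of exactly 15 residues enter the
frequency and motif analyses; `length_distribution()` reports what that
restriction discards.

## Composition analytics

`composition()` accumulates the total occurrence of each of the 20 amino
acids over all selected 15-mers and normalizes by the total residue
count, so frequencies sum to 1 regardless of library depth. It also
keeps the raw 20 x 15 residue-by-position count matrix (positions
numbered 1..15 from the N-terminus). `class_aggregate()` folds the
frequencies into five chemical categories. The membership of those
categories is a convention the analysis must fix; the default places
histidine with the polar residues:

```{r}
aa_class_scheme()
```

The scheme is data, not code: `read_class_scheme()` loads an alternative
partition from YAML (a template ships in `inst/extdata/`).

`compare_rounds()` reports per-residue differences between each round and
the first profile in *percentage points* (100 x difference of
fractions). Points rather than relative percent is the natural scale
here: a shift described as "histidine 5.5% higher in round 4" composes
additively with printed per-round values like 4.9% -> 6.6% for glycine.

No significance machinery is attached. The round-level comparison is
descriptive — the pipeline reports frequencies and deltas, not p-values —
because the sampling unit (a sequenced read) is not an independent draw
from the displayed population once rounds of growth and selection have
amplified clones.

## Motif-level statistics

`kmer_fragments()` tallies sliding windows (12 per 15-mer at the default
k = 4). `rank_sequences()` counts exact peptide occurrences and orders
by count with a lexicographic tie-break, so rankings are reproducible
across runs and platforms. `overlap_peptides()` intersects two peptide
sets (e.g. NGS top-100 vs Sanger-sequenced isolates), deduplicated, in
first-set order.

The pairwise co-occurrence matrix needs a counting rule, and the choice
is genuinely open. The default counts unordered *position pairs* within
each 15-mer: a peptide with n_a copies of residue a and n_b of residue b
contributes n_a x n_b to cell (a, b) and C(n_a, 2) to the diagonal, so
every sequence contributes exactly C(15, 2) = 105 counts and the matrix
mass is 105 x n. This rule is position-free (permuting residues within a
peptide changes nothing) and mass-conserving, which makes it easy to
validate and to normalize. The alternative presence/absence rule —
count a pair once per sequence containing both residues — is available
as `cooccurrence(mode = "presence")`; it answers "how often do a and b
co-occur at all" rather than "how much pair mass do they share", and the
two can rank pairs differently when a residue's counts are concentrated
in few sequences.

Whole-sequence logo rendering is delegated to existing tools;
`position_frequency_matrix()` emits the standard input for them.

## Separation-efficiency statistics

`separation_efficiency()` is `collected / injected`: the fraction of
cells flown through the device that are recovered from the collection
outlet. Two reporting conventions matter for reproducing printed
summaries from raw counts:

- the integer percent **truncates** (2.3e8 / 3.3e8 = 69.69...% prints as
  69%, matching "about 69%" statements derived from such counts);
- `fold_ratio()` divides *unrounded* fractions and then rounds half-up
  to one decimal (0.697 / 0.294 = 2.371 -> 2.4).

`replicate_summary()` gives per-strain, per-flow-rate means and sample
standard deviations of the efficiency fractions, for triplicate-style
measurement tables.

## The synthetic read generator

`generate_fastq()` emits single-end reads of 151 nt (iSeq-style) built
as random flank + precursor + insert + postcursor + random padding, plus
a per-read ground-truth table (intended class, peptide, insert, strand).
Design choices:

- **Single reads, not pairs.** The anchored region at the longest
  default insert (15 aa = 69 nt with anchors) fits comfortably in one
  151 nt read, so paired-end emission and merging are out of scope.
- **Corruption events are mutually exclusive**, resolved blank >
  frame shift > stop codon > ambiguous base. Independent per-event
  uniforms are drawn and the highest-priority event wins; with a single
  nonzero rate the realized class probability equals that rate, which is
  what the filter-recovery checks measure. A frame shift is the minimal
  event producing its class: one +/-1 nt indel at a uniform insert
  position. A read whose sampled insert length is 0 is recorded as
  `blank` whatever else was drawn, since an empty insert can hold
  neither a stop codon nor an indel.
- **Anchor unambiguity by construction.** A random 45 nt insert contains
  the 9 nt postcursor with probability ~1.4e-4, which at library scale
  would create reads whose extracted insert differs from the intended
  one. The generator rejection-samples: any read whose emitted sequence
  does not extract back to exactly the intended insert on the intended
  strand is redrawn (same intended class, length and strand). The
  conditioning excludes anchor-containing inserts, a composition bias
  of order 1e-5 — two orders of magnitude below the 5-sigma binomial
  bands used everywhere — accepted in exchange for an exact per-read
  oracle.
- **Determinism.** All randomness flows from one seeded stream;
  identical configurations produce byte-identical FASTQ. The caller's
  RNG state is saved and restored.
- **Quality is constant Q37.** The pipeline never reads quality, so no
  error/quality model is fitted; substitution errors, PCR duplicates and
  chimeras are out of scope.

What the generator does *not* emulate about real data: sequencing error
inside anchors (real pipelines lose such reads to `no_anchor`;
`max_mismatches` exists to probe that sensitivity), codon-usage bias
(synonymous codons are uniform), clone-amplification structure
(duplicate peptides appear only by chance), and any correlation between
residues within an insert. Passing recovery tests therefore demonstrates
that the pipeline measures what it claims on i.i.d.-composition
libraries; it does not certify behaviour under instrument-specific
artifacts.

## Problem sizes and tolerances

Recovery checks run at 200,000 reads, where the 5-sigma binomial
half-width on a residue fraction of 0.05-0.12 is 0.06-0.10 percentage
points — tight enough to detect a miscounted class or an off-by-one in
the window arithmetic, while a single library simulates in well under a
minute. Filter-rate checks use 20,000 reads per setting; chi-square
composition fidelity uses 100,000 reads at alpha = 0.001. Exact
(non-stochastic) checks — anchor translation identities, co-occurrence
mass 105 x n, k-mer mass 12 x n, brute-force equivalence on <= 20
peptides, byte-identical regeneration — run at small n. The numbered
scripts under `analysis/` run three 50,000-read libraries with all
corruption classes switched on.

## Known limitations

- First-occurrence anchor semantics are a stated convention; a read with
  a spurious earlier precursor copy (possible in real data, excluded by
  construction in synthetic data) would yield a longer, likely invalid
  insert rather than a recovery of the true one.
- `max_mismatches > 0` matches each anchor independently; it does not
  model indels inside anchors.
- The co-occurrence and ranking statistics treat reads as the unit of
  counting; no clone collapsing or abundance correction is attempted.
- Chemical-class percentages inherit whatever partition the scheme
  fixes; comparisons across schemes are not meaningful.
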