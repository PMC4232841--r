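---
title: "Detecting translated splice variants: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting translated splice variants: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceptide)
```

# The problem

Shotgun proteomics identifies peptides by matching spectra against a protein
database; what is not in the database cannot be found. Splice isoforms are
chronically under-represented in curated proteomes, so evidence that an
alternative-splicing event (ASE) is actually translated is usually lost.
`spliceptide` implements the database-augmentation strategy: apply
transcriptome-derived splice events to reference transcript models, predict
each variant's protein ab initio, merge the tagged variants with the
reference proteome, and classify externally identified peptides as
event-supporting when they are explicable only by a variant entry.

This vignette documents the models and conventions the package commits to,
the tunable parameters, what the synthetic data emulate, and the places
where the design was genuinely open.

# Transcript and event model

A `transcript()` is an ordered list of exon sequences plus the intervening
introns, with an annotated CDS on the spliced mRNA. All coordinates are
0-based and half-open in spliced-mRNA space; genome-backed input (GTF +
genome FASTA) is converted at load, with minus-strand transcripts
reverse-complemented, so every downstream computation has a single
coordinate convention.

Simple events are typed: exon skipping (a contiguous 0-based inclusive exon
range), alternative 3'/5' splice sites (a signed shift in nucleotides;
negative acceptor and positive donor shifts grow the transcript into the
intron, the opposite signs truncate the exon), and intron retention.
Dual-specificity splice sites remain in the taxonomy and in every frequency
table, but no generator exists for them: they are extremely rare and
essentially confined to untranslated regions, so a zero row is the expected
output. Combined events hold two or more simple events on one transcript.

Two conventions here were design choices rather than forced moves:

* **Combined events are applied jointly in a single pass** over the
  exon/intron block list. Sequential application on remapped coordinates
  would make the result depend on constituent order; the single pass is
  order-free by construction, and the test suite cross-checks it against an
  independent per-base inclusion oracle.
* **Constituents must not claim overlapping transcript regions.** A skip
  claims its exons (and interior introns), a splice-site shift claims the
  facing exon end plus the adjoining intron side, retention claims the whole
  intron. Adjacent claims are legal — two adjacent single-exon skips are
  exactly the two-exon skip — and a donor extension plus an acceptor
  extension may tile one intron completely, but never overlap inside it.
  Whether combined events may share an exon at all is not observable from
  the event catalogues the package was designed around; the non-overlap rule
  is the conservative reading, and invalid combinations are reported as
  data (violations), never exceptions.

Variant bookkeeping matters more than the variant sequence itself: each
application returns a strictly monotone partial map from reference to
variant coordinates (deleted positions unmapped) and the list of modified
regions — inserted material as real intervals, pure-deletion junctions as
zero-length intervals. The zero-length marks exist so that the TIS logic
can ask "does a codon span the lesion?" even when the lesion has no
sequence of its own.

# ORF prediction and translation

Variant proteins are predicted ab initio as the **largest ATG-initiated
ORF** of the variant mRNA. Length is counted in nucleotides including the
stop codon; ties go to the 5'-most ATG, matching the behaviour of
conventional longest-ORF finders and favouring canonical starts. Initiation
is restricted to ATG throughout — near-cognate starts exist in vivo but are
out of scope here.

Open-ended ORFs (no stop codon before the sequence end) are excluded by
default (`allow_open_ended` in `sp_config()`): the inputs are intended to be
full-length transcript models, and a credible full-length mRNA encodes a
complete ORF. The flag exists because the opposite convention is defensible
for fragment-derived models.

Translation uses the standard genetic code (the table shipped with
Biostrings). Codons containing N translate to X, and an N-containing codon
never terminates an ORF — only literal TAA/TAG/TGA do. This keeps ingestion
permissive (assembly Ns are tolerated) while keeping ORF extension
deterministic.

Products identical to the template's annotated protein are dropped: an
event confined to untranslated sequence produces no proteomic signal and
would only inflate the database. Exact duplicate variant sequences are
de-duplicated (the lexicographically first event id survives; the merged
ids are retained in the build report), so the variant set is non-redundant
at the sequence level. Collisions between a variant and a reference
sequence are kept on both sides — accession-level classification must still
work — and flagged. Reference proteome headers pass through verbatim.

# Digestion and uniqueness

Trypsin is modelled with **no proline restriction**: cleavage after every K
and R, including K/R–P bonds. Defaults are at most two missed cleavages and
a minimum peptide length of seven residues — the same parameters a typical
search configuration uses, and the parameters under which "variant-unique"
is defined. The uniqueness test is membership in the reference
**tryptic-peptide universe**: a peptide supports an event when it occurs in
the variant's digest but nowhere in the digest of the whole reference
proteome. The pipeline-level classifier additionally rejects peptides that
occur as plain substrings of the variant's own template protein, which
guards against coincidental semi-tryptic matches around the lesion; the
same guard is available (off by default) in `variant_unique_peptides()`.

Initiator-methionine handling is explicit. Searches commonly allow
N-terminal processing, so a protein's position-2 peptide can be observed
with the Met removed. `detect_nterminal()` therefore accepts residue 2 of a
Met-initiated protein as N-terminal by default. Digestion and indexing of
Met-removed forms, however, default **off** (`nterm_met_cleavage`): with
the flag on, every Met-initiated reference protein contributes extra
N-terminal forms to the universe, and the package's reference behaviour is
the plain tryptic digest. Ile/Leu folding (`il_equivalence`) is likewise
available and off by default: mass spectrometry cannot distinguish the two,
but folding them coarsens uniqueness, so it is a deliberate opt-in.

# Calling support and classifying TIS

Identified-peptide tables are consumed in the `peptides.txt` dialect
(`Sequence`, `Proteins`, `Score`, `Intensity`, `Reverse`,
`Potential contaminant`; any TSV with a `Sequence` column works). Decoy and
contaminant rows are removed first, and the removal counts are retained.

Support calling is two-staged, and the stages are ordered deliberately:
protein-group evidence outranks recomputation. A peptide listed with any
reference accession is rejected even if its sequence happens to be absent
from the reference digest — the engine that produced the table saw it in a
protein group, and that evidence wins. Only when no accession list is
present is stage 1 recomputed by locating the peptide in the database.
Peptides matching several variant entries are attributed to every matching
event and flagged as shared rather than silently assigned to one.

A supported event whose evidence includes an N-terminal peptide is an
alternative-TIS event. Let `r` be the image of the reference start codon
under the event's coordinate map and `s` the variant's actual start:

* **C (upstream)**: `r` is mapped and `s < r`.
* **A (downstream)**: `s > r` (or `r` was deleted) and the variant-specific
  amino-terminal span does not intersect the event's modified regions.
* **B (start affected)**: the remaining case — the event itself overlaps
  the new amino terminus (a codon spanning a zero-length junction counts).

The "variant-specific amino-terminal span" is the codon range from `s` to
the first residue from which variant and reference agree through their
C-termini, computed as the longest common suffix of the two proteins. A
full pairwise alignment could define the same resynchronization point, but
the suffix formulation is deterministic, independent of gap scoring, and
exact for this taxonomy's cases, so it is the committed definition.

Two flags accompany the category. `first_atg_downstream` asks whether `s`
is the 5'-most ATG at or after the 3'-most modified-region boundary; the
scan is frame-agnostic by default because the underlying question ("was the
first available start used?") does not presuppose a reading frame, and a
frame-restricted variant is available (`first_atg_in_frame`).
`wilson_model` formalizes the amino-terminal-isoform model — event and
alternative start jointly producing proteins that differ only at their
amino end — as a machine-checkable conjunction: the event's net length
change within the reference CDS is a multiple of three, and the two
proteins are identical from the first residue encoded past the event
through their C-termini. `orf_disrupting` is its complement. The original
description of such cases relied on visual inspection of alignments; the
conjunction above is the only reading of "isoforms that differ at their
amino end" that a program can evaluate, and it is applied uniformly.

Merging result sets from different engines is a union keyed by event id
(peptides and engine labels unioned, better scores kept), with the
inclusion–exclusion summary `|a ∪ b| = |a| + |b| − |a ∩ b|` reported
alongside. Frequency tables count simple events per type with integer
percentages, rounded half up, over the simple-event total; combined events
are tallied separately as complex. Rounding half up is a commitment rather
than a discovery: published tables of this kind are not always consistent
with any single rounding rule, and the package needs one.

# Alignment reports

Each supported event can be rendered as a global alignment of reference
versus variant protein with identified peptides marked — reference-supported
peptides on the reference row, variant-specific peptides on the variant row
— in 60-column blocks, as plain text or HTML. The aligner is
Needleman–Wunsch with affine gaps (match +1, mismatch −1, first gap residue
−5, each further −1) and a fixed traceback preference (diagonal, then gap
in the variant, then gap in the reference). The scoring values are
package-defined: nothing in the problem dictates them, but fixing them —
and the traceback — makes every report byte-stable, which the test suite
asserts by rendering twice.

# Synthetic data and what the tests mean

The generator exists so the entire pipeline is testable with no external
data, and its defaults are the package's study conditions rather than knobs.
Genes have 2–10 exons of 30–120 nt with introns of 9–60 nt (intron
retention must be able to preserve frame or break it, so intron lengths are
not multiples of three by construction of the sampler); an ATG is written at
a sampled CDS start, premature in-frame stops are recoded, and a stop codon
is placed in the final exon, so every gene's annotated CDS translates
cleanly. Event types are sampled at 35/29/25/11 percent
(skipping / alt 3' / alt 5' / retention) — the proportions such events show
in transcriptome-wide catalogues — and the default study makes roughly half
of all events combined, matching the observation that about half of
alternative transcripts carry more than one event. Support counts are
sampled at ≥ 2 expressed sequences, the catalogue's own reporting
threshold, which is also the database builder's default inclusion filter.

Ground truth is computed by an **independent oracle**: event application by
per-base inclusion flags over the pre-mRNA, ORF finding by naive
position-by-position scanning, translation by a plain codon loop, digestion
by brute-force enumeration of all start/end pairs. None of this code is
shared with the engines it validates; agreement between the two paths on
every generated case is itself one of the strongest tests in the suite.

The `tis-rich` preset engineers gene/event pairs so all three TIS
categories occur in force: a skipped start exon with an out-of-frame
restart ATG downstream (category A), a retained CDS intron carrying its own
ATG (category B), and a retained 5'-UTR intron whose ATG extends the
protein upstream in frame (category C). ATGs outside the engineered ones
are scrubbed so the largest-ORF choice is determined by construction.

Simulated observation emits each distinct tryptic peptide of the database
with a configurable detection probability, honest accession lists, and
log-normal intensities (median 10^7, one log10 unit of spread — several
orders of magnitude, as real peptide intensity distributions span), plus
flagged decoy and contaminant rows. Intensities and scores are plumbing for
the report columns; classification never reads them.

What passing tests show — and do not show. With full detection and zero
noise, the pipeline recovers exactly the planted events whose truth lists at
least one variant-unique peptide, with matching categories and flags, at
n = 200 genes. That validates the logic end to end. It does not emulate
incomplete detection, fragmentation quality, FDR behaviour in large search
spaces, shared peptides across paralogs, or modified peptides; conclusions
about real-data sensitivity do not follow. One structural fact the
synthetic study does expose is worth stating: a variant that restarts
in-frame downstream and is therefore an exact suffix of its template can
have **no** variant-unique tryptic peptide once template substrings are
guarded against — its evidence, if any, must come from the reference side
of the alignment. The category-A generator therefore plants out-of-frame
restarts, which is also the configuration the downstream-TIS cases
described in the literature predominantly show.

# Numerical and degenerate-input choices

* Coordinates are validated eagerly; `validate_event()` returns violations
  as data and never throws on well-typed input.
* `enumerate_orfs` on a sequence with no ATG returns an empty table;
  `largest_orf` then returns `NULL`, and database construction counts the
  event under `no_orf`.
* An empty frequency table divides nowhere: percentages are `NA`, not
  `NaN`.
* Determinism is treated as an output contract: database FASTA (uppercase,
  60-column wrap, variants ordered by event id, then reference records in
  input order), event-record TSV, and alignment reports are byte-identical
  across runs with equal seeds. All generator randomness flows from a
  single integer seed through a fixed derivation, and the generator
  restores the caller's RNG state.

# Problem sizes

The shipped tests run the oracle-equivalence sweeps at 500 random
transcript/event pairs, 1,000 random sequences (≤ 2 kb) for the ORF engine,
and 500 random proteins (≤ 200 aa) for digestion; the end-to-end study uses
200 genes with one event each. These sizes give full coverage of the
combinatorics (every event type, every TIS category, shared and duplicated
peptides) while keeping a complete check of the package fast enough to run
on every change.

# Known limitations

* Dual-specificity events are classified and counted but never generated.
* FDR estimation, spectral scoring and engine-internal filters are out of
  scope; the package consumes already-filtered identification tables.
* Uniqueness is exact string membership (optionally I/L-folded); it does
  not model mass-equivalent substitutions beyond I/L.
* The Wilson-model flag is a structural criterion; borderline cases a human
  might accept from an alignment (e.g. a single conservative substitution
  in the shared region) are scored as disrupting.
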