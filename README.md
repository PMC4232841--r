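# spliceptide

Proteogenomic detection of alternative-splicing events (ASEs) in shotgun
proteomics data.

Standard protein databases under-represent splice isoforms, so peptides from
rare variants are invisible to a conventional search. `spliceptide`
implements the complementary strategy: modify reference transcript models
with splicing events observed in transcriptome data, translate each variant
mRNA ab initio, merge the tagged variant proteins with the reference
proteome, and then ask — for every peptide a search engine identified —
whether it can only be explained by a variant entry. Such variant-unique
tryptic peptides are evidence that the splicing event is translated.

The package is aimed at proteogenomics practitioners who have (a) reference
transcripts, (b) a catalogue of splice events (exon skipping, alternative
3'/5' splice sites, intron retention, and combinations of these), (c) a
reference proteome FASTA, and (d) peptide identification tables
(`peptides.txt`-style TSV from a probabilistic or de novo engine).

## The method in brief

For a transcript with exons `e_0..e_n` and annotated CDS, an event edits the
exon/intron block structure (e.g. skip exons `i..j`, retain intron `k`,
shift an acceptor/donor by `s` nt). The variant protein is the translation
of the **largest ATG-initiated ORF** of the edited mRNA (nucleotide length,
stop codon included; ties to the 5'-most start). Records whose product
equals the reference protein are discarded; the rest are tagged

```
REFSEQ_NAME# (EVENT_TYPE:EVENT_ID)
```

and concatenated with the untouched reference proteome.

Peptide-level calling digests every protein with trypsin (no proline
restriction, ≤ 2 missed cleavages, ≥ 7 residues) and applies a two-stage
filter: (1) protein-group evidence — any reference accession on the
peptide's protein list rejects it; (2) the peptide must be absent from the
reference tryptic-peptide universe and not a substring of the variant's own
template protein. Supporting peptides that sit at a variant's N-terminus
(residue 1, or residue 2 after initiator-Met removal) mark an **alternative
translation-initiation site (TIS)**, classified as:

* **A** — the variant initiates downstream of the reference start and its
  novel amino-terminal span is clear of the event's footprint;
* **B** — as A, but the event directly overlaps the new amino terminus;
* **C** — the variant initiates upstream of the reference start.

Additional flags report whether the new start is the first ATG downstream of
the event and whether the pair fits the amino-terminal-isoform (Wilson)
model: a frame-preserving event with proteins identical from the first
residue past the event to their C-termini.

## Worked example

```r
library(spliceptide)

t <- transcript("T1", exons = c("ATGGCA", "GAATTC", "TAA"),
                introns = c("GT", "AG"), cds_start = 0, cds_end = 15)
e <- splice_event("E1", "T1", "EXON_SKIP", list(skip_from = 1, skip_to = 1))
vp <- predict_variant_protein(t, e)
vp
#> <variant_protein> T1# (ES:E1) (2 aa, TIS at mRNA offset 0)
vp$sequence            # "MA"   (reference protein is "MAEF")

idx <- build_peptide_index(c(ref1 = "MAAEEFFKGGHHIIKLLMMNNR"))
variant_unique_peptides("MAAKGGHHIIKLLMMNNR", idx)$sequence
#> [1] "MAAKGGHHIIK"        "MAAKGGHHIIKLLMMNNR"
```

The first call composes the splice engine, ORF finder and translator:
skipping the middle exon truncates the reading frame after two residues, so
the record enters the database as `T1# (ES:E1)`. The second call shows the
uniqueness logic: of the variant's six tryptic peptides, only the two
spanning the novel junction are absent from the reference digest — those are
the peptides whose identification would support the event.

A complete synthetic study (genes, events, reference proteome, simulated
peptide table, ground truth) is one call:

```r
fx  <- generate_fixture_set(seed = 1, n_genes = 200, preset = "tis-rich")
db  <- build_database(fx$transcripts, fx$events, fx$reference_proteome)
idx <- build_peptide_index(fx$reference_proteome)
obs <- simulate_observed_peptides(db, detect_prob = 1, seed = 2)
rec <- call_ase_support(parse_identifications(obs), db, idx)
table(rec$tis_category)
#>  A  B  C
#> 66 68 66
```

A thin command-line launcher with `build-db`, `digest`, `simulate`,
`classify`, `merge` and `report` subcommands lives at
`system.file("cli", "spliceptide.R", package = "spliceptide")`.

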