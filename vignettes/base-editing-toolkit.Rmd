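---
title: "Base-editing design, quantification and off-target triage with beditr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Base-editing design, quantification and off-target triage with beditr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beditr)
```

# Scope and model

beditr implements the computational layer of a plant base-editing
experiment: guide design with activity-window modelling and bystander
consequence prediction, amplicon-sequencing quantification of editing
outcomes, mismatch-tolerant off-target site enumeration, and SNV-level
off-target triage over a four-sample WGS/WTS design. This vignette is the
package's own account of the underlying models, the tunable parameters and
their defaults, and the design decisions taken where the design was
genuinely open.

## Editor profiles

A base editor is parameterised by five quantities (`editor_profile`):

* **PAM pattern and side** — an IUPAC string (`NGG` for Cas9-nickase
  fusions, 3′ of the protospacer; `TTTV` for Cas12a fusions, 5′ of it).
* **Protospacer length** — 20 nt for nCas9 profiles, 23 nt for dCas12a.
* **Activity window** `c(lo, hi)` — the protospacer positions, counted
  1..length from the 5′ end, where deamination occurs at useful rates. With
  this counting a 3′ PAM occupies positions 21–23 of a 20-nt guide; for a
  5′-PAM editor the PAM sits immediately before position 1.
* **Conversion** — `A→G` for ABEs, `C→T` for CBEs; on a minus-strand guide
  the same chemistry surfaces as `T→C` (resp. `G→A`) in forward-strand
  coordinates, and every module applies that complementation consistently.

The bundled ABE8e-class profile uses window 4–10. A wider 4–12 window has
been described for the same deaminase at some sites; it is retained as the
separate named profile `GhABE8e-A4A12` rather than silently widening the
default, since the narrower window is what per-position efficiency data
support at most sites. The dCas12a profile's window (8–14) is provisional:
no per-position window measurement exists for that fusion here, so the
value follows the ABE8e–dLbCas12a literature convention and is exposed as
configuration like every other profile field.

## Coordinates

All coordinates in the package are **1-based inclusive** — the native
convention of FASTA, VCF and GFF3 and of the Bioconductor interval stack
(IRanges/GenomicRanges) that performs the interval arithmetic. Keeping a
single convention end to end means no internal re-basing occurs anywhere;
the I/O layer simply passes coordinates through. Boundary behaviour at
position 1 and at the sequence end is asserted by dedicated tests.

# Guide design

`scan_guides` enumerates every protospacer+PAM occurrence of a profile on
both strands (IUPAC semantics for the PAM; an `N` in the reference matches
no pattern letter, and protospacers containing ambiguity codes are not
reported, since a synthesisable guide needs concrete bases). Candidates
record their editable window positions. The scanner is checked against a
literal per-offset enumeration oracle and a strand-symmetry property
(scanning the reverse complement yields the mirrored candidate set).

`rank_guides` orders candidates by a deliberately simple, fully exposed
linear score: `1.0 × (#editable positions) − 2.0 × (TTTT present) + 0.5 ×
(GC fraction in [0.3, 0.7])`. A TTTT run is penalised because it is a
Pol-III terminator for U6-driven sgRNA cassettes. The weights are
configuration, not science: no published scoring function exists for this
design task, so the default is transparent and deterministic (ties broken
by position and strand, making the ranking invariant under input
shuffling), rather than a fitted activity model — which is out of scope.

# Consequence prediction

CDS models are built from GFF3 `CDS` features grouped by `Parent` mRNA,
spliced in transcript orientation (genomic order on `+`, reversed on `-`),
and translated with the standard nuclear genetic code only — the targets
are nuclear plant genes, and no organellar table is offered. Codon
arithmetic is strictly in-frame: CDS nucleotide position `p` (1-based from
the first base of the start codon) lies in codon `floor((p−1)/3)+1`, so
positions 157 and 158 both fall in codon 53. Edits landing in one codon are
applied **jointly** before translation: an `AAA→GGA` double edit is one
`K→G` substitution, not two partial calls. Edits in different codons are
reported as separate rows with a combined display label (`K53G+S78G`).

`enumerate_bystanders` expands all `2^k − 1` non-empty subsets of a guide's
k editable positions (refusing k above a cap, default 6, to prevent
combinatorial blow-up) and labels each with its protein outcome. Window
positions outside the CDS contribute no protein change; a subset whose
edits are all non-coding is labelled `noncoding` — no splice-site modelling
is attempted. The translation path is verified against an independent
engine (seqinr) on all 64 codons, and minus-strand genes are checked for
orientation invariance on mirrored fixtures.

# Amplicon quantification

Reads are aligned to the amplicon with Needleman–Wunsch global alignment
(match +1, mismatch −1, gap open −5, gap extend −1, via
`Biostrings::pairwiseAlignment`); orientation is auto-detected by aligning
both the read and its reverse complement and keeping the better score. The
alignment parameters are configuration with documented defaults — no
canonical parameter set exists for this task, and the defaults are ordinary
DNA-alignment scores that heavily discourage spurious indels in short,
high-identity amplicon reads.

Filtering policy, and why:

* identity `< 0.75` → discarded (`low_identity`): off-amplicon or chimeric
  PCR artefacts;
* an indel overlapping the quantification window (the protospacer span) →
  discarded and tallied separately (`window_indel`): deaminase editors are
  not expected to create indels, so such reads are candidate
  Cas-independent events rather than substitution outcomes, and only
  substitution efficiencies are reported;
* a base with Phred < 20 at an editable position removes the read from that
  position's numerator **and** denominator (per-position denominators may
  therefore differ). At the efficiencies these experiments reach (≥99% is
  routine), untrimmed sequencing error would otherwise bias high-rate
  positions down and low-rate positions up.

The efficiency statistic is read-level, matching how deep-sequencing
editing efficiencies are reported: per-position efficiency is the
percentage of eligible reads carrying the installed base at that window
position, and site efficiency is the percentage of aligned reads with at
least one window conversion. Percentages are rounded half-up to one
decimal (so 99.94 reports as 99.9, 99.95 as 100.0).

Allele tables key reads by their aligned bases over the protospacer ±
`window_pad` (default 5) and label each allele by its window conversions
(`A4G;A6G`; `WT` when none). `classify_sample` aggregates allele rows by
edit genotype and calls the sample `unedited` (no genotype ≥ 5%),
`homogeneous` (exactly one ≥ 5% and carrying ≥ 90% of reads) or `chimeric`
— the typical state of primary regenerants, whose cell lineages carry
different edits.

# Off-target analysis

`enumerate_offtargets` reports every genomic window, on either strand,
whose PAM matches the profile pattern and whose protospacer is within a
Hamming-distance budget of the guide (default `max_mismatches = 4`,
exposed — and echoed into CLI output — because predicted-site counts are
meaningless without their mismatch budget). Only substitution mismatches
are modelled; DNA/RNA bulges are not. A genome `N` matches no guide base
(it consumes mismatch budget) and fails every PAM letter, including
pattern `N` — an unknown base should never *create* a predicted site. The
on-target locus is kept but flagged, mirroring the practice of removing
on-target edits before off-target statistics. The scanner is validated
against an all-windows Hamming oracle and a monotonicity property (the
site set at budget m is a subset of that at m+1).

The SNV triage reproduces the standard four-sample design: SNVs observed in
the negative regenerant or the wild type are background and are subtracted
from the edited and vector-only samples; subtraction is **allele-aware**
(chrom, pos, ref, alt), because a different allele at the same position is
a different mutational event. Only the deamination signatures survive the
compatibility filter (A>G / T>C for an ABE — the forward-strand
representations of adenine deamination on either strand). Remaining SNVs
are intersected with merged predicted-site footprints (protospacer + PAM ±
flank) for the sgRNA-dependence Venn, and annotated into one of six region
categories with priority exonic > UTR > intronic > upstream > downstream >
intergenic (flanks default 2 kb; the category set and flank sizes are
ordinary annotation bins, config-exposed, not asserted against any external
reference). Filtered-to-total percentages round half-up, by default to two
decimals at DNA scale and one at RNA scale, matching how such ratios are
conventionally printed (e.g. 4395 of 1,274,475 → 0.34%).

# Synthetic data and what the tests do (and do not) show

Each generator draws from a private RNG stream seeded by a single integer
(the caller's random state is untouched), making every fixture
reproducible, and returns a truth ledger alongside its output. The closed
loop is the package's central testing device: with sequencing error ε = 0
the pipelines must reproduce the ledgers *exactly*; with ε > 0 or finite
sampling, recovery is asserted within binomial bounds.

Default study conditions, chosen once to emulate a desk-scale version of a
real editing experiment:

* genome 100 kb with 5 two-exon genes (UTRs, intron, in-frame CDS; gene 1
  fixed at a 525-bp ORF, the size of a short single-ORF target gene, which
  also supplies the codon-arithmetic check);
* amplicons of 230 bp — the size class of typical editing-assay PCR
  products — with constant Q40 qualities and uniform substitution errors at
  rate ε;
* SNV designs of 300 shared background variants plus tens of sample-private
  variants per sample, with a configurable mutation-class mix. A real
  allotetraploid WGS comparison involves ~10^6 SNVs per sample against a
  multi-gigabase genome; that scale is not reproducible at desk scale, and
  the pipeline's set algebra is scale-free, so correctness is established
  on designs whose ground truth is known exactly.

What passing tests do **not** show about real data: the read simulator has
no platform error profile, no quality-score structure, and fixed-length
reads; the SNV generator plants point substitutions only (no indel/MNV
background, no mapping artefacts); and genomes are i.i.d. random sequence
without repeats, so off-target site densities are far below those of a
real genome. The generators validate algorithmic correctness, not
robustness to instrument artefacts.

Test problem sizes were chosen to keep the whole suite comfortably
desk-scale: oracle-equivalence sweeps use 100 seeded instances (1-kb
references for guide scanning, 100-kb genomes with planted near-matches
for off-target enumeration), and parameter-recovery uses pools of 1000
reads over a {5, 25, 50, 75, 95}% rate grid, where the 3-percentage-point
recovery bound is the ~2σ binomial envelope.

# Numerical and degenerate-input conventions

* Rounding is half-up everywhere a percentage is printed (base `round`'s
  half-even rule would report 0.345 → 0.34 where 0.35 is conventional).
* Ties in every ranking/ordering are broken by genomic position then
  strand; all outputs are deterministically ordered regardless of
  traversal or input order.
* Empty read pools, zero-total percentages, CDS positions out of range,
  edits whose reference base does not match (stale coordinates), rates
  outside [0,1], and programmed edits at non-editable positions all fail
  loudly rather than degrade silently.
* Multi-allelic VCF rows are split on load; indels and MNVs are dropped
  with a count kept on the set. Duplicate FASTA ids are an error, not a
  merge.

# Known limitations

* No machine-learned on-target activity score; the ranking is a transparent
  heuristic.
* No bulge-tolerant off-target alignment and no CFD/MIT-style specificity
  scores.
* No paired-end merging, UMI handling or barcode demultiplexing — pools are
  assumed demultiplexed upstream.
* No splice-site or promoter cis-element effect prediction; non-coding
  edits are labelled, not interpreted.
* Variant calling itself is out of scope: the triage consumes any
  SNV-bearing VCF and is agnostic to the caller that produced it.
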