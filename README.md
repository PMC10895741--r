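# beditr

Design and analysis toolkit for **base-editing experiments in plants**.

Base editors — adenine base editors (ABEs, A•T→G•C) and cytosine base editors
(CBEs, C•G→T•A) — rewrite single bases without double-strand breaks. Putting
them to work raises four computational problems that this package solves as
one coherent, testable toolkit:

1. **Guide design** (`scan_guides`, `rank_guides`, `apply_window_edits`) —
   find every protospacer+PAM site of an editor on a reference, on both
   strands, and report which *activity-window* positions are editable.
   Editor chemistry is a first-class object (`editor_profile`): PAM pattern
   and side, protospacer length, window, conversion. Bundled profiles cover a
   TadA8e–nCas9 adenine editor (NGG, window A4–A10), its narrow-window
   TadA7.10 predecessor (A5 only), a TadA8e–dCas12a editor (TTTV 5′ PAM,
   23-nt protospacer) and a generic CBE.
2. **Consequence prediction** (`cds_models`, `map_to_codon`,
   `predict_consequence`, `enumerate_bystanders`) — map window edits onto
   spliced CDS models from GFF3, translate jointly-edited codons, and
   enumerate all 2^k−1 *bystander* combinations of k editable positions with
   protein-level labels in the field's usual style (`K53G+S78G`).
3. **Editing quantification from amplicon deep sequencing**
   (`align_reads`, `editing_efficiency`, `build_allele_table`,
   `classify_sample`) — global alignment of reads to the amplicon, then the
   read-level efficiency statistic used throughout the field:

   *efficiency(p) = 100 × (reads carrying the installed base at editable
   position p) / (eligible aligned reads)*,

   plus a site-level efficiency (reads with ≥1 window conversion), allele
   tables over the guide window, and chimera classification
   (unedited / homogeneous / chimeric) for primary regenerants.
4. **Off-target triage** (`enumerate_offtargets`, `site_intervals`,
   `subtract_background`, `filter_editor_compatible`, `intersect_predicted`,
   `annotate_regions`, `run_triage`) — Cas-OFFinder-style mismatch-tolerant
   site enumeration, and the WGS/WTS SNV pipeline over the standard
   four-sample design (edited / vector-only / negative / wild type):
   subtract background SNVs seen in controls, keep only the deamination
   signatures (A>G and T>C for an ABE), intersect with predicted site
   footprints, and annotate genomic regions.

Everything is exercisable without external data: the `simulate_*` generators
produce genomes with planted sites and gene models, programmed amplicon read
pools, and four-sample SNV designs — each with a ground-truth ledger the
analyses must reproduce.

## Worked example

Simulate an amplicon whose guide has editable adenines at protospacer
positions 4, 6 and 7, sequence a pool of 200 reads in which A4 is converted
in 30% of cells and A6 in 60%, and quantify:

```r
library(beditr)

tg   <- simulate_amplicon(seed = 3)                      # 230-bp amplicon, ABE8e-style guide
pool <- simulate_amplicon_reads(tg, n_reads = 200,
                                rates = c("4" = 0.3, "6" = 0.6), seed = 11)
pp  <- align_reads(pool$reads, tg)
rep <- editing_efficiency(pp, tg)
rep
#> <editing_report> 200 reads aligned; site efficiency 76.0%; chimeric
#>   per-position efficiency (%):
#> A4 A6 A7
#> 30 64  0
```

The per-position efficiencies are the realised Bernoulli fractions of the
simulated pool (60/200 and 128/200 reads), recovered exactly because the
pool is error-free; the site efficiency (76.0%) counts reads with at least
one window conversion, and the sample is called chimeric because two edit
genotypes each exceed the 5% detection threshold. The allele table names
each genotype:

```r
head(build_allele_table(pp, tg), 3)
#>                       allele_seq read_count frequency edit_label
#> 1 CTGTTACTACGACGGTCGTTTTACAAGGCG         92      0.46        A6G
#> 2 CTGTTACTACAACGGTCGTTTTACAAGGCG         48      0.24         WT
#> 3 CTGTTACTGCGACGGTCGTTTTACAAGGCG         36      0.18    A4G;A6G
```

Summary percentages in the SNV triage follow the field's reporting
convention (round half-up; two decimals at DNA scale):

```r
triage_percent(4395, 1274475, digits = 2)
#> [1] 0.34
```

A thin command-line front end over the same functions is installed at
`inst/scripts/bedit.R` (`design`, `offtarget`, `quant`, `triage`,
`simulate` subcommands).

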