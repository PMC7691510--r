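# nmdscan

Locate premature termination codons (PTCs) created by coding variants in a
protein-coding transcript, predict whether each one triggers or escapes
nonsense-mediated mRNA decay (NMD), and weigh exome-versus-transcriptome
allele fractions as evidence of actual transcript degradation.

## Who this is for

Whether a truncating variant is degraded by NMD or escapes it changes its
disease mechanism: a PTC that triggers decay causes haploinsufficiency,
while one that escapes yields truncated protein with possible toxic gain of
function. For *SOD1*-linked ALS — where truncated SOD1 is misfolding-prone
and toxic, and antisense therapies are assigned per variant — this
distinction decides whether a PTC is plausibly pathogenic at all. The
package is for geneticists and variant curators who need that call made
reproducibly from a transcript model and an HGVS string, and for
methodologists who want the positional rules, their thresholds and their
edge cases exposed as testable code.

## The rules

A PTC at codon `c` (stop codon anchored by its first nucleotide
`p = 3c - 2`, CDS coordinates, +1 = A of ATG) **escapes** NMD when any of
the four positional rules fires:

| rule | fires when | threshold (default) |
|---|---|---|
| last exon | `p > J` (last exon–exon junction) or single-exon transcript | — |
| junction proximity | `c > floor((J - W - 1)/3)`, junction window `W` | 55 nt (50–55) |
| long exon | exon containing `p` is non-terminal with CDS length > `E` | 400 nt |
| start proximity | `c < max(1, floor((T + 1)/3))` | `T` = 150 nt |

Otherwise the PTC is predicted to **trigger** decay. The complement of the
escapes is the transcript's *trigger region*: nt `T+1 .. J-W-1`, codons
`floor((T+1)/3) .. floor((J-W-1)/3)`, minus long-exon exclusions. Trigger
calls within 2 codons of a region bound are flagged *borderline* (decay may
be incomplete there). For allele-specific expression, the retention of the
mutant transcript is estimated by the DNA→RNA odds ratio
`[vR/(1-vR)] / [vD/(1-vD)]` and tested with an exact binomial test; see the
methods vignette (`vignettes/nmd-escape-prediction.Rmd`) for the verdict
logic and every numerical choice.

## Worked example

The package ships the *SOD1* transcript model (RefSeq NM_000454.4: 465 nt
CDS, five exons, last junction at CDS nt 357) and the catalogue of 16
ALS-associated truncating variants.

```r
library(nmdscan)

sod1 <- sod1_transcript()
trigger_region(sod1)
#> nmd_region [NM_000454.4]
#>   trigger: codons 50-100 (nt 151-301)

rep <- run_classification(sod1, sod1_variants())
rep
#> classification_report [NM_000454.4]: 16 variant(s)
#>   trigger: codons 50-100 (nt 151-301)
#>   escape 15 / trigger 1 (borderline 1)
#>   by class: nonsense 4, frameshift 11, splicing 1, other 0
#>   by rule: last_exon 14, junction_proximal 0, long_exon 0, start_proximal 1
```

Reading: PTCs in this transcript trigger decay only between codons 50 and
100 (CDS nt 151–301). Of the 16 catalogued variants, 14 escape through the
last-exon rule and one (p.Val30Aspfs\*8, PTC at codon 37) through the
start-proximal rule; the single predicted trigger sits exactly on the
region's upper bound and is flagged borderline:

```r
rep$rows[rep$rows$status == "trigger",
         c("label", "hgvs_c", "ptc_codon", "status", "borderline")]
#>     label         hgvs_c ptc_codon  status borderline
#> 7 K92Rfs9 c.275_276delAA       100 trigger       TRUE
```

Allele-fraction evidence — a heterozygous trigger-region PTC seen on 46% of
exome reads but only 9% of RNA-Seq reads:

```r
assess_nmd(allele_counts(46, 54, 9, 91, "sample1"))
#> allele_evidence [sample1]
#>   VAF: DNA 0.460, RNA 0.090; retention ratio 0.116; p = 1.5e-15
#>   verdict: consistent_with_decay
```

The retention ratio says only ~12% of the mutant transcript survives —
consistent with degradation by NMD.

## Command line

`inst/exec/nmdscan` wraps the same operations:

```sh
nmdscan region   --transcript inst/extdata/sod1_nm000454.json
nmdscan classify --transcript inst/extdata/sod1_nm000454.json \
                 --variants inst/extdata/sod1_table1.tsv --out report.tsv
nmdscan ase      --counts inst/extdata/sod1_ase_synthetic_counts.tsv
nmdscan simulate --outdir sim/ --seed 1 --delta 0.1
nmdscan config
```

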