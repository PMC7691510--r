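---
title: "Predicting nonsense-mediated decay escape for premature termination codons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nonsense-mediated decay escape for premature termination codons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdscan)
```

## The problem

Nonsense-mediated mRNA decay (NMD) is the surveillance pathway that degrades
transcripts carrying a premature termination codon (PTC), limiting the
production of truncated protein. Whether a given PTC actually triggers decay
is largely positional, and the distinction matters clinically: a PTC that
triggers NMD causes haploinsufficiency, while a PTC that escapes NMD yields
a truncated protein that may act through a toxic gain of function. For
*SOD1*-linked amyotrophic lateral sclerosis this distinction separates
variants expected to be pathogenic through misfolded truncated protein from
variants that may have no pathogenic significance at all.

`nmdscan` takes a transcript model (exon structure plus CDS sequence) and
coding variants described in HGVS c. nomenclature, locates the resulting
PTC by directly editing and translating the CDS, classifies it against the
positional rules of NMD surveillance, and — when matched exome and RNA-Seq
read counts are available — weighs allele-fraction evidence of actual
transcript degradation.

## The model

### Coordinates

Everything is expressed in CDS coordinates: position 1 is the A of the ATG
initiation codon (the HGVS c. convention), codon $c$ occupies nucleotides
$3c-2 \ldots 3c$. UTR exons and UTR lengths are ignored; the four rules as
used here are all expressible from the CDS-overlapping exon lengths and the
derived junction list. The last CDS nucleotide of each non-terminal exon is
an exon–exon junction and belongs to the upstream exon.

### The four escape rules

A PTC at codon $c$, anchored by the first nucleotide $p = 3c-2$ of its stop
codon, escapes NMD when any of the following fires:

1. **Last exon**: $p > J$, where $J$ is the last junction position (or the
   transcript has a single exon). No junction lies downstream of the PTC, so
   no exon-junction complex survives to mark the transcript.
2. **Junction proximity** (the "50-nt rule", window $W$, default 55 nt,
   documented range 50–55): $c > \lfloor (J - W - 1)/3 \rfloor$ and rule 1
   does not already apply.
3. **Long exon**: the exon containing $p$ is internal (or first) and its
   CDS-overlapping length exceeds 400 nt.
4. **Start proximity** (threshold $T$, default 150 nt):
   $c < \max(1, \lfloor (T+1)/3 \rfloor)$.

Otherwise the PTC is expected to **trigger** decay. The trigger region of a
transcript is the complement of the escapes: nucleotides $T+1$ through
$J - W - 1$, codons $\lfloor (T+1)/3 \rfloor$ through
$\lfloor (J-W-1)/3 \rfloor$, minus any long-exon exclusions. For the
bundled *SOD1* transcript (CDS 465 nt, $J = 357$) the defaults give
nucleotides 151–301 and codons 50–100.

```{r}
sod1 <- sod1_transcript()
trigger_region(sod1)
```

### Numerical choices at the boundaries

The published nucleotide interval (151–301) and amino-acid interval
(50–100) for *SOD1* are mutually inconsistent at single-nucleotide
resolution: codon 50 spans nucleotides 148–150, outside the nucleotide
interval. We reproduce both statements simultaneously by treating the codon
index as the canonical rule space and deriving codon bounds as
$\lfloor \mathrm{nt}/3 \rfloor$; with $T = 150$, $J = 357$, $W = 55$ this
yields exactly nt 151–301 and codons 50–100. Three related decisions
follow:

* The junction window default is 55, the upper end of the documented 50–55
  range, because $357 - 55 - 1 = 301$ matches the published bound. Over the
  whole 50–55 sweep the *SOD1* codon bounds change by at most 2 codons.
* Region emptiness is decided in codon space (`codon_lo > codon_hi`), since
  at the bounds the nt and codon intervals can disagree by up to 2 nt.
* A stop codon straddling the last junction is assigned by its first
  nucleotide — a deterministic tie-break; which stop-codon nucleotide
  anchors the junction distance is not specified by the rules themselves,
  and alternative anchors move boundary codons by at most one.

A trigger verdict within `borderline_codons` (default 2) of either region
bound is flagged borderline rather than given a third status: at such
positions decay may be incomplete and truncated protein partly produced
(the *SOD1* codon-100 case). The flag width is configurable because the
rules literature quotes soft thresholds ("50–55", "approximately 400").

### Variant consequence calling

`parse_cdna_hgvs()` covers substitution, deletion, duplication, insertion
and delins syntax; intronic offsets are rejected as non-coding edits, to be
supplied either as an explicit `transcript_edit` (e.g. a pseudo-exon
insertion established by transcript analysis) or as a printed protein-level
consequence. `find_ptc()` scans the mutant frame 5'→3' for the first stop;
the mutant codon index is the canonical "resulting PTC position" (for a
frameshift `p.Xaa{pos}Yaafs*{N}` it equals `pos + N − 1`). Stop-codon
coordinates are projected back onto the reference frame by subtracting the
net length inserted 5' of the stop, so the positional rules always operate
on the reference exon structure. Frameshift consequences are named from the
first residue at which the mutant translation diverges from the reference
protein; three-letter codes are emitted, one-letter accepted on input.
Parsed names are taken at face value (no 3'-re-shifting) since catalogued
names are the authority; names the package *generates* are 3'-shifted and
written as `dup` when the insertion copies the preceding span. In-frame
delins consequences are named approximately (fs-style); they are outside
the frameshift/nonsense scope this package targets.

## Allele-fraction evidence

Matched exome and RNA-Seq read counts over a heterozygous PTC give a direct
readout of transcript loss. With variant allele fractions $v_D$ (DNA) and
$v_R$ (RNA), the odds ratio
$$\hat\delta = \frac{v_R/(1-v_R)}{v_D/(1-v_D)}$$
estimates the mutant transcript's relative retention under a two-allele
model with equal DNA representation — a model assumption, not a
measurement. `assess_nmd()` combines $\hat\delta$ with a two-sided exact
binomial test of the RNA alt count against $v_D$:

* `consistent_with_decay`: significant imbalance (`p < alpha`, default
  0.05) and $\hat\delta$ below `ratio_threshold`;
* `consistent_with_escape`: $\hat\delta$ at or above the threshold, or no
  significant imbalance at informative RNA depth (`min_depth`, default 20);
* `indeterminate`: no significant imbalance but too few RNA reads to mean
  anything.

The default `ratio_threshold` is 0.25. The eyeball comparison this
formalizes provides two empirical anchors: a trigger-region PTC observed at
9% of RNA reads versus 46% of DNA reads ($\hat\delta \approx 0.12$, called
degradation) and a last-exon PTC at 32% versus 56% ($\hat\delta \approx
0.37$, called escape). Any threshold that separates partial decay from
escape must lie between those anchors; 0.25 is their midpoint region. A
threshold of 0.5 — superficially natural as "half the transcript lost" —
would call the observed escape case decay, because even clearly escaping
last-exon PTCs show mildly depressed RNA fractions in tumor data. The
quantitative decay/escape boundary is genuinely undefined in the rules
literature, which is why the threshold is a configurable parameter reported
in every output rather than a constant.

```{r}
assess_nmd(allele_counts(46, 54, 9, 91))   # trigger-region PTC
assess_nmd(allele_counts(56, 44, 32, 68))  # last-exon PTC
```

## What the simulator emulates — and what it does not

`sim_config()` states the simulated world once:

* **Transcripts**: 150–250 codons over 3–6 exons of 60–300 CDS nt —
  a *SOD1*-like locus (154 codons, five exons of 72/97/71/117/108 CDS nt).
  The CDS is built codon-wise from the 61 sense codons, so internal stops
  are impossible by construction; exon lengths are drawn and rescaled to
  partition the CDS exactly (rounding can push individual exons slightly
  outside the drawn range).
* **Variants**: the type mix follows the catalogued truncating-variant
  spectrum (4 nonsense : 3 frameshift deletions : 2 insertions :
  4 duplications : 2 delins). Ground-truth PTCs are derived by a separate
  minimal translation path (a hand-typed codon lookup), not by the code
  under test; draws that hit the natural terminator or lose the stop are
  resampled.
* **Counts**: DNA alt reads are Binomial(depth, 0.5); under retention
  $\delta$ the RNA alt probability is
  $0.5\delta/(0.5\delta + 0.5) = \delta/(1+\delta)$, which makes the odds
  ratio $\hat\delta$ an unbiased estimator of $\delta$ at $v_D = 0.5$.
  Depth defaults to 100×; parameter-recovery tests use 500×.

One root seed drives per-component child streams derived by fixed offsets,
so a fixed seed reproduces every output byte for byte.

The simulator deliberately ignores mapping bias, overdispersion
(beta-binomial behaviour of real RNA-Seq), copy-number distortion of DNA
fractions, tissue-specific NMD efficiency and splicing. A green test
therefore establishes that the implementation computes its stated model
correctly — not that the model captures every property of real tumor
ASE data.

## Degenerate inputs and errors

* Transcripts failing any invariant (length not a codon multiple, missing
  ATG or terminal stop, internal stop, exon lengths not partitioning the
  CDS) are rejected at construction with structured conditions; internal
  stops are reported with their codon index.
* A DNA fraction of exactly 0 or 1 is not a heterozygous call: the odds
  ratio is undefined and `assess_nmd()` refuses it
  (`nmdscan_degenerate_odds`).
* Stated reference bases that disagree with the transcript raise
  `nmdscan_reference_mismatch` naming position, expected and found bases.
* A mutant with no stop codon (stop-loss) raises `nmdscan_no_terminator`;
  stop-loss and start-loss naming are out of scope.
* When a printed protein consequence and the computed one disagree, the
  report row carries both plus a discordance flag; classification uses the
  computed call unless `prefer_printed = TRUE`. Nothing is silently
  reconciled.

## Known limitations

* Single transcript, single variant at a time; no phasing, no multi-isoform
  handling, no genome-wide annotation.
* The long-exon rule sees CDS-overlapping exon lengths only; a first/last
  exon's UTR portion does not count toward the 400 nt threshold.
* The classification of a splice variant supplied at protein level uses the
  reference exon structure, not the pseudo-exon-containing transcript; the
  resulting PTC is placed on the reference diagram by its codon index.
* No EJC-deposition modelling, UPF mechanics or quantitative decay-rate
  prediction: the rules are positional heuristics with soft thresholds, and
  every threshold is exposed in `nmd_config()`.
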