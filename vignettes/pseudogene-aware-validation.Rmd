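---
title: "Validating variant detection in a pseudogene-shadowed gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating variant detection in a pseudogene-shadowed gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A handful of clinically important genes sit inside segmental duplications.
The archetype is *PKD1*, the major gene of autosomal dominant polycystic
kidney disease: the genomic region containing its first 33 exons is
duplicated into six pseudogenes (*PKD1P1–P6*) that retain roughly 97.7%
sequence identity. Short reads from the pseudogenes are captured and
sequenced along with reads from the genuine gene, and every read whose
sequence is locally compatible with both competes for placement. The
observable consequence at a heterozygous variant site is a depressed
alternative-allele fraction: reads that carry an allele also present in a
pseudogene align perfectly to the pseudogene and are lost from the master
pileup, while reference-carrying reads stay put.

`pseudocall` packages the full analysis used to validate capture-based
sequencing of such a locus, together with a synthetic-locus simulator so
every statement the package makes can be exercised end to end on a laptop,
with no reference genome, no external aligner and no protected cohort data:

* a locus simulator (master gene, pseudogene copies at a controlled
  identity, planted truth variants),
* a paired-end read simulator with explicit coverage accounting,
* a seed-and-extend Smith–Waterman read mapper, so competitive mapping is
  reproducible in-package,
* the tiered allele-fraction caller,
* depth-ratio copy-number calling against a control panel with a named
  filter ledger, plus an MLPA-style ratio comparator,
* split-read breakpoint resolution with sliding-window decomposition, and
* truth-based evaluation (sensitivity, specificity, detection-rate tables).

## The calling rules

Variant detection in the shadowed gene does not use genotype likelihoods;
it thresholds the alternative-allele fraction, with the denominator being
the **total filtered depth** at the position:

* a variant is reported when **≥ 20%** of total reads carry the
  alteration (`standard` tier),
* it is called homozygous at **≥ 85%**,
* and, in a *second-step* screen applied only inside the duplicated
  region of a sample in which the first step found nothing, the
  threshold is relaxed to **≥ 8%** (`relaxed-candidate` tier). Candidates
  at this tier exist to be confirmed orthogonally, not to be reported
  directly; the threshold sits where competitive mapping can push a true
  heterozygous site, while random sequencing error at rate 0.001 cannot
  reach it at any realistic depth.

Sites with fewer than `min_depth` (default 20) filtered reads are
reported as *uncovered* rather than silently negative — a distinction
that matters in practice because the GC-rich first exon of such loci is
chronically under-covered. Mapping-quality filtering is off by default:
at pseudogene-identical sites, precisely the read pairs that rescue the
variant carry MAPQ 0, and a blanket filter removes true signal; the
opt-in floor exists for the site-specific cases where filtering helps.

A truth site is a **critical site** when its observed fraction falls
below the standard threshold or its zygosity is miscalled. Critical
sites cluster in exons with long identity tracts, and those exons feed
the CNV filter ledger below.

## Copy-number calling

Per-target (exon) mean depths are internally normalised — each sample is
scaled so its mean target depth is 1 — and the index sample is compared
against **each control separately**: `log2(index/control)` per target per
control. A target supports a deletion in a control when the ratio is
≤ −0.6 (amplification ≥ +0.6). Support by ≥ 85% of the panel gives a
`pass`, 50–85% an `indicated` status. Adjacent same-direction targets are
merged into one event, and a passing anchor exon carries the merged event
to `pass`: internal normalisation necessarily shrinks per-exon ratios as
an event grows (a heterozygous deletion of 7 of 30 exons sits near
log2 −0.82, not −1.0), so the distal exons of a long deletion are often
found in the indicated band and the event's extent is read off the 50%
band from its anchor.

The **filter ledger** then removes calls in named region classes —
critical exons with restricted discriminative mapping, recurrent artifact
exons, exons with insufficient or varying coverage — and deletion calls
that contain standard-tier heterozygous variant evidence (a true
heterozygous deletion cannot show heterozygous sites inside the deleted
span; the default evidence band is an alt fraction in [0.20, 0.80]).
Reasons are a set: applying the ledger in any order yields the same
status. The ledger is configuration, not code, because the artifact-exon
lists differ between laboratories and even between reports of the same
laboratory.

An `mlpa_ratio()` comparator covers the orthogonal assay: per-probe
relative peak area against the control mean, deletion flagged strictly
below 75%.

## Breakpoints from soft-clipped reads

Reads spanning a deletion junction align up to the junction and carry the
retained downstream sequence as a soft clip. `extract_soft_clips()` and
`cluster_clips()` turn these into boundary clusters with a per-column
majority consensus; `place_clip()` aligns the consensus against the locus
by Smith–Waterman, and the placement start is the 3' endpoint candidate.
A placement is *confident* at ≥ 90% of the maximum attainable score.
When direct placement fails — the situation that arises when repeat
shuffling separates the clip into segments — `window_decompose()` places
20-base windows (step 1) independently and lets the extremal confident
windows delimit the endpoint interval; if nothing places, the
CNV-supported interval itself is reported, which is the honest outcome
when the far endpoint lies in sequence absent from the capture design.

## What the simulator emulates, and what it does not

The synthetic locus is a uniform-random master sequence with evenly
spaced, evenly sized exons (default 33 × 150 bp with 100 bp introns); the
duplicated block (exons 1–33 plus half-intron flanks) is copied
`n_pseudogenes` times, each base mutated independently at rate
1 − identity (default 0.023, substitutions only by default so master and
copy coordinates stay aligned). Reads are 2 × 150 bp pairs at an outer
distance of 200 — the mates overlap by 100 bp — with i.i.d. substitution
errors at 0.001 and constant Q30 qualities. Coverage is accounted per
200 bp fragment: `ceiling(coverage × length / 200)` pairs, so 1000×
means 1000 fragment footprints per base (the per-base *read* depth is
1.5× that; both conventions are available in `pairs_for_coverage()`).

Truth variants are planted with ≥ 1 variant per 100 bp of coding sequence
(plus extra at rate 0.02), 15% indels with geometric length extension
(p = 0.3), heterozygous by default — the hardest detection case. Planted
variants keep a minimum spacing of 10 bp: an indel touching another
variant has no unique anchored representation, and truth matching would
become ill-defined rather than harder.

The end-to-end experiment plants two variant classes:

* **divergent** — positions at which no pseudogene copy diverges, with a
  random non-reference allele; the allele can never coincide with a
  pseudogene base, so discrimination is always possible;
* **pseudogene-matching** — heterozygous SNVs at divergence sites of copy
  1 whose alternative allele *is* the copy's base. A read pair carrying
  this allele is lost to the pseudogene exactly when its footprint
  contains no other divergence site, so the magnitude of depression is a
  property of local identity-tract geometry. The planter therefore
  prefers the most *isolated* divergence sites (largest distance to the
  nearest neighbouring divergence site of the same copy): these are the
  synthetic analogue of real critical sites, which are characterised by
  reads mapping perfectly to a homologous region. Uniform sampling is
  available, but it turns the depression signal into a per-locus lottery.

The two classes are phased onto separate haplotypes. With both on one
haplotype, a read can carry a divergent-class allele *and* a
pseudogene-matching allele, and the pseudogene then outscores the master
for that read, dragging the divergent variant down as a side effect —
the coupling is real (neighbouring sites interfere in real data too) but
it would make the per-class measurements uninterpretable.

Mapping ties — a pair scoring equally at the master and a copy — are
assigned uniformly at random with MAPQ 0, reproducibly under the run
seed. This mirrors how production aligners place multi-mapping reads and
is the mechanism that produces depressed fractions at all; any
deterministic tie rule either hides the phenomenon (always-master) or
caricatures it (always-pseudogene).

Not modelled, deliberately: capture and GC bias (and hence the
chronically failing GC-rich first exon), quality decay along reads,
duplicate reads, sequencer-specific error profiles, clustered
(gene-conversion-like) pseudogene divergence, and real exon-size
heterogeneity. Consequently a passing simulation says the *rules* work
when reads behave as modelled; it does not certify performance on real
capture data, where coverage unevenness and clustered identity tracts
are the dominant failure modes. Under uniform divergence the depression
at matched sites is moderate (observed fractions mostly 0.18–0.50 at
1000×; a site is counted *depressed* below 0.45, which is more than 3
binomial standard deviations under the 0.5 heterozygous expectation);
the real locus shows sites below 8% because its divergence is clustered,
leaving identity tracts much longer than this generator produces.

## Numerical and design choices

* **Alignment scoring** defaults to match 2, mismatch 4, gap open 6, gap
  extend 1 (a gap of length L costs 6 + L); the published analysis names
  Smith–Waterman but not a scheme, so the common short-read defaults are
  used. DP tie-breaks prefer the smaller target start, then the shorter
  alignment, making outputs deterministic.
* **Mapping quality** is `min(60, 6 × (best − second best))`, 0 on ties —
  a monotone, testable proxy for aligner MAPQ, not a calibrated error
  probability.
* The mapper scores candidates gaplessly and falls back to local
  alignment only when no candidate meets the mismatch budget (default 8),
  which is the indel/junction-read case; with substitution-only
  divergence the gapless score *is* the optimal local score for
  full-overlap placements.
* **Pileup conventions**: deletions are keyed `-L` at their anchor base,
  insertions `+SEQ` at the preceding base; at an anchor, a read carrying
  the indel votes for the indel allele instead of its anchor base, so
  allele counts always sum to depth. Calls and truth are matched after
  left-normalisation, so the aligner's gap placement cannot create
  false discordances.
* **Specificity** needs a negative universe; the per-site definition
  (all evaluated reference positions carrying neither truth nor call) is
  reported alongside precision, because published specificities rarely
  state their universe and the value depends on it strongly.
* The **breakpoint truth generator** redraws junctions whose retained
  continuation aligns past the junction with positive affine-gap score
  (exact microhomology is the gapless special case). Such junctions have
  no single well-defined coordinate — an aligner extends across them —
  and real callers report a homology interval there instead; ±1 bp
  recovery is only a meaningful claim against junctions where the
  coordinate exists.

## Problem sizes

The shipped experiments run at deliberate scale-downs chosen so each
statistic operates where it does at production depth: the full
validation experiment uses the complete stated conditions (33 duplicated
exons, six copies, 1000×, ~120 planted variants; about 30–40 s), CNV
recovery uses a 30-exon master-only locus at 400× against six controls
(per-exon log2 noise sd ≈ 0.08 against the 0.6 threshold; the production-scale
depth is ~5× higher), and breakpoint recovery uses 50 deletions of
0.5–5 kb on 10 kb loci with reads simulated in a ±400 bp junction
window. A master-only locus is used for CNV because the depth-ratio
statistic is orthogonal to competitive mapping; the interaction between
the two is handled by the filter ledger, which is tested on constructed
calls.

## Known limitations

* The built-in mapper exists for desk-scale reproducibility; it makes no
  claim of equivalence with BWA-MEM, and production data should be mapped
  externally and ingested via `load_alignments()`.
* Duplicate marking, indel realignment and base-quality recalibration are
  not reimplemented; on error-free synthetic data their effect is
  neutral, on real data it is not.
* The caller is a fraction thresholder by design; it inherits the
  published method's blindness to sites whose evidence is spread across
  multiple alignments (no local assembly, no genotype likelihoods).
* Segmentation is per-target with a maximum segment size of 300 bp; no
  CBS/HMM segmentation, no purity or ploidy modelling.
* Mosaicism below the 8% tier is out of scope (it requires the ultra-deep
  amplicon workflow this package does not model).
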