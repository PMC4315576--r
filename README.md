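# pseudocall

Pseudogene-aware variant, copy-number and breakpoint calling for
segmentally duplicated loci, with a built-in simulator that makes the
whole analysis reproducible at desk scale.

## The problem

Some disease genes live inside segmental duplications. The archetype is
*PKD1* (autosomal dominant polycystic kidney disease): its first 33 exons
are duplicated into six pseudogenes at ~97.7% sequence identity, so short
reads from gene and pseudogenes compete for alignment. At a heterozygous
variant whose alternative allele coincides with a pseudogene base, the
variant-carrying reads align perfectly to the pseudogene and are lost
from the gene's pileup — the observed alternative-allele fraction *f* is
depressed, sometimes below ordinary calling thresholds. Diagnostic
pipelines for such loci therefore use tiered fraction thresholds instead
of genotype likelihoods:

* call a variant when *f* ≥ 0.20 of the total filtered depth,
* call it homozygous when *f* ≥ 0.85,
* and in mutation-negative samples, re-screen the duplicated region only
  at *f* ≥ 0.08 for candidates to confirm orthogonally.

Copy-number events are detected from per-exon depth ratios against a
control panel (log2 ratio beyond ±0.6 against ≥ 85% of controls = pass,
50–85% = indicated), filtered through a named ledger (critical exons,
recurrent artifact exons, low-coverage exons, heterozygous-evidence
inside a deletion), and deletion breakpoints are resolved from clustered
soft-clipped reads by Smith–Waterman placement of the clipped consensus,
with a 20-base sliding-window decomposition for repeat-obscured
endpoints.

`pseudocall` implements all of the above, plus the synthetic locus /
read simulation needed to validate it: a master gene with pseudogene
copies at a controlled identity, planted truth variants (including
variants deliberately planted to match pseudogene alleles), wgsim-style
paired-end reads (2 × 150 bp, outer distance 200, error rate 0.001,
1000× fragment coverage), and a seed-and-extend Smith–Waterman mapper so
competitive mapping happens inside the package rather than in an
external aligner. It is aimed at people building or validating
diagnostic pipelines for duplicated loci, and at anyone who wants a
self-contained model system for competitive read mapping.

## Worked example

Simulate a small duplicated locus, plant truth variants — 28 at
positions where the pseudogenes cannot interfere, 5 whose alternative
allele equals a pseudogene base — sequence, map, call and score:

```r
library(pseudocall)

locus <- locus_params(exon_count = 8, duplicated_exon_range = c(1, 8),
                      n_pseudogenes = 3, identity = 0.977)
cfg <- validation_config(locus = locus,
                         reads = read_sim_params(target_coverage = 200),
                         n_matched = 5, seed = 42)
ex <- run_validation_experiment(cfg)
ex
#> <validation_experiment>
#>   planted: 28 divergent + 5 pseudogene-matching variants
#>   standard-tier sensitivity (divergent class): 1.0000
#>   depressed pseudogene-matching sites: 3 of 5
```

Every divergent-position variant is recovered at the standard 20% tier
with no false positives. The pseudogene-matching class shows the
competitive-mapping effect directly:

```r
ex$matched_sites
#> # A tibble: 5 × 5
#>     pos depth observed_count observed_fraction depressed
#>   <int> <int>          <int>             <dbl> <lgl>
#> 1   160   299            171             0.572 FALSE
#> 2   429   313            146             0.466 FALSE
#> 3   729   286            125             0.437 TRUE
#> 4  1243   242             80             0.331 TRUE
#> 5  1881   244             74             0.303 TRUE
```

These are true heterozygous variants (expected fraction 0.5) whose
carrier reads drift to the pseudogene wherever the local sequence gives
the aligner no way to tell gene and copy apart; site 1881 has lost ~40%
of its evidence. `glance(ex)` returns the one-row summary
(sensitivity, per-site specificity, zygosity concordance, candidate and
critical-site counts), `tidy(ex)` the per-variant table, and
`autoplot(ex)` the alt-fraction dot plot with both thresholds.

The other half of the toolkit follows the same pattern:
`run_cnv_experiment(deleted_exons = 15:21)` plants a heterozygous
7-exon deletion, simulates six controls, and returns the merged `pass`
deletion spanning exactly `exon15 … exon21`;
`run_breakpoint_experiment(n_cases = 50)` plants deletions of 0.5–5 kb
and resolves their junctions to ±1 bp from clustered soft clips. A thin
command-line front end (`inst/cli/pseudocall.R`) exposes
`simulate-locus`, `simulate-reads`, `map`, `call` and `validate`
subcommands over the same functions.

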