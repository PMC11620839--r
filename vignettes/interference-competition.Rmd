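---
title: "Modelling interference competition by an intron homing endonuclease"
author: "phageHoming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interference competition by an intron homing endonuclease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageHoming)
```

## The biological system

Nucleus-forming jumbo phages (chimalliviruses such as PhiKZ and
PhiPA3 of *Pseudomonas aeruginosa*) enclose their replicating genomes
in a proteinaceous compartment that selectively imports proteins.
One phage may carry, inside a group I self-splicing intron that
interrupts a virion RNA polymerase (vRNAP) gene, a homing
endonuclease. The enzyme cleaves the intron-less (intron(−)) allele
of its own insertion site — including the homologous locus of a
co-infecting competitor. When co-infection produces a *hybrid*
nuclear compartment that imports proteins of both phages, the
endonuclease reaches the competitor's genome, cleaves its vRNAP
gene, blocks capsid maturation and eliminates that cell's competitor
progeny. Cleavage can be reversed by recombination with the
intron(+) allele (homing proper: unilateral gene conversion that
copies the intron in), but only when the genomes share a compartment
and enough flanking homology.

`phageHoming` implements this system as four connected layers: a
per-cell stochastic competition model with a closed-form companion
and an inference routine; the assay statistics applied to
plaque-titer and count data; the sequence-level genetics of the
insertion site; and a synthetic fluorescence-image quantification of
intracellular DNA redistribution. A synthetic-data module generates
every input the analyses consume.

## The co-infection model

Per cell, infection counts for the intron(+) strain A and the
intron(−) strain B are independent Poisson draws at their
multiplicities of infection (MOIs). Strain A always bursts when
present. In a co-infected cell, strain B's lineage is eliminated
when four independent events line up:

* a hybrid compartment forms, probability $h$;
* the target site is not a pre-existing heritable escape mutant,
  probability $1-\mu$;
* cleavage succeeds, probability $k$;
* recombination rescue fails, probability $1-r_{\mathrm{eff}}$.

The effective per-co-infection interference probability is
$q = h\,k\,(1-\mu)(1-r_{\mathrm{eff}})$. With
$P_0 = e^{-\mathrm{MOI}_A}$ the probability that a B-infected cell
escapes co-infection entirely, the expected fold-change of the B
population when the endonuclease is inactivated versus active is

$$F \;=\; \frac{1}{P_0 + (1-P_0)(1-q)},$$

which `expectedFoldChange()` evaluates and `fitInterference()`
inverts exactly: $\hat q = (1 - 1/F)/(1 - P_0)$.

### Parameter defaults and their provenance

| parameter | default | reading |
|---|---|---|
| `moiA`, `moiB` | 10, 0.1 | the one-round competition design, chosen so nearly every B-infected cell is co-infected |
| `h` | 0.536 | measured fraction of co-infection nuclei importing both phages' proteins (75 of 140) |
| `k` | 1 | calibration choice, not a measurement: cleavage is treated as certain given import and an intact site |
| `mu` | 1.7e-5 | calibration to the 0.0017% efficiency of plating under forced endonuclease import, where heritable escape is the only survival route |
| `rMax`, `identityThreshold` | 1, 0.7 | rescue is a hard threshold in flank identity; the vRNAP alleles of the two phages share only ~60%, so rescue is off by default |
| `burstSize` | 30 | typical jumbo-phage scale; all reported statistics are ratios, so the value cancels |
| `replicationRateB` | 1.2 | the intron(−) competitor replicates somewhat faster, giving it the replicative edge the interference must overcome |

The threshold form of $r(\mathrm{identity})$ is the simplest testable
choice consistent with "recombination limited by divergence"; a
smooth curve would add a shape parameter no data constrains.

Burst sizes enter as deterministic per-lineage yields: the burst
mean is the only moment any reported ratio depends on, and holding
it fixed keeps the Monte-Carlo error of the fold-change in closed
form (`foldChangeSE()`), at the cost of not modelling burst-size
variance — which would only widen, never bias, the ratios.

### Variance reduction and determinism

`simulateRound()` evaluates the endonuclease-active and -inactive
arms on common random numbers (same adsorption counts, same event
uniforms), which removes most Monte-Carlo variance from the
fold-change ratio and makes carrier progeny *identical* across arms
by construction. Trajectories (`simulateTrajectory()`) consume the
same number of random draws per generation whether or not the
endonuclease acts, so an endonuclease-deleted run with the same seed
is an exact seed-matched control. All stochastic entry points seed
from their parameter object and restore the caller's RNG state.

### The homing trajectory

`simulateTrajectory()` adds a Wright–Fisher-style pool update: each
generation the total MOI is split across genome classes (A, B
converted to intron(+), B intron(−)) in proportion to frequency,
and in non-compartmentalized cells where a cut is rescued, the
intron(−) lineage is converted — gene conversion copies the intron
in. With certain rescue in a shared compartment the intron allele
fixes within a few generations; with compartmentalized genomes the
same machinery only kills, and the competitor is suppressed below
its seed-matched neutral control.

## Assay statistics

The statistics mirror the conventions of plaque-assay analysis:

* `efficiencyOfPlating()` summarizes per-pair titer ratios with a
  geometric mean (ratios are analyzed on the log scale throughout);
* `ratioPairedTTest()` is a one-sample t-test of
  $\log_{10}(\mathrm{test}/\mathrm{control})$ against zero — the
  standard "ratio paired t-test";
* `unpairedTTest()` defaults to the pooled-variance Student form
  with a Welch option, since the convention does not fix the
  variant;
* `foldChange()` divides each experimental titer by the arithmetic
  mean of the control titers;
* percentages compared against reported values are rounded half-up
  to one decimal (`percentDecrease()`, `importFractions()`).

## Target-site genetics

Coordinates are 1-based and the CDS frame starts at position 1, so
codon $c$ spans nucleotides $3c-2 \ldots 3c$ and nucleotide 3214 is
the first base of codon 1072.

`findIntronInsertion()` solves a spliced split-alignment: the
uninterrupted homolog is partitioned at a single point, its prefix
aligned forward (starts anchored, ends free) and its suffix in
reverse, under affine gaps (+2/−1 match/mismatch, −4 gap open, −1
extend). Enforcing a *consistent* split — rather than taking two
independent flank argmaxes — is what makes recovery exact: an
independent left flank can drift into the intron on chance matches,
but under the consistent objective any such extension steals homolog
bases the right flank needs, and loses more than it gains. Ties
break to the leftmost insertion point. This convention also resolves
a genuine ambiguity: when an intron boundary base repeats the
adjacent exon base, two insertion coordinates describe the same
sequence, and the leftmost is reported. The synthetic generator
avoids creating such boundaries so round-trip tests are exact.

Detection thresholds are a fraction (default 0.2) of the maximum
attainable score. Under the default scores, flanks at 50% identity
score a fraction 0.25 of maximum while unrelated sequence has
negative expected score, so 0.2 separates the two regimes; insertion
recovery is exact in all tested constructions at 60% flank identity
and above, while at exactly 50% identity occasional shifts are
intrinsic (a locally mismatch-rich flank stretch adjacent to the
junction can legitimately outscore the constructed truth).

`mapHomologousSite()` reuses the flank machinery with free starts to
place the insertion junction on a competitor gene. By default the
critical escape-conferring positions are the two bases immediately
upstream of the junction-aligned coordinate; the PhiKZ gp178
geometry (junction at 3217, critical positions 3214/3215) is
expressed with `criticalOffsets = c(-3, -2)`. The endonuclease's
true recognition footprint is unknown, so the recognition window is
a configurable range rather than a fixed constant.

`recodeSilent()` places at most one synonymous substitution per
codon, which guarantees the requested Hamming distance and an
unchanged protein; asking for more substitutions than the window's
synonymously mutable codons is an explicit "infeasible" error that
reports the achievable maximum.

## Image quantification

`genCellImage()` draws a capsule-shaped cell with a mid-cell
Gaussian nucleus and punctate bouquet foci in the flanking cytosol,
spaced on a bin grid with alternating transverse offsets so foci do
not stack. `lineProfile()` samples along the long axis at 1-pixel
steps with bilinear interpolation, averaged over a 3-pixel band —
single-pixel lines are noise-dominated. `bouquetNucleusRatio()`
segments the nucleus as the connected Otsu-foreground component
containing the brightest mid-cell pixel and takes the cell-mask
pixels axially outside it as bouquet territory; degenerate images
(uniform, empty or mask-wide foreground) fall back to a fixed
central-third nucleus, and an image with no signal returns a
distinct "no nucleus" result. The region boundaries are a package
convention — the underlying assay does not define them — so only
ratios and their *direction* across conditions are meaningful, not
absolute values.

## The synthetic-data generators

The generators reproduce the statistical structure of the study
conditions: lognormal titer noise around expected means with 5
replicates per condition; binomial co-import counts (p = 0.536 over
140 nuclei); negative-binomial capsid counts with means 22.6
(control, N = 5 tomograms) and 0.76 (treated, N = 17) sharing one
dispersion parameter (size 16, calibrated once from the control
condition's standard error, 3.3 at N = 5); a multinomial escaper
spectrum placing 14/17 of escapes at nucleotide 3215 and 3/17 at
3214; and toy vRNAP allele pairs with a perfectly conserved 12-nt
core around the insertion point and flanks diverged to a configured
identity (default 60%), mutated codon-aware so translation never
hits a premature stop. Titer noise magnitude is not a measured
quantity; the default 0.2 log10 units (a ~1.6-fold one-sigma
multiplicative error) is a realistic plaque-assay spread and is
freely configurable.

What the generators deliberately do not emulate: plaque images, raw
tomograms, sequencing reads, burst-size variance, within-cell copy
number of genomes, or secondary structure of the intron. Passing
tests therefore demonstrate internal consistency of the models and
statistics under the stated distributions — not that real data obey
those distributions.

## Problem sizes and numerical choices

Stochastic rounds use $10^5$ cells (Monte-Carlo standard error of
the fold-change about 1% at the default calibration); trajectories
use $2\times10^4$–$5\times10^4$ cells over 10–20 generations;
alignment property suites use 100 random constructions with 60-nt
flanks and 300-nt introns; image cohorts use 50 cells per condition.
Closed-form/simulation agreement is asserted at three Monte-Carlo
standard errors; exact identities (fold-change inversion, codon
arithmetic) at $10^{-9}$ or tighter; statistics against brute-force
oracles at $10^{-10}$.

Degenerate inputs are handled as distinct results, not errors, where
the distinction is informative: colinear sequences yield "no
insertion detected", signal-free images "no nucleus". True
contract violations (negative MOI, non-positive titers, length
mismatches between sequences to be compared base-by-base) raise
errors immediately.

## Limitations

The competition model tracks lineages, not genome copies: one
successful cut eliminates a cell's intron(−) lineage, justified by
the near-total loss of filled capsids under forced import, but it
cannot represent partial within-cell escape. The rescue threshold
in identity is a stylized stand-in for a recombination efficiency
curve nobody has measured. Inference from a single observed
fold-change identifies only the product $q$; separating $k$ from
$h$, $\mu$ and rescue requires fixing the others, and the implied
$\hat k$ is clipped (with a flag) when the observed fold exceeds
what the fixed factors allow. The image module is 2-D and
single-channel; membrane signal is generated nowhere and z-structure
is not modelled.
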