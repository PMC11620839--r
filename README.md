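# phageHoming

Quantitative models and statistics for **interference competition
between co-infecting bacteriophages mediated by an intron homing
endonuclease**.

Nucleus-forming jumbo phages (chimalliviruses such as PhiKZ and
PhiPA3) shield their genomes inside a protein compartment with
selective protein import. One phage can carry, inside a group I
intron interrupting a virion RNA polymerase gene, a homing
endonuclease that cleaves the intron-less allele of its insertion
site — including the homologous locus of a co-infecting competitor.
When co-infection produces a hybrid compartment importing both
phages' proteins, the endonuclease reaches the competitor's genome,
blocks its virion assembly, and hands its host a relative fitness
advantage. This package is for researchers who want to simulate,
analyze and reason about that system quantitatively.

## What it computes

**Co-infection model.** Per cell, infection counts are
Poisson(MOI). In a co-infected cell the intron(−) phage lineage is
eliminated with probability

    q = h · k · (1 − μ) · (1 − r_eff)

(hybrid compartment `h`, cleavage `k`, heritable escape `μ`,
recombination rescue `r_eff`, a hard threshold in flank identity).
With `P0 = exp(−MOI_A)`, the expected competitor fold-change
(endonuclease inactive / active) is

    F = 1 / (P0 + (1 − P0)(1 − q))

`simulateRound()` is the stochastic version (common random numbers
across arms), `expectedFoldChange()` the closed form,
`fitInterference()` its exact inverse (`q̂ = (1 − 1/F)/(1 − P0)`),
and `simulateTrajectory()` iterates a Wright–Fisher-style pool with
homing gene conversion.

**Assay statistics.** `efficiencyOfPlating()` (geometric-mean EOP),
`foldChange()`, `ratioPairedTTest()` (one-sample t on log ratios),
`unpairedTTest()`, `capsidCountSummary()`, `percentDecrease()`,
`importFractions()`.

**Target-site genetics.** `findIntronInsertion()` (split-consistent
spliced alignment, Rcpp kernel), `mapHomologousSite()`,
`classifyEscaper()` (substitution → codon → amino-acid-change
labels like `D1072A`), `recodeSilent()`, `percentIdentity()`.

**Image quantification.** `genCellImage()`, `lineProfile()`
(3-pixel-band bisecting profile), `bouquetNucleusRatio()`
(Otsu-segmented nucleus vs flanking bouquet regions),
`bouquetRatioExperiment()`.

**Synthetic data.** `syntheticConfig()` plus generators for noisy
titer tables, import counts, capsid counts, escaper spectra and toy
intron(+)/intron(−) gene pairs at a configurable identity.

## Worked example

One round of competition at the calibrated study conditions — MOIs
10 (intron(+)) and 0.1 (intron(−)), hybrid-compartment probability
0.536, certain cleavage, escape frequency 1.7e-5:

```r
library(phageHoming)
p <- interferenceParams(nCells = 1e5, seed = 1)
rr <- simulateRound(p)
rr
#> RoundResult (one round of co-infection competition)
#>   progeny (endonuclease active):   A = 3e+06, B = 1.594e+05
#>   progeny (endonuclease inactive): A = 3e+06, B = 3.409e+05
#>   intron(-) fold-change vs control: 2.139  (q = 0.536)
expectedFoldChange(p)
#> [1] 2.155017
```

The simulated fold-change (2.139 ± ~0.023 Monte-Carlo SE) agrees
with the closed form: under these conditions the endonuclease costs
the competitor a bit over two-fold per infection cycle, while
carrier progeny (strain A) is identical whether or not the
endonuclease acts. Inverting an observed 3.7-fold competition
deficit gives the interference strength the data imply:

```r
fitInterference(3.7, interferenceParams(moiA = 10))
#> $q
#> [1] 0.7297629
#> $k
#> [1] 1
#> $clipped
#> [1] TRUE
```

A 3.7-fold deficit corresponds to an effective interference
probability of 0.73 per co-infected cell — more than the measured
hybrid-compartment fraction (0.536) alone can deliver, which is why
the implied cleavage probability clips at 1 (flagged).

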