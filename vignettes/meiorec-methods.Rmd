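---
title: "Models and methods behind meiorec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meiorec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meiorec)
```

meiorec bundles three analyses of meiotic recombination — crossover (CO)
calling from low-coverage backcross sequencing, tetrad/single-pollen
genetics, and single-molecule spot quantification — together with a
synthetic-data generator that produces inputs with known ground truth for
all of them. This vignette describes the underlying models, the tunable
parameters and their defaults, the numerical conventions, and what the
validation suite does and does not demonstrate.

## The BC1 design and the pooled heterozygosity score

An F1 hybrid between two fully homozygous accessions (Col-0 and Ws) is
backcrossed as pollen donor to Col-0. Each BC1 offspring inherits one
intact Col-0 genome and one F1 gamete; at any locus it is either
heterozygous Col-0/Ws or homozygous Col-0, and the boundaries between such
blocks are exactly the crossovers of the single F1 meiosis that produced
the gamete. Only *informative* SNPs are used: sites homozygous for
different alleles in the two parents and heterozygous in the F1
(`select_informative_sites()`).

At 1–9× coverage, per-SNP genotype calls are unreliable, so 100 adjacent
SNPs are pooled into a bin (`bin_snps()`). Read counts — not per-SNP scores
— are summed over the bin before computing

$$h = \frac{2RA}{(R+A)^2},$$

where $R$ and $A$ are the bin's Col-0 and Ws read counts. Pooling counts
rather than averaging per-SNP scores matters at 1× coverage, where most
sites have 0 or 1 reads and a per-SNP score is degenerate. $h$ is symmetric
in $R$ and $A$ and lies in $[0, 0.5]$: about $0.5$ in heterozygous regions
and about $2\varepsilon$ in homozygous regions with per-read error
$\varepsilon$.

Bins are classified (`classify_bins()`) as homozygous when $h < 0.05$,
heterozygous when $h > 0.45$, and undetermined (UNDET) otherwise. Both
inequalities are strict; a score exactly at a threshold is undetermined.
Two situations the classification must handle are not fixed by the score
itself and are resolved as follows:

* a bin with zero reads has an undefined score and is UNDET
  (a `min_reads` parameter, default 1, generalizes this);
* a homozygous bin dominated by Ws reads is impossible under the BC1
  pedigree; it is flagged with a warning as likely contamination or a
  sample mix-up, and never interpreted as a crossover.

Chromosome tails shorter than a full bin are kept as their own bin when
they contain at least `min_tail = 50` SNPs and merged into the preceding
bin otherwise — discarding chromosome ends would lose real crossovers,
while very small bins would have too few reads for a stable score.

### Switch detection and breakpoint intervals

`call_crossovers()` scans the determined (HOM/HET) bins of each chromosome
in order; every class change emits one call. UNDET bins never emit or
suppress calls — they are skipped, counted in `n_undetermined_spanned`,
and simply widen the breakpoint interval. The interval is delimited by the
adjacent SNPs of the two flanking determined bins: `left_pos` (last SNP of
the left bin) and `right_pos` (first SNP of the right bin). Two adjacent
switches (HET→HOM→HET) are two calls; no minimum-block filter is applied
by default (`min_block_bins = 1`).

The two-SNP interval is the method's natural point estimate, but it is not
a confidence interval. If the true breakpoint falls in the last
(approximately) third of a bin, the pooled score of that bin still exceeds
0.45 — the mixture leaves $h = (1-f^2)/2 > 0.45$ whenever the discordant
fraction $f < 0.316$ — so the bin classifies as the left-hand class and
the true crossover lies *left of* `left_pos`. At any coverage this
affects roughly a third of crossovers. Each call therefore also carries
conservative bounds `left_bound`/`right_bound` spanning the full extent of
the two flanking determined bins; the true breakpoint is contained in
`(left_bound, right_bound]` whenever the crossover is detected at all.
Validation checks containment against these bounds.

### A known blind spot: terminal bins

A crossover in the interior of a chromosome's *first or last* bin leaves
that bin UNDET (or assigns it the interior class), and with no determined
bin beyond it the switch rule has nothing to compare against: the
crossover is missed. The per-crossover miss probability is about
$0.68 \times (\text{terminal-bin fraction of the map})$. At the real
study's scale (457,591 SNPs, ≈4,576 bins) this is negligible (<0.3% of
crossovers); at the package's desk scale (20,000 SNPs, 200 bins, ~5.2
crossovers per genome) it loses ~0.17 crossovers per genome, so only
~84% of genomes are recovered with an exactly correct genome-wide count.
The validation suite runs at desk scale and reports this number; it should
not be read as the method's accuracy at full scale.

## Synthetic BC1 cohorts

`arabidopsis_like_genome()` builds a scaled genome: five chromosomes with
physical lengths in TAIR10 proportions, 20,000 informative SNPs placed
uniformly at random (mean spacing ≈1,534 bp, as in the real SNP set), and
genetic lengths summing to 520 cM so that a gamete carries ≈5.2 crossovers
— the wild-type genome-wide mean. Centromere positions use the
approximate TAIR10 arm ratios.

Crossovers are simulated directly on the transmitted gamete
(`simulate_crossovers()`) as a *stationary gamma renewal process* on the
genetic map: inter-event distances are Gamma(shape $\nu$, mean 100 cM),
and the first event is drawn from the equilibrium (length-biased) forward
recurrence distribution, so the expected count on a map of length $L$ cM
is exactly $L/100$ with no origin effect. $\nu = 1$ is the no-interference
(Poisson) case; larger $\nu$ spaces events more evenly and underdisperses
counts. The default $\nu = 5$ gives interference of roughly the strength
seen in Arabidopsis wild type. Simulating on the gamete rather than on a
four-chromatid bivalent with thinning keeps the marginal rate identical
and is all the caller can observe anyway; $\nu$ is therefore a
gamete-level interference knob, not a chiasma-level one.

Physical positions assume a uniform recombination rate along each
chromosome — adequate for testing a caller whose resolution is the bin,
though real Arabidopsis maps are suppressed at centromeres and elevated
near telomeres.

Sequencing is modelled per SNP as Poisson(λ) depth; at heterozygous sites
each read is Col-0 with probability 1/2, at homozygous sites with
probability 1; every read's allele flips with probability ε. Defaults
λ = 3.0 and ε = 0.005 match the study's low-coverage regime. The
simulation does not model read mapping, indels, gene conversion tracts, or
an obligate crossover per bivalent (chromosomes without a crossover simply
occur at their renewal-process frequency).

## Tetrad genetics

For two linked hemizygous markers, a tetrad is a parental ditype (PD),
tetratype (TT) or nonparental ditype (NPD); `interval_ditype()` applies
the definitions strictly and treats anything else — including non-2:2
marker segregation — as malformed, excluded and counted, never repaired.
Perkins' formula converts counts to map distance,
$\text{cM} = 100\,(TT/2 + 3\,NPD)/n$.

The interference ratio partitions tetrads by the adjacent interval's
crossover status (PD versus TT-or-NPD; NPD is a subgroup label, not a
weight) and divides the focal interval's Perkins distance *with* an
adjacent crossover by that *without*. This orientation — interference
gives IFR < 1, clustering IFR > 1 — matches the published wild-type
(0.19–0.36) and mutant (>1) values. When a subgroup is empty or the
baseline distance is zero the ratio is undefined (`NA` with a warning).

### The tetrad simulator

`simulate_tetrads()` uses a two-interval 0/1-chiasma model: interval $i$
receives a chiasma with probability $d_i/50$ (so the tetratype frequency
is $2d_i/100$ and Perkins recovers $d_i$), and both intervals jointly with
probability $S\,(d_1/50)(d_2/50)$, where $S$ is the coefficient of
coincidence. Each chiasma involves one chromatid of each homolog, chosen
uniformly and independently per interval (no chromatid interference).
Spore genotypes are obtained by tracking molecules through the strand
permutation: a chiasma joins the molecules *currently occupying* the two
chosen strands, which is what makes three-strand double crossovers come
out double-recombinant rather than silently parental.

Within-interval double chiasmata are neglected — valid for the 3–11 cM
intervals analyzed, where simulated NPDs essentially never arise — but the
analysis functions handle NPDs in real data. Under this model the
estimable interference ratio is

$$\mathrm{IFR} = \frac{S\,(1-p_2)}{1-S\,p_2}, \qquad p_2 = d_2/50,$$

which tends to $S$ as the intervals shrink. At $d = 6.2$ cM and $S = 0.2$
the exact value is 0.180; validation therefore checks the estimate
against this exact model value (within three standard errors) *and*
against $S$ with an absolute margin of 0.05 that covers the small-$d$
bias. $S = 1$ gives IFR = 1 exactly.

`tetrads_to_pollen()` expands tetrads into single grains scored for one
interval's flanking markers; on NPD-free data the single-pollen distance
equals the tetrad Perkins distance identically (both reduce to the
recombinant-chromatid fraction).

## Spot counting

`find_maxima()` reproduces the flood-based semantics of ImageJ's "Find
Maxima": candidates (pixels not exceeded by any 8-neighbour) are processed
in decreasing intensity; each grows a region over connected pixels with
intensity above `peak − noise_tolerance`; a candidate whose region touches
territory claimed by a higher maximum is absorbed; a plateau yields a
single maximum at its centroid. The published "threshold of 6,000" is
interpreted as this noise tolerance (prominence), not an absolute
intensity floor — that is the parameter ImageJ's function actually takes.
Two boundary conventions are fixed deliberately:

* plateau centroids at exact half-pixels round toward the top-left;
* a plateau whose tolerance region covers the entire image has no
  prominence anywhere and is not counted, so a constant image yields zero
  maxima.

With `exclude_border = TRUE` (default), maxima on the outermost pixel
row/column are discarded. No background subtraction, flat-fielding, PSF
fitting or sub-pixel localization is performed.

`render_spot_image()` generates ground-truth images: isotropic Gaussian
peaks (integer-pixel centers, pairwise separation ≥ 6σ) on a constant
background, optional Gaussian noise, rounded and clipped to the 16-bit
range. On noiseless renders with amplitude above the tolerance the finder
attains recall and precision 1.0 at exact pixel positions.

`oligo_fraction()` divides volume-normalized summed oligo-channel counts
by volume-normalized summed protein-channel counts;
`fold_change()` is the mutant/wild-type ratio of such fractions, with
per-replicate ratios and their mean ± SD when replicate vectors are given.

## Group comparisons

`compare_groups()` implements the study's test-selection rule: both groups
are screened with the D'Agostino–Pearson omnibus K2 normality test
(implemented in-package from the standard skewness and kurtosis
transformations and verified against an independent implementation); if
both pass at α = 0.05 an unpaired two-tailed Welch t test is used,
otherwise a two-tailed Mann–Whitney U test. K2 is undefined below n = 8,
so smaller groups default to Mann–Whitney. The Mann–Whitney p-value is
exact for groups of ≤ 20 without ties and uses the tie-corrected normal
approximation otherwise; exact p-values from other software may differ
slightly in tie handling. Fisher's exact test for recombinant fractions is
two-sided by point-probability summation.

## Synthetic golden data sets

The raw published tables (tetrad scores, single-pollen scores, the
single-molecule overview) are not redistributed. `synthetic_golden_*()`
load *synthetic reconstructions*: joint ditype count tables and per-image
count manifests solved so that the package's estimators reproduce the
published summary values at printed precision (e.g. I5d 6.2 cM wild type /
11 cM mutant, interference ratios 0.36 and 1.37 at n = 4,682 and 696
tetrads, single-pollen 1.7 and 7.0 cM, fold changes 1.87 and 2.11). They
exercise the full analysis path deterministically but contain no
information about the real raw data beyond those summaries; in particular
the joint counts are one of several integer solutions consistent with the
published values. The recorded `focal`/`adjacent` pairing (I5d given I5c;
I2a given I2b) is the direction that reproduces the printed ratios.

## Problem sizes and reproducibility

The validation suite uses 20,000-SNP genomes with 40 samples for caller
recovery, 10^5 simulated tetrads for distance/coincidence recovery, and
256×256-pixel images with 50 spots for the maxima finder; all stochastic
tests fix seeds and test statistical claims at three standard errors or
with chi-square goodness-of-fit at α = 0.01. All randomness flows through
R's global RNG: `set.seed()` before a pipeline makes
simulate → bin → classify → call bit-reproducible. Run configurations are
YAML (`read_run_config()`), and the command-line wrapper `exec/meiorec`
echoes its parameters into JSON alongside its outputs.

## Known limitations

* Terminal-bin crossovers are structurally invisible to bin-level switch
  detection (quantified above); callers needing chromosome-end sensitivity
  would have to model partial-bin evidence explicitly.
* The caller does not detect gene-conversion (noncrossover) tracts, which
  are far shorter than a 100-SNP bin.
* The backcross simulator assumes a uniform genetic-to-physical map and no
  obligate crossover.
* The tetrad simulator omits within-interval double chiasmata and hence
  never produces NPDs; NPD handling in the estimators is validated on
  constructed tables instead.
* The spot model uses isotropic Gaussians on constant background; it does
  not emulate TIRF background gradients, camera gain artefacts or
  overlapping molecules.
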