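---
title: "Methods: the chromatin-guided methylation model and its estimators"
author: "chromameth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the chromatin-guided methylation model and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`chromameth` analyses how chromatin features shape the de novo DNA
methylation deposited by an ectopic DNMT3B in a naive genome, and ships a
generative model of such an experiment so every estimator can be
exercised against known ground truth. This vignette records the model,
the estimator definitions, the numerical choices, and the design
decisions taken where the problem was genuinely open — the things a
maintainer would want to know before changing a default.

# The generative model

## Genome and annotation

Chromosome sequences are drawn from a first-order model with configurable
GC content (default 0.40) and a CpG-enrichment multiplier on the C→G
transition (default 1, i.e. independent bases); a separate lambda-like
spike-in contig (20 kb) is carried through every stage as fully
unmethylated ground truth. Genes (150 by default, truncated-normal
lengths of 1400 ± 400 bp, minimum 400 bp) are placed sequentially with
500–1200 bp intergenic gaps, random strand, and log-normal expression
(sdlog 0.5). Coordinates in all tables and interchange files are 0-based
half-open; a '−' strand cytosine is recorded at the position of its G
complement on the + strand.

## Nucleosomes

Each gene carries a phased dyad array through its body — dyads at
oriented offsets NRL/2, 3·NRL/2, … from the TSS with no jitter — and
nucleosome-free regions (NFRs) spanning twice the NFR half-width (80 bp)
immediately upstream of the start and downstream of the end. Intergenic
stretches are filled with dyads at NRL spacing plus Gaussian jitter
(sd 5 bp). Occupancy is the indicator of being within ±73 bp (the core
half-width) of a dyad. The defaults NRL = 170 and core = 73 give 24-bp
linkers inside arrays.

## Marks

Histone marks are carried by nucleosomes, so the H3K4me3 bump (Gaussian,
sd 150 bp, amplitude ∝ expression) is centred on the **+1 nucleosome**
(TSS + NRL/2), not on the TSS itself: the promoter NFR is
nucleosome-free and carries no histone mark. This placement matters
quantitatively — centring the bump on the TSS would put suppression mass
on NFR linker DNA and bias the linker/core methylation contrast well
below its construction value. H3K36me3 ramps linearly 0 → expression
across the body toward the TTS; H3K4me1 is a mid-body plateau; Pol II is
flat over the body at the expression level. Tracks are normalized to max
1 genome-wide and zeroed on the spike-in. Genotypes: `set1` removes
H3K4me3/H3K4me1, `set2` removes H3K36me3, `dot1` changes no track (H3K79
methylation does not enter the model); all deletion strains express the
induced enzyme at 0.6 of the wild-type level (`expressionScale`),
reflecting their reduced induction.

## Methylation probability and counts

For a CpG cytosine at position $i$:

$$p(i) = \mathrm{clamp}\!\left(p_0\, L(i)\, H(i)\,
  e^{\,w_{36} s_{36}(i) - w_4 s_4(i)}\, g,\; 0,\; 0.95\right)$$

with $p_0 = 0.035$; $L = 1.5$ outside dyad ± 73 bp and 1 inside (the
linker preference); $H = 1 + 0.15\cos(2\pi d/10)$ inside cores (helical
pitch modulation, $d$ = distance to the nearest dyad); $s_4, s_{36}$ the
normalized mark tracks with weights $w_4 = 1.2$, $w_{36} = 0.8$; and $g$
the genotype activity scale. Non-CpG cytosines get $5\times10^{-4} g$;
the spike-in is exactly 0. The 0.95 clamp prevents degenerate saturated
sites. The DNMT3b occupancy track is defined as the 147-bp moving
average of $p$ over cytosines, normalized to max 1 — the enzyme sits
where it methylates.

Counts are simulated at the per-cytosine level (no read-level
simulation; counts are the unit all downstream mathematics consumes):
coverage ~ Poisson(20), methylated reads ~ Binomial(cov, $q$) with
$q = p + (1-p)\varepsilon$ and non-conversion error
$\varepsilon = 0.0027$.

The $w_4/w_{36}$ weights are calibration constants of the landscape, not
measured quantities: they were chosen, once, together with the +1
nucleosome mark placement, so that the default landscape reproduces the
magnitudes the analysis pipeline is designed to detect (a CpG level of a
few percent, an order-of-magnitude CpG preference, a ~50% linker
contrast) while keeping both mark effects strong enough to dominate the
binned regression. All defaults live in `syntheticConfig()` and are not
revisited per analysis.

# Estimators

## Levels

`weightedLevel` is the pooled count ratio $\sum mc / \sum cov$ — the
standard WGBS summary — and is used wherever a single number is
reported. Within profiles, per-site levels $mc/cov$ are averaged instead
(each covered site one observation), which keeps profile bins comparable
when coverage varies; whether figure-style summaries should be pooled or
site-averaged is genuinely underdetermined, so both are exposed
(`weightedLevel` vs `siteSignal`) with pooled as the default for scalar
reports. Symmetric CpG strand records are kept separate throughout — the
generator emits both strands independently and no merging rule is
assumed. Cytosines within 2 bp of a contig end are flagged
unclassifiable (`NA` context) and excluded from summaries. Reported
levels are *not* corrected for non-conversion; `correctNonconversion` is
available, and clamps corrected per-site levels at 0 — for pooled
ratios, correct the pooled means instead (clamping mc = 0 sites biases
ratios downward).

## Profiles

`anchoredProfile` averages observations per strand-oriented offset with
exact n bookkeeping; unobserved offsets are `NA`, never zero-filled.
`metageneProfile` uses 60 body bins and 1000-bp flanks at 25 bp/bin,
weights genes equally (per-bin mean of per-gene means, so long genes do
not dominate), and excludes genes under 300 bp. `metaNucleosome` treats
dyads as strandless anchors contributing in both orientations.

## Periodicity

`estimatePeriodicity` subtracts a centred moving average of width
`maxPeriod`, computes the autocorrelation function, and takes the lag of
the highest autocorrelation in the search range (smallest lag on exact
ties). One refinement: a signal of period $P$ is equally correlated at
every multiple of $P$, so when an in-range integer divisor of the argmax
lag reaches ≥ 75% of the maximum autocorrelation, the smallest such
divisor is returned. This resolves the fundamental-vs-harmonic ambiguity
(a 10-bp helical signal searched over 5–20 bp is nearly as correlated at
lag 20 as at lag 10, and sampling noise can flip the argmax) without
ever displacing a true long period, whose sub-multiples are
anti-correlated. Missing interior bins are linearly interpolated and
counted; the profile must span at least 3× `maxPeriod`.

## Linker-vs-core contrast

`linkerCoreIncrease` stratifies observations by distance to the nearest
dyad (core ≤ 73 bp) and returns $100(L-C)/C$ on weighted stratum means.
With `maxDist = NRL/2` it becomes the meta-nucleosome version: only
sites within half a repeat length of a dyad are sampled, so the linker
stratum is the DNA between adjacent nucleosomes and both strata share
the same regional composition. That restriction matters: genome-wide,
linker DNA is over-represented in NFRs and nucleosome-depleted
intergenic stretches, whose mark environment differs systematically from
gene-body cores, and the unrestricted contrast conflates nucleosome
positioning with mark effects. The package's parameter-recovery check
uses the restricted contrast on non-conversion-corrected pooled means,
which recovers the construction value $100(\text{linkerFactor}-1)$.

## Stratification and correlation

Deciles are assigned by stable sort on (key, unit id) — a deterministic
function of both — into 10 groups whose sizes differ by at most one,
extras to the lower deciles. Spearman matrices use pairwise-complete
observations with per-pair n reported. The qualitative sign structure
(methylation vs marks) is evaluated on 200-bp genome bins rather than on
per-gene summaries: in the generative model both the H3K4me3 amplitude
and the H3K36me3-driven methylation gain scale with the same per-gene
expression value, so gene-level ranks of the two are confounded
positively, while the spatial (bin-level) correlation isolates the
within-gene architecture — promoter-proximal suppression, 3'-body
promotion — which is the structure the marks model encodes. Real data
are not subject to this particular confound in the same way; gene-level
summaries remain available via `summarizeUnits` (region modes: whole
body, last third, promoter = TSS ± 300 bp).

## Mutant normalization

Two normalizations are provided, mirroring experimental practice:
`normalizeTotal` divides per-site levels by the sample's genome-wide
weighted CpG level (the interpretation adopted for "total amount of DNA
methylation"), and `scaleByExpression` divides by a relative expression
fold, e.g. from `ddctRelativeExpression` ($2^{-\Delta\Delta Ct}$ against
a reference gene). `mutantWtRatio` divides profiles bin-by-bin on
identical grids, flagging (not dividing) bins whose wild-type mean is
below $10^{-4}$.

## Binned linear model

`binFeatures` drops partial end bins and the spike-in, averages each
track per 200-bp bin, pools CpG counts into a weighted level (missing if
no covered CpG), and natural-log-transforms with pseudocount $10^{-3}$
(the log base is immaterial to R²; the pseudocount bounds empty-signal
bins). `fitLinearModel` is ordinary least squares via `lm()`; constant
or aliased predictors are dropped with a warning (the pseudo-inverse
situation arises only from degenerate tracks, e.g. H3K36me3 in a `set2`
run). `comparePredictorSets` fits every set on the complete cases of the
union of predictors so adjusted R² values are directly comparable.

# Problem sizes and determinism

The reference landscape is 2 × 200 kb chromosomes + 20 kb spike-in, 150
genes, coverage 20 — about 168,000 cytosine records, of which ~160,000
read observations fall on the spike-in — sized so a full simulation and
analysis completes in seconds and the spike-in estimate has a relative
SD below 5%. Unit tests run on a 30-kb single-chromosome landscape.
Every stochastic stage takes an explicit seed; `simulateExperiment`
derives per-stage seeds (seed, seed+1, …) so identical (config,
genotype, seed) reproduce byte-identical outputs end to end, including
pipeline file checksums.

# What the synthetic landscape does and does not emulate

It emulates the *statistical structure* the estimators assume: context
composition, NFR-flanked phased arrays, promoter/elongation mark
geometry scaled by expression, multiplicative mark effects on
methylation, spike-in purity, and binomial count noise at realistic
coverage. It does not emulate: sequence-dependent nucleosome
positioning or MNase bias; fuzzy/delocalized nucleosomes (occupancy is a
hard indicator); replication- or cell-cycle-linked methylation dynamics;
read-level artefacts (mapping, PCR duplicates, M-bias); mark breadth
variation independent of expression; or a mammalian-scale genome.
Passing parameter-recovery tests therefore shows the estimators are
correct and well-calibrated under the model's assumptions — not that the
model captures every property of real chromatin. In particular, the
expression-coupling of both marks makes gene-level mark/methylation
correlations uninformative in simulation (see above), a caveat that does
not transfer to real data.

# Known limitations

- The NFR geometry is symmetric at both gene ends; real promoter NFRs
  are wider and asymmetric.
- `correctNonconversion`'s per-site clamp makes corrected site-level
  distributions slightly non-linear near zero; pooled corrections avoid
  this.
- The periodicity estimator reports a single dominant period; it does
  not decompose mixtures of periods beyond the harmonic rule described
  above.
- `readTrackBedGraph` materializes per-base vectors and is intended for
  desk-scale contigs, not mammalian chromosomes.
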