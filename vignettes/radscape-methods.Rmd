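---
title: "Models and methods behind radscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscape)
```

radscape analyses the phylogeographic history of a species sampled in a few
disjunct regions from two complementary marker sets: a catalog of short
(~100 bp) nuclear RAD loci genotyped per individual, and a single
mitochondrial fragment (658 bp, CO1-like) sequenced for many individuals.
This vignette explains the models the package implements, the parameters
that matter, and the design choices made where more than one reasonable
convention exists.

## The coalescent simulator

All synthetic data come from a backward-time n-coalescent with piecewise
demography. A `scenario()` is a rooted divergence history: a set of leaf
populations with diploid effective sizes $N_e$, and merge events
$(t, \text{derived} \to \text{ancestral})$ ordered backward in time. Within
a population carrying $k$ lineages, coalescences occur at rate
$\binom{k}{2}/(2N_e^{(m)})$ per generation, where the marker-specific
effective size $N_e^{(m)}$ is $N_e$ for nuclear loci (a sampled diploid
individual contributes two lineages) and $N_e/4$ for the maternally
inherited haploid mitochondrial genome. Lineages in different populations
cannot coalesce before the populations merge; a history that strands
lineages in unmergeable populations is a configuration error.

Mutation is finite-sites with four states. Each locus holds a fixed mask of
variable sites, $L_\text{var} = L \cdot (1 - f_\text{inv})$: with the RAD
default $f_\text{inv} = 0.98$ a 100-bp locus carries 2 variable sites, which
is what makes a "$\le 2$ SNPs per locus" catalog arise naturally; the
mitochondrial default is $f_\text{inv} = 0.95$. Mutations per branch are
Poisson with mean $\mu \, L_\text{var} \, \ell$ for branch length $\ell$;
each hit lands on a uniform variable site and substitutes one of the other
three bases. Ancestral states are drawn from a configurable base
composition (default A 26.9%, C 22.8%, G 22.5%, T 27.8%). The engine is
written in C++ (Rcpp) and uses R's RNG throughout, so every simulation is
reproducible from `set.seed()` or a `seed` argument.

Two consequences of the deliberately small $L_\text{var}$ are worth knowing:

* recurrent mutation is not negligible. Same-site double hits deflate the
  segregating-site count a little more than the pairwise differences, which
  can push a pooled multi-locus Tajima's D slightly above zero at higher
  per-site $\theta$. The neutral calibration tests therefore assert the
  replicate-mean band $[-0.2, 0.2]$ rather than exact zero;
* one simulated dataset's pooled D is noisy (SD ≈ 0.26 for 1500 loci at
  that $\theta$), so calibration statements are made about replicate means.

The observation layer is separate from the genealogy: per locus and
individual a read depth is drawn from a negative binomial (mean 20,
dispersion 5 by default; `Inf` makes depths deterministic) and genotypes
below `min_depth` are masked. This reproduces the structure of real RAD
missingness — whole individuals drop out of a locus — without modelling
reads themselves.

The generator defaults mirror the study design the package targets: 17
diploid individuals in 8 sites across 4 regions (Black Forest 10, Massif
Central 2, Pyrenees 2, Cantabrian Mountains 3) for RAD, and 352 haploid
sequences in 26 sites (219/7/61/65) for the mitochondrial fragment. The
built-in scenario library ships the three histories that can be written
down unambiguously: vicariance `((CM,PY),(MC,BF))` (scenario 6), gradual
colonization from the Cantabrian Mountains `(CM,(PY,(MC,BF)))` (scenario
17) and its Pyrenean variant `(PY,(CM,(MC,BF)))` (scenario 20). Default
split times follow the strict-clock dating of the mitochondrial data
(0.21 My for MC/BF, 0.925 My for the deep north–south split, one
generation per year); default sizes place the larger $N_e$ in the more
diverse southern regions. All of this is overridable, and arbitrary
user-defined scenarios are first-class.

What the generator does *not* emulate: read-level error, allele dropout
through restriction-site mutations (null alleles), paralogy, selection,
migration after divergence, and linkage within loci beyond complete
linkage of a locus's 2 sites. Tests passing on synthetic data therefore
show correctness of the statistical machinery under the stated model, not
robustness to those artefacts.

## Catalog filtering

`filter_catalog()` applies the standard RAD hygiene rules in a fixed
order: depth masking of individual genotypes (default $\ge 5\times$),
removal of loci with any SNP showing more than two alleles (putative
paralogs), removal of loci with more than `max_snps` (default 2)
polymorphic sites, then a per-locus presence threshold (default 9 of the
genotyped individuals, i.e. 50% of 17; the stricter 11-individual setting
used for ABC input is the same rule with a higher cut). Depth is
interpreted per genotype, not per locus mean, because stack depths differ
between individuals; presence is counted after masking. The filter is
idempotent, and raising the presence threshold can only shrink the
retained set — both are tested properties.

## Diversity and differentiation statistics

Heterozygosity is per SNP by default (share of called SNP genotypes that
are heterozygous; a per-locus mode is available behind a flag since
printed "heterozygosity" percentages are sometimes per locus). Haplotype
diversity uses Nei's unbiased $H = \frac{n}{n-1}(1 - \sum p_i^2)$;
nucleotide diversity is the mean pairwise p-distance with pairwise
deletion. Tajima's D uses the 1989 constants from the region's sample
size; sites with missing data within a region are dropped for $S$.

$F_{ST}$ comes in three estimators: Weir–Cockerham $\theta$ for diploid
SNP catalogs, accumulated over SNPs and alleles as a ratio of sums
(negative estimates are reported as computed); Hudson's $1 - H_w/H_b$ for
haploid sequences; and a haplotype-identity variant of the latter (a
frequency-based haplotype $F_{ST}$) matching how mitochondrial
differentiation is conventionally reported. Significance testing permutes
individuals across the two regions (both chromosomes of an individual move
together).

The ABC summary-statistic vector follows the DIYABC convention: per region
(1) mean and (2) variance of pairwise differences, (3) Tajima's D, (4)
number of segregating sites; per region pair (5) the within mean `w`
(average of the two within-region means), (6) the between mean `b`, and
(7) $F_{ST}$ — with four regions, a 34-entry vector in a fixed order
(region blocks in popmap order, then pairs). Because multi-locus pooling is
a convention choice, we state ours: locus SNP columns are concatenated per
pseudo-haplotype (two per diploid individual, phase within a $\le 2$-SNP
locus arbitrary), pairwise differences are summed across loci, and $S$
counts segregating sites over columns complete within the region.
Statistics that are undefined on a dataset (D without a segregating site, a
region with fewer than two sequences) are `NA` sentinels; the ABC machinery
imputes them to the reference-table mean (zero after standardization) and
appends 0/1 indicator columns so that missingness itself remains
informative and the vector length stays fixed.

`strict_clock_time()` converts an uncorrected percent p-distance into an
age via a strict clock expressed as percent between-lineage divergence per
million years (default 3.54, an insect mitochondrial CO1 rate): 3.54%
corresponds to 1 My.

## Saturation diagnostics

Two resampling procedures ask how many loci are enough.

**Heterozygosity saturation** (`het_saturation()`): for subsample sizes
$L = 10, 20, \dots, 1000$ and (by default) 1000 replicates per size,
per-SNP heterozygosity is recomputed on a random locus subsample and
summarized as mean ± SD over replicates, per region or for two tracked
individuals (defaults: 1000 replicates for regions, 100 for individuals).
For speed, one replicate draws a single random locus permutation and the
grid sizes use its nested prefixes; at each $L$ the subsample is still a
uniform draw without replacement, so per-$L$ means and SDs are unchanged
while the loop is two orders of magnitude faster. The convergence point is
the smallest grid $L$ from which on the SD stays below a configured
fraction of the mean (region mode, default 0.1) or the two tracked
individuals' mean ± SD bands stop overlapping (individual mode).

**Topology saturation** (`topology_saturation()`): per replicate, $L$
sampled loci are concatenated into one pseudo-haplotype per individual
(heterozygous sites resolved to the catalog-wide major allele — a
documented simplification; monomorphic loci are legitimate draws that
contribute no columns), pairwise K2P distances are computed with pairwise
deletion, a neighbor-joining tree is built, and its distance to a
partially resolved reference (constraint) tree is measured with the
rescaled symmetric-difference metric. With $b$ nontrivial splits in the
test tree ($n-3$ when binary) and $k$ in the reference, the raw
Robinson–Foulds count $d$ is rescaled as $(d - (b-k))/(2k) \in [0,1]$; a
star reference ($k = 0$) is refused as degenerate. The default convergence
rule is the smallest grid $L$ whose mean distance is below 0.025 there and
at every larger grid point. The 0.025 default is taken as stated (5% of an
expected random rescaled distance of 0.5) rather than re-derived: under
the min–max rescaling above, random binary trees rescale near 1, so the
"expected 0.5" premise is not reproducible from the rescaling definition
and the threshold is treated as a configured constant.

The shipped 17-leaf constraint tree encodes four clades: the Black Forest
individuals, the Pyrenees pair, the three Cantabrian individuals, and the
north/south split (Black Forest + Massif Central vs the rest), with the
two Massif Central individuals left unresolved inside the northern group.

## Statistical-parsimony haplotype network

`collapse_haplotypes()` merges identical sequences (N matches any base; a
sequence containing N joins a fully called haplotype when compatible at
every site, ties resolved toward the lexicographically smallest
representative). `build_parsimony_network()` then builds a minimum
spanning network over haplotype Hamming distances: distance classes are
processed in increasing order and every edge of a class that links two
components still separate *before* the class is kept, so alternative
equal-length connections survive (a network, not a tree). Edges longer
than the connection limit are excluded — the network may fall apart into
components — and `force_connect = TRUE` afterwards adds the minimal
over-limit links, flagged, which is how a distant outgroup (e.g. 40 steps
away) can be drawn into the picture. An edge of $s$ steps implies $s - 1$
unsampled intermediate haplotypes. Full TCS-style loop breaking by
frequency criteria is deliberately not reproduced; all minimal
alternatives are reported.

The connection limit itself is the largest step count $j$ for which a
connection is non-homoplastic with probability at least $\alpha$ (default
0.95). The probability of parsimony is derived in-package from the same
model family the simulator uses: for two sequences of length $m$ differing
at $j$ sites, the pair coalescence time is exponential, per-site hits are
Poisson with a Jukes–Cantor four-state kernel, and the per-site scaled
rate is estimated from the observed divergence $j/m$ by method of moments
($\hat\theta = x/(1 - 4x/3)$ for $x = j/m$). The probability that every
observed difference is a single hit and no unseen site was hit integrates
in closed form in the numerator and numerically in the denominator.
Single-step connections are accepted by convention, making the limit 1 in
the $\alpha \to 1$ boundary. For $m = 658$ bp at $\alpha = 0.95$ the limit
evaluates to 8 steps; this value is frozen as a regression constant and
cross-checked against a Monte-Carlo simulation of the generative model in
the tests.

## ABC model choice

Priors are log-uniform in the DIYABC style: $N_e \in [1, 4\times10^5]$ for
the RAD marker and $[0.25, 10^5]$ for the mitochondrial effective size
itself (stored on the nuclear scale as $4 N_e^{mito}$), divergence times
in generations $\in [10^3, 10^7]$, mutation rates $[10^{-8}, 10^{-6}]$
(RAD) or $[10^{-7}, 10^{-5}]$ (mito). Event times are drawn independently
and sorted to respect the scenario's backward ordering — the exact
conditioning DIYABC applies is not documented, and sorting independent
log-uniforms is the simplest exchangeable choice.

`build_reference_table()` simulates equal numbers of parameter draws per
scenario and records each dataset's summary vector; per-statistic means
and SDs are stored for standardization. The table size is a configurable
budget: the analyses here use $10^4$ rows, which our recovery experiments
show is enough to separate the three built-in scenarios; production
analyses can raise it. Distances are Euclidean on standardized statistics
(no LDA projection). `abc_direct()` reports scenario shares among the
`n_closest` rows (default 500, the lower end of the conventional
500–50,000 window) with 95% Wilson intervals. `abc_logistic()` fits a
multinomial logistic regression of the scenario label on the standardized
statistics centered at the observed vector over the retained rows and
evaluates the fitted class probabilities at zero; intervals propagate the
intercept covariance through the softmax by the delta method, and complete
separation falls back to a flagged weight-decay (ridge) refit. Degenerate
statistics (zero variance across the table) are dropped with a warning.

`abc_scenario_recovery()` wraps the standard calibration experiment:
pseudo-observed datasets are simulated under a known scenario with
parameters from the prior, and both estimators are scored on how often
they rank the truth first. With the three built-in scenarios, priors
narrowed to deep splits ($N_e \in [5\times10^3, 5\times10^4]$,
$t \in [10^5, 2\times10^6]$ — chosen so that splits are mostly older than
$2N_e$ generations and histories are identifiable), 100-locus datasets and
a $10^4$-row table, logistic regression recovers the colonization
scenario in well over 80% of replicates, and logistic posteriors are
sharper than the direct shares, reproducing the qualitative direct vs
logistic contrast familiar from DIYABC-style analyses.

## Problem sizes and numerical conventions

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which the checked properties are stable:
simulator calibration on 1500 loci (8 replicates for the D band),
saturation on 1000–1200-locus catalogs with 100 replicates (individual
mode) or 15 (topology mode), and ABC recovery with a $10^4$-row reference
table and 50 pseudo-observed datasets. Other conventions: all locus
coordinates are 0-based within the locus; genotypes are unphased; NJ ties
follow ape's implementation; K2P saturation (non-positive log argument)
returns `Inf` and such replicates are skipped in saturation curves;
distance matrices must be symmetric with zero diagonal.

## Known limitations

The mutation model is Jukes–Cantor-like (no transition/transversion bias),
so on simulated data the K2P correction has little to correct — the K2P
machinery is exercised on toy and empirical-style inputs in the tests, not
because the generator favours transitions. The pseudo-haplotype resolution of heterozygous sites
slightly compresses between-individual distances at shallow divergence.
Migration and admixture events are not implemented; the scenario algebra
covers pure divergence histories only. The 17 graphically defined
alternative study scenarios are out of scope — users define their own with
`scenario()`.
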