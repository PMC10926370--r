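---
title: "Methods: admixture-based detection of Helicoverpa hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: admixture-based detection of Helicoverpa hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helihybrid)
```

## The problem

*Helicoverpa armigera* (Old World cotton bollworm) and *H. zea* (New
World corn earworm) diverged roughly 1.5 Myr ago, hybridize where the
invasive *armigera* meets local *zea* populations, and are essentially
indistinguishable morphologically. Identifying hybrids — and the fraction
of each genome deriving from each species — from whole-genome sequence is
therefore the practical route for surveillance. This vignette documents
the statistical model, the parameter choices, and the numerical behavior
of the pipeline, and is explicit about what the accompanying simulations
do and do not demonstrate.

## The admixture model and its estimators

Let $g_{ij} \in \{0,1,2\}$ be the alternate-allele dosage of individual
$i$ at biallelic SNP $j$, $q_{ik}$ the fraction of $i$'s genome from
population $k$ ($\sum_k q_{ik} = 1$), and $f_{kj}$ the alt-allele
frequency in population $k$. Each of the two allele copies is alt with
probability $p_{ij} = \sum_k q_{ik} f_{kj}$, giving

$$\ell(Q, F) = \sum_{i,j\,\text{called}} \Big[ g_{ij}\log p_{ij} +
  (2-g_{ij})\log(1-p_{ij}) \Big].$$

Missing genotypes are skipped term-wise; the per-individual count of
called sites $J_i$ enters the EM normalization so missingness does not
bias $q$.

**Unsupervised fit** (`fit_admixture()`): EM on both $Q$ and $F$. The
E-step attributes each observed allele copy to a population in
proportion to $q_{ik} f_{kj} / p_{ij}$ (alt copies) or
$q_{ik}(1-f_{kj})/(1-p_{ij})$ (ref copies); the M-step renormalizes.
EM was chosen over quasi-Newton block relaxation because it is simple,
provably monotone in $\ell$ (the test suite asserts the trace is
non-decreasing on every fit), and fully adequate at the panel sizes this
package targets (tens of genomes, thousands of pruned SNPs). The cost is
slower convergence near the boundary of the simplex; pure genomes
approach $q = 1$ geometrically, which is why the default iteration cap
is generous (2000) and the convergence criterion is
$|\Delta\ell| < 10^{-6}$.

**Supervised projection** (`fit_supervised()`): the K = 2 frequencies
are fixed at empirical alt frequencies of classified pure panels
(`reference_frequencies()`), and $\ell$ is maximized over each query's
$q$ alone — a one-dimensional concave problem solved by the same EM
restricted to $Q$, iterated to $|\Delta q| < 10^{-8}$. Tests verify the
EM optimum against a brute-force grid search (step $10^{-4}$) to within
$10^{-3}$. Projection is the right mode for scoring new field samples
against an established reference panel, and for validation: an F1 hybrid
has true $q = (0.5, 0.5)$ by construction.

**Numerical choices.** $F$ is clipped to $[\varepsilon, 1-\varepsilon]$
with $\varepsilon = 10^{-6}$ so fixed differences cannot produce
$\log 0$; the clip binds only at sites fixed in a fitted population and
does not measurably perturb $q$. Label switching (the model is invariant
to permuting populations) is resolved after fitting by correlating each
fitted $F$ row with empirical frequencies of species-labeled samples;
with no labels available the columns are reported as `pop1`/`pop2` with
a warning and ordered deterministically by the first sample's $q$.
Initialization is a seeded symmetric-Dirichlet $Q$ and perturbed
empirical frequencies for $F$; the seed is a mandatory part of the
configuration, and identical seed + data reproduce the fit bit for bit.

**Purity classification** (`classify_purity()`): a genome is called
unhybridized when $q \ge 0.99$ for one species. The threshold is strict
because the pure panels anchor everything downstream (reference
frequencies and AIM discovery); at the panel sizes used here the fitted
$q$ of truly pure genomes is within $10^{-3}$ of 1, so the call is not
threshold-sensitive.

## Site filtering

`filter_spec()` defaults: mean read depth $\ge 5$ (mean over **all**
samples, including zero-depth ones, since the joint caller emits
reference calls there), site quality $\ge 20$ (phred), minor allele
frequency $\ge 0.05$, and exclusion of `chr1`, the lepidopteran Z sex
chromosome, so ancestry is computed from autosomes only (hemizygosity in
females and sex-biased inheritance would otherwise distort $q$).
Removal conditions are stated strictly (`< 5` removed), so a site with
mean depth exactly 5.0 is kept. MAF is computed jointly across all
samples — the matrix comes from joint calling across both species, and
what the MAF filter must remove is sites that are rare *in the combined
panel* (mostly sequencing artifacts); a per-species MAF would discard
precisely the fixed interspecific differences that carry the ancestry
signal. Each criterion is counted independently in the filter report,
plus the union.

## LD pruning

The ancestry model assumes independent loci, so one member of each
highly correlated pair is removed first. `prune_ld()` computes squared
Pearson correlation of dosages (genotypes are unphased, so this is
allele-count LD, not haplotype LD) over jointly called samples, with a
zero-variance convention of $r^2 = 0$. Within sliding windows of 50
retained SNPs (step 5) per chromosome, while any pair exceeds
$r^2 = 0.95$, the lower-MAF member of the worst pair is removed (ties
broken toward the later position); passes repeat until a fixed point, so
the pruned set satisfies the threshold in its own frame and re-pruning
removes nothing. Only the $r^2$ threshold carries scientific meaning
here; the window/step geometry is a conventional default and is
configurable. On independent simulated loci with $\ge 40$ samples, fewer
than 5% of sites are removed, so the procedure does not starve the model
of data; on structured panels, perfectly diagnostic sites are mutually
correlated and are deliberately thinned to one representative per
window.

## AIM discovery, coding, and reference bias

With unhybridized panels identified, a site is a **zea-diagnostic AIM**
(`discover_aims()`) when (a) *every* zea reference genome carries at
least one alt allele — a missing genotype disqualifies the site, since
missingness cannot certify presence — and (b) at most one armigera
reference genome carries it. With 7 zea genomes this is the minor
allele count 7 (zea) / 1 (armigera) rule; the single tolerated armigera
carrier admits slightly imperfect markers and creates a small nonzero
floor in the AIM score of pure armigera genomes (visible in the worked
example in the README), while `max_armigera_carriers = 0` gives the
strict variant with a floor of exactly 0%.

Two codings of the per-genome AIM score are provided
(`aim_ancestry_proportion()`): **dosage** coding,
$100 \times \sum g / (2n)$, and **presence** coding,
$100 \times \#\{g \ge 1\}/n$. Dosage is the default because it is the
only coding whose expectation for an ideal F1 is the true 50% (an F1 is
heterozygous at every diagnostic site, so presence coding saturates at
100%). Both are reported side by side in `aim_report()`.

**Reference bias.** Reads are mapped to an *armigera* reference genome,
and a joint caller emits the reference genotype wherever a sample has no
coverage. A zea or hybrid genome sequenced at low depth therefore
acquires spurious armigera alleles exactly at its uncovered AIMs, and
its zea score drops by the uncovered fraction. `depth_diagnostics()`
counts AIMs at DP = 0 and DP < 5 per sample, and masking (AIMs with
DP below 5 excluded from numerator and denominator) restores the
unbiased score; the DP < 5 masking threshold deliberately matches the
site filter's depth threshold — below it a genotype cannot be called
with confidence in the first place. The acceptance suite verifies the
arithmetic exactly: zeroing coverage at a fraction $m$ of fixed AIMs in
a pure zea genome yields a dosage-coded score of $100(1-m)$, and
masking returns it to 100.

## What the simulator emulates — and what it does not

`sim_config()` describes the generative model: per site, an ancestral
frequency $p_0 \sim U(0.05, 0.95)$ and species frequencies
$\mathrm{Beta}\big(p_0(1-F)/F,\ (1-p_0)(1-F)/F\big)$ — the
Balding–Nichols divergence model, with variance $F p_0 (1-p_0)$, so the
configured $F$ is recovered by a Hudson-type $F_{ST}$ estimator (a test
asserts this within $\pm 0.03$ at 5000 sites). A configurable fraction
of sites (default 5%) is forced to fixed differences so diagnostic
AIM-like sites exist at desk scale; because these inflate divergence
above the nominal $F$, the $F_{ST}$ recovery test runs with the
fraction at zero. Defaults mirror the reference panel the method is
designed around: 34 pure armigera, 7 pure zea, two F1 hybrids, mean
depth 30× (within the 25–44× range typical of the real panels), five
chromosomes with `chr1` as the excludable Z. $F = 0.3$ is used as a
plausible divergence for a strongly differentiated ~1.5 Myr-old species
pair; it is a simulation condition, not an estimate.

Genotypes: pure individuals draw dosage $\sim \mathrm{Bin}(2, f_S)$;
an F1 draws one allele per species (heterozygous at every fixed
difference, the defining F1 property); admixed individuals with
armigera fraction $q$ draw each allele from the armigera frequency with
probability $q$. Backcrosses are modeled as admixed with $q = 0.75$ or
$0.25$ — the *unlinked-loci* approximation, chosen deliberately because
the downstream model itself assumes independent loci; real BC1 genomes
have blocky local ancestry, which this package does not model (no
recombination maps, no chromosome painting).

The caller emulation: depth $\sim \mathrm{Poisson}(\bar d)$ per sample
and site; each read carries one of the two allele copies uniformly, so
a true heterozygote at depth $d$ is called het with probability
$1 - 2^{1-d}$ (verified against enumeration in tests); homozygotes are
called without error; and **DP = 0 yields a homozygous-reference call,
never a missing genotype** — the artifact under study. Site QUAL is a
depth-linked score, $\min(99, 3\bar{\mathrm{DP}})$, with 5% of sites
forced below 20 purely to exercise the quality filter. This read-draw
model is a stand-in: the real caller's error model (base quality,
mapping error, allele balance priors) is richer, so passing tests show
the *pipeline's* arithmetic and inference are correct under a clean
error model, not that any particular caller is well calibrated.

## Problem sizes and runtime

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in about a minute: panels of 20–50 genomes,
500–7500 SNPs, EM fits of a few hundred to ~2000 iterations. The
validation experiment projects 10 simulated F1s against 20 + 20 pure
panels over 5000 post-filter SNPs (LD-pruned to ≈ 4500) and recovers a
mean armigera fraction within two percentage points of the true 50%.
Full-scale datasets for this species pair run to ~10⁷ SNPs; nothing in
the implementation is specific to desk scale, but the shipped tests do
not exercise that regime.

## Known limitations

* Global ancestry only: no local (chromosome-painting) ancestry, no
  K > 2 model selection, no bootstrap standard errors.
* The AIM score's absolute value depends on the reference panel's size
  and diversity; with only 7 zea genomes, markers polymorphic in the
  species at large leak through, and hybrid scores sit below their
  dosage expectation. The score is best read comparatively, against
  pure controls scored on the same panel.
* Hybridization and cross-species sample contamination produce similar
  intermediate signals; distinguishing them needs read-level evidence
  outside this package's scope.
* The simulator's unlinked-loci and clean-caller assumptions mean
  simulation-based accuracy figures are upper bounds on real-data
  performance at equal depth and panel size.
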