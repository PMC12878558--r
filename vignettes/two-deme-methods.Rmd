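---
title: "Methods: models, estimators and design choices in twodeme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in twodeme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## The setting

The package targets resequencing studies of a species sampled across a
broad range and provisionally split into two populations — here called
demes — where differentiation may be near zero. Everything downstream is
built around two consequences of that setting: absolute diversity measures
need *all-sites* denominators (an invariant site is information, not
absence of data), and model comparison must work in a regime where the
competing demographic scenarios are nearly observationally equivalent.

## The simulator (the stated world of every test)

`simulate_coalescent_dataset()` draws independent genealogies per locus
under a two-deme structured coalescent: within a deme of diploid size
$N_e$, each lineage pair coalesces at rate $1/(2N_e)$ per generation;
a lineage in deme $i$ migrates (backward in time) to deme $j$ at rate
$m_{ij}$; at $T_{div}$ generations all lineages join a single ancestral
deme of size $N_{anc}$. Time is continuous (no generation stepping);
mutations are infinite-sites, Poisson with rate $\mu L$ per unit branch
length, at uniform distinct positions; diploids pair consecutive
haplotypes of a deme (haplotypes are exchangeable, so this realises
random pairing). The C++ core uses R's RNG, so a seed fixes the dataset
bit-for-bit. During this build the engine was cross-checked against an
independent coalescent simulator on an asymmetric
isolation-with-migration scenario (within-deme π and $D_{xy}$ agreed
within Monte-Carlo error); the shipped tests rely on closed-form neutral
expectations ($\bar\pi = 4N_e\mu$, the $1/i$ frequency spectrum, mean
Tajima's $D \approx 0$) instead.

Defaults mirror the scales of the study system this package grew out of:
$N_e$ of order $10^3$–$10^4$, divergence a few hundred generations ago,
backward migration $10^{-4}$–$10^{-1}$ per generation, basidiomycete-range
mutation rates $10^{-8}$–$10^{-7}$.

Two deliberate idealisations: no recombination within a locus (loci are
exchangeable mini-chromosomes; real contigs mix linkage scales), and no
selection except the optional environment clines. A green simulation test
therefore establishes correctness of the estimators under neutral
exchangeable-locus data, not robustness to recombination-rate variation or
background selection.

One statistical consequence matters for testing: sites within a locus
share one genealogy, so SNP counts are over-dispersed relative to
independent sites. The spectrum goodness-of-fit test uses many short loci
(per-locus $\theta \ll 1$) where the chi-square approximation is honest;
with long loci it would reject a correct simulator.

The artifact overlay adds negative-binomial depth per sample,
binomial(DP, 1/2) allele balance for heterozygotes (optionally forced
aberrant), Gaussian site QUAL with a low-quality fraction, and uniform
genotype missingness. Because a binomial draw lands outside [0.25, 0.75]
with positive probability even without any aberrant fraction, the
*idealised* artifact-free configuration — the one under which the filter
cascade must provably remove nothing — uses `depth_dispersion = Inf`
(constant depth) and `ab_noise = FALSE` (AD exactly DP/2). The default
keeps the realistic noise.

## The filter cascade

Order: QUAL (variant records only by default — invariant records rarely
carry a meaningful QUAL; a flag extends it) → allele balance →
all-heterozygous sites → depth → site missingness. Three choices were
open and are now fixed:

* **Allele balance masks the genotype**, not the site; the upstream
  convention for this filter acts per call. `ab_site_mode = TRUE`
  restores site-level removal for comparison. A heterozygous call without
  AD fails the test (conservative) and is logged.
* **The depth upper bound is per sample**: mean + 3 SD of that sample's
  depth over all sites, with the *population* SD (divisor $n$), so the
  documented oracle is a one-line moment computation. Depth values are
  genome-wide observations; masking a call does not delete its depth from
  the threshold computation.
* The cascade is idempotent and monotone in its thresholds; both are
  tested as properties, not examples.

## Windowed statistics

All window statistics are ratios of counted sums over fixed 1-based
windows $[(w-1)W+1,\, wW]$. At a site where the focal population has $k$
non-missing alleles with $a$ alternate copies: comparable pairs
$k(k-1)/2$, differing pairs $a(k-a)$. π is the ratio of the two sums;
an all-invariant window is exactly 0, a window without data is `NA` —
never silently 0. θ sums $1/a_{k-1}$ (harmonic number at each site's
own $k$) over segregating sites and divides by the count of sites with
data. Tajima's D applies the 1989 variance constants at the harmonic mean
of per-site allele counts — per-site exact treatment is noisier and is
not what the standard windowed tools do. $D$ is undefined at $S = 0$.

$F_{ST}$ is Hudson's estimator aggregated ratio-of-sums (Bhatia-style),
chosen for robustness to unequal sample sizes; the per-site within-deme
heterozygosity uses the unbiased $a(k-a)/\binom{k}{2}$ form, which leaves
a small negative $O(1/k)$ finite-sample offset when the two demes have
literally identical frequencies — visible in toy fixtures, negligible at
realistic $k$. Weir–Cockerham was considered and not used; the module
keeps the estimator behind one function so a flag could add it without
touching the window machinery.

The genome-wide summary of a windowed statistic is the ratio of summed
numerators and denominators (equal to a one-pass computation; tested to
1e-12), with SE = SD across windows / √(windows) — the across-window
convention, since the alternative (across samples) is not defined for
π-like quantities.

## ROH and inbreeding

A reported run is a *maximal qualifying window*: a stretch of homozygous
variant calls with at most `max_het_in_run` heterozygotes (default 0 —
strict; the upstream tool's allowance is configurable), skipping missing
calls, that satisfies ≥ 100 SNPs, span ≥ 100 kb and span/SNPs ≤ 50 kb and
is contained in no larger window that also satisfies them. The subtlety —
surfaced by the exhaustive-scan oracle — is that the density rule is not
monotone in window extent, so a qualifying ROH may be a trimmed subwindow
of a het-bounded run whose full extent is too sparse. Overlapping
qualifying windows merge. $F_{ROH}$ divides summed
span by genome size (default 33 Mb, the focal reference assembly).
$F_{IS}$ per sample is $1 - O_{het}/E_{het}$ with
$E_{het} = \sum 2p_i(1-p_i)\,k_i/(k_i-1)$ over the sample's genotyped
sites (cohort allele frequencies, small-sample corrected so the panmictic
expectation is 0).

## Structure

PCA drops sites above the missingness ceiling (1 % by default), mean
imputes the rest, centres, and eigendecomposes; axis signs are fixed by
making each axis's largest-magnitude loading positive. 1−IBS counts
0 / 0.5 / 1 per dosage difference. The NJ input distance is
allele sharing over *all* sites — for bi-allelic diploid data this equals
the IUPAC-ambiguity p-distance under the half-weight heterozygote
convention, which is why invariant sites belong in it (they compress
distances onto the genome-wide scale the tree is read on). NJ itself is
the canonical agglomeration with lowest-index tie-breaks and negative
branch lengths clamped to zero with the deficit moved to the sister
branch. MRM regresses lower triangles and permutes the *response* matrix
(the standard Mantel scheme; the alternative — permuting the predictor —
is equivalent under the null and was not needed).

Ancestry is estimated as masked-cross-validation NMF rather than a
re-derivation of the original sNMF algorithm (no public pseudocode to
match): dosages/2 are factorised as $QG$ with $Q$ rows on the K-simplex
and $G \in [0,1]$, by alternating least squares with projection; missing
and held-out entries are EM-imputed with the current fit, which solves the
masked problem exactly at convergence. The masked binary cross-entropy
scores each of `n_runs` restarts (default 10; no extra regularisation),
and `select_k()` takes the K with the lowest mean. The acceptance surface
is K-selection behaviour and label recovery — not numeric identity with
any particular ancestry program.

## Demographic inference

The folded joint SFS uses hypergeometric projection to $(n_1, n_2)$
haploid alleles, excludes (and counts) sites with insufficient genotyped
alleles, accumulates invariant sites in the monomorphic cell, and folds by
global minor allele with the canonical cell on the fold diagonal taken as
the one with the smaller row index. The monomorphic cell stays in the
composite likelihood because invariant sites were retained on purpose; an
option drops it for the fixed-cells-excluded convention.

The expected spectrum under a scenario is Monte-Carlo: branch lengths
accumulated by descendant configuration over `n_sims` genealogies, scaled
by $\mu$; the monomorphic probability is the complement. Desk-scale
defaults are `n_sims = 2e4` and 15 conditional-maximisation cycles
(full-scale: 10⁶ and 60, via arguments). Each cycle line searches one
parameter in log space under common random numbers; the reported
likelihood is re-evaluated at `final_sims` (5 × `n_sims`) on a seed shared
across scenarios, so AIC differences are not dominated by simulation
noise. Because the three scenarios are nested (single ⊂ isolation ⊂
migration), `compare_scenarios()` warm starts each richer model from the
simpler fit and additionally scores the embedded nested optimum — the
richer model can then never lose by more than evaluation noise plus its
parameter penalty, which is the analytically correct behaviour.

Two numerical guards: initialisation ranges follow the stated priors
(Ne 100–10,000; $T_{div}$ 50–300; m 10⁻⁴–10⁻¹) but the search is
soft-bounded far beyond them (estimates may exceed the priors, as real
fits do); and the region with more than ~60 expected backward migrations
per lineage ($[(m_{12}+m_{21})\,T_{div}] > 60$) is excluded from the
*search* — there the two-deme spectrum is panmictic to within Monte-Carlo
error while simulation cost grows linearly in $m \cdot T_{div}$, and any
mixing level the data can express is reachable well inside the bound.
`expected_sfs()` itself carries no such bound.

Parameter counts: single = 1 (only $N_{anc}$; the pseudo-demes are tied),
isolation = 4, migration = 6. AIC uses the printed-formula convention
$2k - 2\,\mathrm{MaxEstLhood}/\log_{10}(e)$ with the likelihood in
log₁₀ units.

Honest limits, measured during development and reproduced by the
acceptance suite at its stated scale: scenario *selection* is reliable
when the truth is panmictic, and distinguishing migration from isolation
requires the full-resolution joint spectrum — with a coarse projection
(e.g. 8+8 alleles) the two scenarios are near-equivalent at desk-scale
data sizes and AIC ordering approaches a coin flip. The acceptance test
therefore projects to the full 16+16 spectrum. Divergence-time estimates
under strong gene flow ($N_e m \gg 1$) are weakly identified; the test
suite does not assert point recovery of $T_{div}$ in that regime.

## Genotype–environment association

The collinearity filter is the greedy worst-pair rule (drop the member
with the larger mean absolute Spearman correlation; ties by column order)
— a deterministic reimplementation of the caret-style recipe. RDA
regresses centred (mean-imputed, as in the PCA — the upstream treatment
is unstated, so the two stages share one convention) dosages on
standardised variables and eigendecomposes the fitted values; explained
variance is reported both as a share of total genotype variance and
within the constrained space. Outliers are |z| > 3 on an axis's loadings,
union over axes 1–2; a degenerate axis yields none. The marginal test
permutes the focal variable's values and recomputes its partial
constrained sum of squares (the simplest marginal scheme; residual
permutation under the reduced model is a known alternative and was left
out to keep the null exact under exchangeability).

Under the null the outlier rate per axis is ≈ 2Φ(−3) ≈ 0.27 %; with
planted clines spanning an allele-frequency range ≥ 0.5 the recall target
is ≥ 0.8. Both are checked by simulation at fixed seeds.

## Configs, formats, seeds

Pipeline configurations are JSON (this environment ships no R YAML
parser; the structure is flat enough that the difference is syntax).
All randomness flows from explicit integer seeds; stage seeds derive
deterministically from the master seed. VCF output is v4.2 with
`GT:DP:AD`, "." ALT for invariant records and "./." for missing calls;
round-tripping is identity on GT/DP/AD/QUAL and is tested.

## Known limitations

* No within-locus recombination; LD decay in simulations reflects locus
  boundaries, not recombination maps.
* Composite likelihood treats sites as independent; with linked sites the
  AIC penalty under-corrects for overfitting, which is why the
  single-population recovery test uses a modest data volume.
* The NMF ancestry model has no spatial prior and no explicit
  regularisation path.
* Sample-level QC (the minimum-coverage sample removals done upstream of
  the published filter cascade) is out of scope; only the site/genotype
  cascade is implemented.
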