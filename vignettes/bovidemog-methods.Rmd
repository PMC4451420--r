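---
title: "Methods: diversity, demography and replicated selection scans from SNP-array genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, demography and replicated selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bovidemog` implements a complete analysis pipeline for multi-breed
SNP-array genotype panels of the kind produced for world cattle
diversity studies: quality control, per-breed diversity and inbreeding,
coancestry trees, linkage-disequilibrium (LD) based demographic
reconstruction, and a replicated cross-population extended haplotype
homozygosity (XP-EHH) scan for selection signatures. Because such
genotype panels are usually not redistributable, the package ships a
forward Wright–Fisher simulator that generates phased multi-population
datasets with the structural features the analyses assume, so every
stage is testable end to end without any external data.

## Data model and quality control

Genotypes are held as counts of the alternate allele (0/1/2, `NA`
missing) over a variant map sorted by chromosome and position; the
alternate allele is the second allele observed in the PLINK-text input,
following the PLINK convention. Phased data are 0/1 haplotype matrices
with two rows per individual and no missing entries.

QC applies two call-rate filters **in a fixed order**: individuals with
call rate below 95% are removed first, then SNPs with call rate below
95% computed on the remaining individuals. The order matters — an
individual responsible for most of a SNP's missingness can rescue that
SNP by leaving first — and is asserted by a test. The published filter
thresholds are phrased without strictness, so the package keeps a
sample or SNP whose call rate equals the threshold (`>=`); this is a
documented choice, not an inference about the original intent.

LD pruning (used before model-based structure analyses) removes SNPs
with minor allele frequency (MAF) below 0.01, then slides a 50-SNP
window in steps of 10 SNPs; within a window, any pair with genotype
correlation r² above 0.1 loses its later-positioned member. Pruning
runs on unphased genotype correlations because it precedes phasing in
the intended workflow.

## Diversity and inbreeding

Observed heterozygosity Ho is the mean per-SNP heterozygote fraction
over called genotypes. Expected heterozygosity uses Nei's small-sample
correction, with `k` called allele copies and alternate frequency `p`:

$$\widehat{He}_v = \frac{k}{k-1}\left(1 - p^2 - (1-p)^2\right)$$

SNPs monomorphic within a breed contribute 0 and stay in the mean —
the array panel is fixed across breeds, so dropping them would inflate
diversity differentially. The inbreeding coefficient is the multilocus
ratio $F_{IS} = 1 - \bar{Ho}/\bar{He}$ (ratio of means, not mean of
ratios), which is robust to low-He loci and consistent with published
per-breed arithmetic (a breed with Ho = 0.026 against a panel-wide He
of 0.34 gives F = 0.924). Group contrasts (e.g. taurine vs indicine
F values) use Welch's unequal-variance t-test. A transcription of the
published per-breed summary table ships in `inst/extdata/` and is
exposed by `cattle_diversity_table()`.

## Coancestry trees

Between-population distances use the Reynolds–Weir–Cockerham
least-squares coancestry distance for biallelic loci,

$$\theta = \frac{\sum_v \sum_a (p_{va} - q_{va})^2}
                {2 \sum_v \left(1 - \sum_a p_{va} q_{va}\right)},$$

appropriate for short, drift-dominated divergence. The dendrogram is
Saitou–Nei neighbor joining (delegated to `ape::nj`); bootstrap support
resamples SNPs with replacement, rebuilds the tree, and scores each
internal edge by the fraction of replicates containing the same
bipartition, ignoring branch lengths and rooting. Negative NJ branch
lengths — an artifact of noisy distances — are clamped to zero for
display, with raw values available behind a flag.

## LD-based effective population size

For each population, all within-chromosome SNP pairs separated by 5 kb
to 1 Mb with MAF ≥ 5% contribute a Hill–Robertson r² computed from
phased haplotype frequencies, $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$.
Pairs are pooled across chromosomes and sliced into 30 equal-count
distance bins (a stable sort-and-slice, equivalent to empirical
distance quantiles; bin sizes differ by at most one). Physical distance
maps to recombination fraction linearly at 1 cM/Mb. Each bin's mean r²
is inverted through Sved's relation

$$N_t = \frac{1}{4f(c)}\left(\frac{1}{\bar{r}^2} - 1\right),
  \qquad t = \frac{1}{2c},$$

so the 1 Mb pair limit makes the most recent estimate ~50 generations
ago. The published form of $f(c)$ is typographically degenerate (its
denominator reads $(1-2)^2$); the package defaults to the linear map
$f(c) = c$ and offers `sved_paper`, $f(c) = c(1-c/2)/(1-2c)^2$, as an
option — the two agree to well under 0.5% at the small `c` values the
distance limits allow, so the choice is immaterial in practice but is
made visible rather than silently guessed. No sample-size correction
of r² is applied by default; an optional `r2_adjust` subtracts
1/(haplotype count). Generations convert to years at 4 years per
generation only in reporting.

Trajectory summaries use the harmonic mean of per-bin estimates, the
conventional summary for effective sizes across epochs.

## EHH, XP-EHH and the replicated consensus

EHH is computed on the whole phased sample of a population (the
unpartitioned form XP-EHH requires): haplotypes are grouped by their
allele string from the core SNP to the extension, and EHH is the
probability that two random haplotypes fall in the same group,
$\sum_g \binom{n_g}{2} / \binom{N}{2}$. The curve starts at 1 at the
core, is non-increasing outward (asserted on every construction), and
truncates when EHH drops below 0.05 (that point is kept — its trapezoid
counts), when the next SNP is more than 400 kb away (the gap limit
chosen for 50K-density arrays; the record is kept with shortened
support rather than discarded), or at the chromosome end. iHH is the
trapezoidal integral of EHH over physical distance, left plus right;
under the linear 1 cM/Mb map, integrating over bp is proportional to
integrating over the genetic map. A brute-force pairwise-identity
oracle checks the group-counting implementation exhaustively on small
random instances.

XP-EHH per SNP is $\ln(iHH_A/iHH_B)$, computed only where the SNP has
MAF ≥ 5% in both populations and both integrals are positive; scores
are standardized per chromosome (mean 0, sample SD 1 over tested
records) and flagged as outliers beyond the genome-wide 5% and 95%
quantiles of the standardized distribution (linear-interpolation
quantiles, inclusive comparison; per-chromosome quantiles are available
behind a flag since the published phrasing is ambiguous). Positive
scores mean longer haplotype homozygosity — a sweep signal — in
population A.

The replicated design bundles oriented pairwise comparisons
(`build_figure1_design()`): a between-lineage family pairing each
taurine with an indicine population (a SNP is called when extreme with
the same sign in at least K−1 of the K pairings, so failing the MAF
threshold in one breed does not discard it), and within-lineage
families across continents requiring unanimity. The published rule does
not address opposite-sign extremes among the remaining comparisons; the
default here is conservative — any opposite-sign extreme vetoes the
call — with `allow_conflict = TRUE` restoring the permissive reading.
`null_consensus_rate()` gives the per-SNP false-call probability under
independent flags (for K = 3, m = 3, q = 0.05: $2q^3 = 2.5\times
10^{-4}$), the calibration expectation for sweep-free data.

Called SNPs link to every gene whose interval intersects a ±50 kb
window (distance 0 inside the gene, else the gap to the nearer edge),
and biotype tallies count distinct genes, not links.

## The synthetic-data generator

The simulator is a forward diploid Wright–Fisher model over standing
variation: no new mutation during the simulated epoch, mirroring a
pre-ascertained array panel, with initial allele frequencies uniform on
[0.05, 0.95] — the lower bound mimics array ascertainment toward
common variants (configurable). Each generation every offspring draws
two parents (fitness-weighted 1, 1+s, 1+2s at a sweep's focal SNP —
additive selection, the simplest scheme that produces the EHH
signature the scan targets) and each gamete recombines with a Poisson
number of crossovers placed uniformly on a genetic map strictly
proportional to physical position. Population splits found a child by
reproduction from the parent pool; two-parent (admixed) populations
draw each founding gamete from parent A with probability α. Identical
seeds reproduce identical datasets bit for bit.

Two sweep modes exist. Selection on a *standing* variant starts from
whatever haplotype mosaic the allele has accumulated — an old allele
has recombined onto many backgrounds (its associated haplotype spans
roughly 1/(r × age)), so such sweeps are soft and leave weak EHH
signals. Specifying `initial_freq` instead *injects* the allele at
sweep start as a young, single-origin mutation — a hard sweep, the
phenomenon XP-EHH is designed to detect. With
`resample_until_established`, any reproduction step that loses an
allele its parents carried (in a target population or its ancestors)
is redrawn, conditioning trajectories on establishment; losses are
recorded in the truth record either way.

The default `default_cattle_config()` emulates the structure of world
cattle diversity — an ancestral pool splitting into taurine-like and
indicine-like lineages, African/non-African sub-splits, a two-parent
hybrid, declining terminal sizes, and a taurine-confined sweep — at a
rescaled depth (about one simulated generation per four real ones, the
standard forward-simulation rescaling) so a run takes seconds rather
than hours.

What the simulator does **not** emulate: genotyping error, pedigree
structure within breeds, non-random mating, variable recombination
maps, mutation, and realistic site-frequency spectra (the uniform
standing spectrum is a caricature of ascertainment). Passing tests
therefore demonstrate correctness of the estimators under their own
model assumptions, not robustness to array artifacts.

## Validation scales and numerical choices

The test suite validates each stage at deliberately compact problem
sizes chosen so the whole suite runs in minutes on one core:

* drift and heterozygosity-decay oracles at Ne = 50–200 over ≤ 100
  generations, against the closed form $h_0(1 - 1/2N_e)^t$;
* constant-Ne recovery at Ne = 200 with 2000 SNPs on a 50 Mb
  chromosome after 600 generations of burn-in — enough for the
  drift–recombination equilibrium at the distances that dominate the
  30 bins (median bin dates ~100 generations back, well inside the
  burn-in), while the oldest bins, dating beyond the simulated epoch,
  legitimately drift toward the linkage-equilibrium start;
* a declining history (1000 → 100 diploids over 500 generations) tested
  as a rank property — recent bins below ancient bins — rather than
  absolute recovery;
* topology recovery for a balanced four-population history (splits 100
  and 200 generations deep at Ne = 100) with bootstrap support;
* hard-sweep localization in a λ-rescaled scenario (Ne = 200, s = 0.4,
  giving 2Ns = 160; map rescaled 100-fold to 1 Morgan/Mb so the
  expected footprint s/(r·ln 2Ns) ≈ 80 kb sits inside the 100 kb
  detection window; 2000 SNPs at 2.5 kb spacing; allele injected 35
  generations before sampling), 50 replicates per run.

Numerical conventions worth knowing: missing genotypes are `NA`, never
a sentinel used in arithmetic; coordinates are 1-based inclusive
internally with BED converted on read; quantiles are type-7
(linear interpolation); equal-count binning resolves ties by stable
sorting, and an all-tied distance vector produces a single bin flagged
`degenerate`; LD pruning and consensus calling are deterministic in
input order; all stochastic stages take explicit seeds.

## Limitations

Absolute Ne levels from array LD are biased by ascertainment and by
the sample-size term in r² (left uncorrected by default, as the
estimator is conventionally reported); trends and ranks are the robust
output. XP-EHH has megabase-scale localization for strong old sweeps
and no power for soft or ancient ones. The consensus rule treats
comparisons as independent replicates, which admixture between the
compared breeds would violate. NeighbourNet-style split networks,
model-based ancestry estimation, PCA and GO enrichment are outside the
package's scope.
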