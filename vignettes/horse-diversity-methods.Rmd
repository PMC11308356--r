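---
title: "Methods: genomic and pedigree diversity analysis in equidiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic and pedigree diversity analysis in equidiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`equidiv` implements the standard analysis battery for SNP-array diversity
studies of managed animal populations — developed with native horse breeds
in mind — together with a forward simulator that makes every stage testable
against exact ground truth. This vignette documents the models, the
parameters that matter, and the numerical and design choices behind the
implementation.

## Genotype representation and quality control

Genotypes live in a `genotype_matrix`: samples by markers, each call coded
as the count of one of the two array alleles (0/1/2, `NA` missing).
Because every statistic used downstream (heterozygosity, allele frequency,
homozygosity runs, composite LD) depends only on heterozygote/homozygote
status and allele counts, no attempt is made to resolve strand or allele
orientation; relabeling alleles (0 and 2 swapped) changes nothing. Markers
are restricted to a declared autosome list (31 autosomes for the horse) and
sorted by chromosome and physical position; duplicate (chromosome,
position) pairs keep the first record with a warning — a deterministic,
logged policy for a situation array manifests occasionally produce.

PLINK text (`.ped`/`.map`) and binary (`.bed`/`.bim`/`.fam`, SNP-major)
filesets are read and written directly, bit-exact against the PLINK 1
layout. The binary dialect is lossless; in the text dialect the two alleles
of each marker are inferred from the data (lexicographic order), which is
the one place where a monomorphic marker's coding is not recoverable —
a caveat documented in `?read_plink`.

Quality control runs in a fixed order: autosome restriction, SNP call rate
(default maximum missing fraction 0.10), sample call rate (0.10), then an
optional minor-allele-frequency floor. Two profiles mirror standard
practice: the **ROH profile** applies no MAF filter (pruning rare alleles
removes exactly the homozygous stretches the scan is looking for), while
the **diversity profile** adds MAF ≥ 0.05 for heterozygosity and Ne
estimation. The order itself is a declared choice — published threshold
sets rarely state one — and the per-stage removal counts in the `QCReport`
make any order effect visible. MAF is computed on the matrix remaining
after the call-rate filters. Hardy–Weinberg and LD pruning are deliberately
not implemented: the analyses here do not use them. PCA (for outlier and
mix-up screening) standardizes each SNP as $(x - 2p)/\sqrt{2p(1-p)}$ with
mean imputation of missing calls and monomorphic SNPs excluded; it is
deterministic up to the sign of each axis.

## Runs of homozygosity

The scan is the classic sliding-window procedure. With window size $w$
(default 10 SNPs) every contiguous block of $w$ SNPs is a window, and a
window is *homozygous* when it contains at most `window_max_het`
heterozygous (default 0) and `window_max_miss` missing (default 0) calls.
Each SNP is then flagged when the proportion of homozygous windows among
the windows covering it exceeds `snp_inrun_threshold` (default 0.05, the
conventional default for this family of tools; near chromosome ends the
denominator is the actual covering-window count, with no padding).
Candidate runs are maximal stretches of flagged SNPs, split wherever
consecutive SNPs are more than `max_gap_bp` apart (default 100 kb), and a
candidate survives if it has at least `min_snp` SNPs (10), spans at least
`min_length_bp` (100 kb; 500 kb as the usual sensitivity variant), reaches
`min_density_snp_per_kb` (0.05 SNP/kb), and contains at most one
heterozygous and one missing call (`run_max_het`, `run_max_miss`).

Two conventions are worth stating. Run length is `end_bp - start_bp`
(first to last SNP, not +1), matching the kb arithmetic of the tools this
reproduces; and run boundaries are SNP positions, not window boundaries.
The run-level het/miss allowance is applied as a post-filter on candidate
runs: with the default window tolerance of zero a candidate can only
contain a heterozygote if the per-SNP proportion rule bridges one, so the
post-filter is normally non-binding — it is enforced anyway so that
permissive window settings still honour the run-level contract. Candidates
are maximal by construction and never merged across gaps.

The test suite checks the scan against an exhaustive oracle that
enumerates every SNP interval and keeps the maximal ones satisfying the
flag, gap and filter definitions directly — the two implementations agree
exactly on thousands of randomized small instances.

`coverage_validation()` answers "could these settings detect a run here at
all?" without looking at genotypes: marker stretches are split at gaps
over `max_gap_bp`, and stretches meeting the SNP-count, length and density
floors contribute their span. The returned fraction of the autosomal
length is the standard validity check for a parameter set (values near 1
mean the map supports detection almost everywhere). On a 670K-like equine
map this construction yields values around 99%.

## Genomic inbreeding and ROH islands

$F_{ROH}$ is an individual's summed ROH length divided by the autosomal
genome length $L_{auto}$. By default $L_{auto}$ is derived from the map
(sum over autosomes of last-SNP minus first-SNP position); it can be
pinned to a constant — e.g. 2281 Mb for a 670K equine array map — to
replicate published values. Per-chromosome $F_{ROH}$ uses the
corresponding chromosome's covered length. Runs are classified into five
length classes, left-open/right-closed (0.1–1, 1–2, 2–4, 4–8, > 8 Mb), so
a run of exactly 1 Mb falls in the shortest class; per-class $F_{ROH}$
values sum exactly to the total because every run has exactly one class.
Samples without runs are kept with $F_{ROH} = 0$.

Island detection works on the per-SNP *incidence*: the fraction of the
population's individuals (all post-QC samples, not only those with runs)
having at least one run covering the SNP position. Islands are maximal
stretches of consecutive SNPs with incidence strictly above the threshold
(default 0.70 — "shared by over 70%"), with coordinates at the first and
last SNP of the stretch. Raising the threshold can only shrink islands,
never create new territory, and the tests assert this nesting property.
Cross-population comparison is by interval overlap of separately-called
islands, not joint incidence. Coordinates are 1-based inclusive
internally; BED export converts to 0-based half-open.

## Effective population size from LD decay

For unphased array data the package uses composite LD: $r^2$ is the
squared Pearson correlation of genotype codes across individuals with both
calls present, for every intra-chromosomal SNP pair between
`min_pair_dist_bp` (0.05 Mb) and `max_pair_dist_bp` (40 Mb). Pairs are
binned by distance (30 equal-width bins by default; the bin scheme is a
declared choice, as the cited tools do not publish theirs), each pair's
$r^2$ is adjusted by $-1/(\beta n)$ for sample size, and the bin mean
feeds the estimator

$$N_e(t) = \frac{1}{4c}\left(\frac{1}{\overline{r^2_{adj}}} - \alpha\right),
  \qquad t = \frac{1}{2c},$$

with $\alpha$ (default 2.2) absorbing mutation, and $c$ the recombination
fraction mapped from the bin's mean physical distance. Three mappings are
available: `linear` ($c = d$ Morgans at the genome-wide rate, default
$1.24 \times 10^{-8}$ per bp), `haldane` ($c = (1 - e^{-2d})/2$), and
`sved_feldman`. The exact closed form the classic software uses for the
third is not stated in the papers that cite it, so the package implements
the quadratic approximation $c = d(1 - d/2)$ — first-order identical to
the other two at small $d$ and bounded by 0.5 over the usable range — and
keeps the modifier pluggable so replications can test all three. Bins
with non-positive adjusted $r^2$ or negative $N_e$ (possible when
$1/\overline{r^2_{adj}} < \alpha$) are excluded with a warning rather than
clamped. The estimator involves no sampling: trajectories are
deterministic given data and configuration.

On the sample-size adjustment: $\beta = 1$ (subtract $1/n$) is the default
and the right choice when the genotyped sample is small relative to the
population, which is the usual survey situation. When a simulation — or a
completely genotyped herd — is analysed with *sample = census*, half of
the $1/n$ null inflation is not sampling noise at all but the genuine
drift LD of the finite gamete pool ($1/(2N)$ of the $2N$ gametes), and
subtracting all of it deletes real signal and inflates $N_e$. The
package's own recovery tests therefore run with $\beta = 2$ and the
Haldane mapping (the simulator's crossover model is exactly Haldane), and
recover a constant true $N_e = 100$ within ±35% at the most recent
trajectory point across seeds. Users genotyping a large fraction of their
population should consider `sample_size_beta = 2`.

## Pedigree analysis

Pedigrees are validated (acyclicity via topological sort) and unknown
parents are treated as founders; unknown-parent groups are not modelled.
Three quantities are computed:

* **Generation equivalents** $ge_i = \sum_a (1/2)^{\mathrm{depth}(a)}$
  over all known ancestor positions — the standard completeness measure; a
  fully known $g$-generation pedigree scores $g$.
* **$F_{PED}$** by the tabular relationship recursion:
  $F_i = \phi(\mathrm{sire}_i, \mathrm{dam}_i)$ with kinship
  $\phi(i,i) = (1+F_i)/2$ and
  $\phi(i,j) = (\phi(s_i,j) + \phi(d_i,j))/2$. The tests verify it to
  $10^{-12}$ against an independent path-counting oracle
  ($F = \sum (1/2)^{n_1+n_2+1}(1+F_A)$ over common ancestors and
  non-overlapping path pairs).
* **Coancestry-rate $N_e$**: for each cohort pair the individual rate
  $\Delta c_{jk} = 1 - (1 - c_{jk})^{1/((ge_j + ge_k)/2)}$, and
  $N_e = 1/(2\,\overline{\Delta c})$. The reference cohort is
  configurable (default: all pairs in the chosen birth cohort); the
  pair-set definition is a declared choice since the literature names the
  method but not the cohort rule. A mutually unrelated cohort has zero
  mean rate and infinite $N_e$, reported as such. On simulated closed
  populations of constant census $N$ under random mating the estimate
  recovers $N$ within ±30%.

Kinship is computed over the full pedigree with a dense matrix, which is
appropriate at the package's intended scale (up to a few thousand
records).

## The simulator and what passing tests mean

The generator emulates a 670K-style array experiment at desk scale while
preserving marker density: by default 10 chromosomes of 17 Mb with 5,000
jittered SNPs each (≈0.29 SNP/kb, the density of 670K markers on a
2281 Mb genome). Founder allele frequencies follow a configurable law
(uniform MAF on [0.05, 0.5] by default; Beta or fixed alternatives);
founder haplotypes are drawn site-wise independently — founders are in
linkage equilibrium. Meiosis uses a Poisson crossover count
(chromosome length × $1.24 \times 10^{-8}$ per bp) with uniform breakpoint
placement: the Haldane model, no interference, consistent with the
distance-to-recombination assumption of the Ne module. Gene dropping
tracks founder-haplotype identity, so true autozygous segments (both
copies from the same founder chromosome) are known exactly; truth is
recorded *before* missingness and genotyping errors are injected (an
error flips a call to a uniformly chosen different code). The
Wright–Fisher mode runs discrete generations of random mating with
replacement (monoecious, selfing allowed) without mutation — standing
variation only, adequate on the tens-of-generations timescales analysed.
All generators are deterministic under the mandatory seed; the heavy
meiosis loop is implemented in C++ on the R RNG.

Features of real array data the simulator does **not** emulate:
ascertainment bias of array SNP selection, founder LD and population
structure, genotyping batch effects, variable recombination along the
chromosome, and real chromosome length heterogeneity. Passing recovery
tests therefore demonstrate the *correctness of the algorithms under
their stated models* — e.g. that the ROH scan recovers essentially all
IBD segments ≥ 1 Mb at array density with zero error, and that
$F_{ROH}$ correlates almost perfectly with true autozygosity — not that
those accuracy levels transfer to any particular real dataset.

Truth segments are delimited by SNP positions (first/last SNP of the
identical-founder stretch), matching how detected runs are reported, so
recall/precision comparisons are on a common footing.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 1,000 randomized ≤50-SNP
instances for the oracle equivalence; a 100-sample gene-dropped cohort on
10 × 5,000 SNPs for $F_{ROH}$ ground truth; ten Wright–Fisher replicates
(N = 100, 200 generations, 20 × 1,000 SNPs) for Ne recovery; 200
replicates of a full-sib pedigree for the F = 0.25 expectation; and a
500-founder Hardy–Weinberg cohort for the heterozygosity consistency
check. These sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping a full run in the low minutes on one core. Pair
enumeration in the Ne module is exhaustive below $10^5$ SNPs, with an
optional seeded per-bin cap for larger maps.

## Known limitations

* Text-dialect PLINK files cannot encode which allele of a monomorphic
  marker is which; round trips are exact for calls only when both alleles
  are observed (the binary dialect is always lossless).
* The composite-$r^2$ estimator reads whole-genome LD; it does not model
  admixture or overlapping generations, and the most recent trajectory
  points inherit the known approximation error of the $1/(\alpha + 4Nc)$
  relation at large $c$.
* Pedigree $N_e$ depends on pedigree completeness through $ge$; shallow
  pedigrees bias rates downward.
* No support for sex chromosomes, genotype likelihoods, HMM-based ROH
  calling, or coalescent simulation — all outside the package's scope.
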