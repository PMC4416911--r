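---
title: "Methods: variant calling, population genetics and demographic inference in altipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant calling, population genetics and demographic inference in altipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

altipop implements the computational chain of a two-species alpine amplicon
resequencing survey: diploid individuals sampled in populations at the upper
(H) and lower (L) altitudinal margins of a species' range are sequenced at a
panel of orthologous gene regions, polymorphisms are called from the read
pileups, per-gene diversity and selection statistics are computed, the
populations' differentiation and structure are tested, a single-population
demographic history is inferred by Approximate Bayesian Computation (ABC),
and individual SNP genotypes are tested for association with seasonal
climate variables while controlling for ancestry.  This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the procedure left room.

## Variant calling under a binomial error model

Each individual-by-gene assembly is a pileup of aligned reads.  At a site
covered by $n$ reads of which $k$ carry a putative minor allele, the
probability that the minor allele is produced entirely by sequencing error
at per-base rate $f_M$ is the binomial point mass

$$P_{\mathrm{false}} = \binom{n}{k} f_M^{\,k} (1-f_M)^{\,n-k}.$$

`p_false_profile()` tabulates this quantity for increasing depth with $k$
set to the smallest integer strictly greater than $0.3\,n$ (so depth 5
requires a minor count of 2, depth 10 a count of 4).  The default error
rate is $f_M = 0.024$, the rate estimated from haploid plastid amplicons
sequenced in the same kind of run, where any mismatch must be an error.  A
site is called when its depth is at least 5 and the minor allele is present
in *more than* 30% of reads; at the default rate this bounds the false-call
probability at depth 5 by about 0.0054.  The depth threshold is a
configuration constant rather than a quantity re-derived from the formula:
the point mass is not monotone in $n$ (it is smaller at $n=4,k=2$ than at
$n=5,k=2$), so no arg-min rule reproduces the published choice.

Indel alleles (gap versus base) are eligible for calling.  Sites where a
*third* allele passes the frequency filter are rejected with an error
rather than silently reduced to two alleles, since only biallelic handling
is defined.

**Phasing.**  Each read is reduced to its *minimal haplotype* — the ordered
alleles it carries at called sites.  Full haplotypes are assembled by
greedy left-to-right chaining: for each pair of consecutive called sites,
the reads covering both vote for the parallel or the crossed pairing of
alleles and the majority wins; a tie with support on both sides is an
ambiguity error.  When no read covers two consecutive sites (a *phase
gap*), the two flanking blocks are joined by a seeded uniform random pick
and the pair is flagged `phase_gap_resolved`.  The random join changes
neither diversity nor divergence statistics, which depend only on the
multiset of alleles, but it can mis-pair haplotypes relative to the truth;
the flag makes such pairs identifiable.  The consensus backbone is the
per-position majority base, with ties broken in the fixed order
A < C < G < T < gap for determinism.

## Per-gene statistics

All diversity statistics are computed on *effective sites*: alignment
columns of the requested class (intron, exon, or all) where no haplotype
carries `N` or a gap.  A site is segregating when at least two states are
present among haplotypes; singletons count.

* $\pi$ — mean pairwise difference per effective site.
* $\theta_W = S / (a_1 L_{\mathrm{eff}})$ with
  $a_1 = \sum_{i=1}^{n-1} 1/i$.
* Tajima's $D$ with the exact constants computed from $n$ (never
  approximations); undefined and reported `NA` when $S = 0$.
* Haplotype diversity $H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$.
* $ZZ = Z_a - Z_{nS}$, the mean $r^2$ of adjacent segregating-site pairs
  minus the mean over all pairs, a signal of intragenic LD decay; per-pair
  $r^2$ significance comes from seeded allele shuffles (default 10,000).
* Divergence is the mean per-effective-site difference between each
  haplotype and the aligned outgroup.
* The McDonald–Kreitman table counts synonymous/non-synonymous
  polymorphisms and fixed outgroup differences over effective coding
  sites and is tested with a two-sided Fisher exact test;
  $\mathrm{DoS} = D_n/(D_n+D_s) - P_n/(P_n+P_s)$.  Codon classification
  substitutes each allele into the majority-consensus codon with the
  reading frame anchored on the annotated exons; a variant is synonymous
  iff every observed allele preserves the amino acid.  This per-SNP
  convention is deterministic; codons carrying several segregating sites
  are classified against the consensus background rather than by
  enumerating mutational paths.

**Differentiation.**  $F_{ST}$ uses the Hudson–Slatkin–Maddison form
$1 - H_w/H_b$ from mean within- and between-population pairwise
differences, pairwise and overall; negative estimates are reported as
computed.  Jost's $D_{est}$ is computed per gene from haplotype
frequencies with Nei–Chesser sample-size corrections (harmonic-mean
$\tilde n$, $\tilde n/(\tilde n - 1)$ within, $+H_S/(k\tilde n)$ total)
and clamped to $[0,1]$; genes are combined by the arithmetic mean of
per-gene values.  The exact internal convention of the original
web-calculator ("across-alleles harmonic means") is not recoverable; the
per-locus estimator with arithmetic combination is the documented
interpretation.  H-vs-L contrasts of within-class pairwise values use the
two-sided Wilcoxon rank-sum test.

## Structure tests

* The ancestry-asymmetry test compares mean first-cluster ancestry between
  H and L individuals; the null redistributes the observed ancestry values
  across classes preserving class sizes, and the P value uses the add-one
  estimator $(\#\{\text{null} \ge \text{obs}\} + 1)/(B + 1)$, which is
  never zero and matches the resolution of an empirical count.
* The Evanno $\Delta K$ statistic is the mean absolute second difference
  of the log-likelihood across $K$, divided by the replicate standard
  deviation at $K$; it needs at least two replicates and three consecutive
  $K$ values, and is invariant to likelihood shifts.
* Mantel isolation-by-distance correlates the lower triangles of a genetic
  and a great-circle geographic distance matrix (sphere of radius 6371 km),
  with seeded label permutations.  For the ln-transformed variant,
  non-positive genetic entries are offset by half the smallest positive
  observed value before the log — a documented rule where the original
  web application's behavior is unrecoverable.
* Spearman correlations use exact small-sample P values; the partial rank
  correlation removes the control variable linearly from both rank vectors
  and tests the residual correlation on $n-3$ degrees of freedom.

## Coalescent simulation and ABC

Four single-population histories are modelled (times in generations before
present, sizes in diploid individuals): constant size CON($N_C$); stepwise
reduction RED($N_C < N_A$ at $T_R$); exponential expansion EXP with
$N_C = N_A e^{rT_E}$; and a bottleneck BOT($N_B$ between $T_{B,end}$ and
$T_{B,start}$).  The simulator draws a neutral coalescent genealogy under
the piecewise size trajectory (exponential phases are discretized into 64
steps, a resolution at which the discretization error is far below Monte
Carlo noise), places infinite-sites mutations as a Poisson process with
rate $\mu$ per site per generation along branches, and, when the
recombination rate $\rho$ is positive, threads recombination through the
ancestral recombination graph: lineages carry their ancestral segments,
recombination splits them at a uniform breakpoint within the ancestral
span, and coalescence merges segment lists with carrier counts.  When the
expected number of recombination events on the genealogy is below 0.01 the
ARG is bypassed, since its marginal effect is then orders of magnitude
below the simulation noise; when it exceeds 10, the locus is split into
blocks carrying about five expected events each and the blocks are
simulated as independent ARGs — in that regime distant sites are already
nearly independent, so the approximation error is far below the
between-replicate spread.  The event loop is implemented in compiled code
(driven by R's RNG, so a seed fixes the run exactly), with a pure-R
reference implementation kept alongside and cross-checked in the tests.

The summary vector is the mean and standard deviation across loci of $S$
and $\pi$ (intronic regions only, since coding regions may be under
selection); a single-locus configuration defines both SDs as 0.  Rejection
retains the closest fraction of simulations (production setting 0.5%, i.e.
5,000 of 1,000,000) in Euclidean distance on SD-standardized summaries —
the standard metric where the original toolbox's exact choice is not
stated.  Posteriors are sharpened by a weighted local-linear regression
adjustment (Epanechnikov weights in the rejection distance, log scale for
strictly positive parameters, values clipped to the retained support);
this is the package's stand-in for the reference GLM adjustment, with the
same contract (an adjusted posterior sample).  Model choice normalizes
multivariate Gaussian-kernel marginal densities of the observed summaries
across models; the model-fit P is the fraction of retained simulations
with estimated density at most that of the observation.  Power is the
fraction of pseudo-observed datasets (PODs) whose generating model attains
the maximum posterior probability, and the kernel-corrected probabilities
condition the observed probability vector on each model's POD cloud with a
product-Gaussian kernel (common bandwidth, default 0.1, admissible range
0.01–0.2).  Posterior modes come from a 1-D Gaussian kernel density
(Silverman bandwidth, log scale for sizes and times) and the 95% HPD is
the shortest interval containing 95% of the sample.

**Priors.**  Only the mutation-rate range ($10^{-9}$–$5\times10^{-7}$ per
site per generation, log-uniform) and recombination-rate range
(0–$10^{-8}$, uniform) are inherited from the study design.  Sizes and
times have no published priors; the package defaults to log-uniform
$N \in [10^2, 10^6]$ and $T \in [10^2, 10^5]$ generations, supports wide
enough to contain the posterior intervals typically reported for alpine
herbs (hundreds to ~$8\times10^5$ individuals).  For EXP, $r$ is uniform
on $[0, \log(N_{\max}/N_A)/T_E]$ so the growth constraint is always
satisfiable within the size prior.  Because these supports are a package
choice, published model-choice numbers (marginal densities, posterior
probabilities, power) are procedure anchors, not reproduction targets; the
test suite instead verifies the machinery's properties: simulator
calibration against the neutral expectations $E[\pi] = 4N\mu$ and
$E[S] = 4N\mu a_1 L$, directional Tajima's $D$ under growth and reduction,
model-choice power above 0.9 when the four models occupy non-overlapping
size scales, and coverage of true reduction-model parameters by the 95%
HPDs.

## Association

Each SNP's minor-allele dosage (0/1/2 per individual, complete-case) is
regressed on one climate variable plus the ancestry proportions of a
Q-matrix (one column dropped for identifiability); the observed statistic
is $|t|$ for the climate coefficient.  Climate is a population-level
predictor, so the permutation null permutes climate values *across
populations as blocks* — individual-level shuffles would be
anti-conservative.  P values use the add-one estimator and are corrected
by the number of climate variables (four: spring/summer temperature and
precipitation, $p_c = \min(1, 4p)$).  This fixed-effects model with
block-permutation inference replaces the original mixed-linear-model
machinery, whose kinship component is outside this package's scope; it
consumes the same inputs and emits the same per-SNP decisions.  The
default permutation count is 10,000 (the 100,000 production setting is a
configuration choice).

## What the synthetic data emulate — and what they do not

`simulate_study()` mirrors the sampling design: 10 populations (5 H + 5 L,
interleaved along a west–east transect) of 6 diploids, 19 gene regions of
which 15 contain an intron, an outgroup at ~0.27 substitutions per site,
temperature decreasing with elevation, and precipitation independent of
the transect.  Genealogies come from a finite-island structured coalescent
in which each deme receives an equal share of the model's total size and
H-demes can receive less gene flow (defaults $4N_m = 2$ versus 8), so the
qualitative H/L differentiation asymmetry is a scenario preset rather than
a hard-coded outcome.  `simulate_reads()` draws reads with uniform starts
(overhanging ends are clipped, so expected depth is uniform), equal
haplotype sampling in expectation, and independent substitution errors at
$f_M$; the `balanced` option alternates haplotypes along the start order
for noiseless round-trip checks.  `plant_association()` rewrites one
segregating column so dosage tracks a latent climate score at a chosen
variance fraction while preserving the allele counts exactly.

Not emulated: homopolymer-specific 454 error profiles, PCR chimeras and
alignment error, within-population coordinate scatter, linkage between
genes, and any selection other than the planted association.  Passing
tests therefore demonstrate the correctness and calibration of the
machinery on data satisfying the model assumptions, not robustness to
those artifacts.

## Problem sizes and numerical choices in the test suite

The suite runs the full chain at reduced sizes chosen to keep the
statistical checks sharp while remaining quick on one core: simulator
calibration uses 5,000 replicates at $n=100$, $L=500$; model-choice power
uses 10,000-row tables, 5 loci of 16 haplotypes and 2 kb, and 100 PODs per
model; parameter recovery uses one 50,000-row reduction-model table, 3
loci of 12 haplotypes, and 40 pseudo-experiments; permutation calibrations
use 500 null replicates at 199 permutations; the end-to-end pipeline runs
twice at 4 populations × 3 individuals × 4 genes and must be byte-identical.
In the separation experiment the bottleneck is placed behind the
coalescent timescale so each model keeps a distinct diversity scale; in
the recovery experiment the recombination prior is capped at $10^{-9}$ —
recombination is a nuisance parameter there and rare events dominate the
runtime, not the posterior.  The association power experiment plants its
effect at a site of intermediate frequency (minor-allele frequency
0.25–0.75, closest to 0.5): at extreme frequencies the discrete dosage
cannot carry half the latent variance, so the criterion's premise — an
effect explaining at least 50% of dosage variance — would not hold.

## Known limitations

* The ancestry matrices consumed by the structure and association stages
  come from external clustering software in a real analysis; the package
  generates structured stand-ins for testing but does not re-implement
  admixture inference.
* The MFDM neutrality test and the mixed-model kinship correction are out
  of scope.
* The regression adjustment is a local-linear stand-in for the reference
  GLM machinery; with weakly informative summaries it falls back towards
  the unadjusted rejection sample.
* Multi-population demographic models (the structured generator exists for
  data synthesis) are not part of the ABC model set, which matches the
  four single-population scenarios.
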