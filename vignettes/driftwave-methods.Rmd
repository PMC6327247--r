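---
title: "Models and methods in driftwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in driftwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

driftwave estimates allele-frequency correlation statistics (f2, f3, f4,
D) from ancient and present-day genotype data, tests how many independent
streams of ancestry relate a set of test populations to a set of
outgroups, and fits admixture graphs to the observed statistics.  This
vignette explains the models behind each stage, the tunable parameters
and their defaults, the numerical choices, and what the simulation-based
tests do and do not establish about real data.

## The statistics

For populations with allele-1 frequencies $p_A, p_B, \dots$ at a SNP, the
per-SNP summands are

* $f_4(A,B;X,Y)$: $(p_A-p_B)(p_X-p_Y)$ — a treeness test; its
  expectation is zero whenever $(A,B)$ and $(X,Y)$ lie on opposite sides
  of an edge of the population tree.
* $f_2(A,B)$: $(p_A-p_B)^2 - h_A/n_A - h_B/n_B$ — squared drift
  distance, with finite-sample bias terms described below.
* $f_3(C;A,B)$: $(p_C-p_A)(p_C-p_B) - h_C/n_C$ — negative values
  indicate that $C$ is admixed between $A$- and $B$-related sources;
  with an outgroup in the $C$ slot the statistic measures the drift
  shared by $A$ and $B$ ("outgroup f3").
* $D(A,B;X,Y)$: the ratio of summed $f_4$ numerators to summed
  heterozygosity products
  $(p_A+p_B-2p_Ap_B)(p_X+p_Y-2p_Xp_Y)$, the frequency-level analogue of
  the ABBA–BABA counting form.

The genome-wide estimate of each statistic is the per-SNP mean over the
sites where every involved population has at least one observed allele
call.  This *per-statistic* intersection is the default (the behaviour
most analyses of sparse ancient data use); a global-intersection mode is
available through `snp_set = "global"` for sensitivity checks.

### Pseudo-haploid data and the heterozygosity correction

Low-coverage ancient samples are represented by a single randomly drawn
allele per site (genotype codes 0/2).  `allele_frequencies()` therefore
counts **one** allele call per pseudo-haploid genotype and two per
diploid genotype.  Squared-difference statistics computed from such
frequencies are inflated by sampling noise; the correction terms
$h/n = \hat p(1-\hat p)/(n-1)$ subtract an unbiased estimate of that
noise, built from *between-individual* allele mismatches — the only kind
observable after random-allele calling, since within-individual
heterozygosity is destroyed by the representation.  `inbreed = TRUE`
(the default) applies the correction to f2 and f3; disabling it
reproduces the naive upward-biased estimator, and the package's tests
confirm the contrast: on simulated pseudo-haploid data the corrected f2
is centred on the generating drift while the uncorrected one exceeds it
in every replicate.

Two conventions worth stating explicitly: `f2(A, A)` with the same label
twice is exactly zero by definition (the bias terms assume disjoint
sample sets), and sites fixed identically in all populations of a
statistic contribute a zero summand but stay in the SNP count, keeping
reported counts reproducible.

### Block jackknife

Standard errors come from a weighted delete-one-block jackknife over
blocks of SNPs: contiguous 5-Mb physical windows by default (linkage
rarely extends further), or exactly $N$ contiguous equal-count blocks
(`make_blocks(..., "count")`), the variant used for per-edge graph
uncertainties.  Block weights are the usable-SNP counts *for the
specific statistic*, so heterogeneous missingness is handled per
statistic.  The variance formula is Busing's weighted jackknife; with
equal weights it reduces to the textbook pseudovalue form, and the unit
tests pin it to an explicit leave-one-out loop at $10^{-12}$.

## The rank ("streams of ancestry") test

For left populations $L$ (test set) and right populations $R$
(outgroups), the $(|L|-1)\times(|R|-1)$ matrix
$E_{ij} = f_4(l_0, l_i;\, r_0, r_j)$ has rank at most $k$ when the left
populations descend from $k+1$ ancestry streams relative to the rights.
`test_rank()` fits the best rank-$k$ approximation $E \approx AB^\top$
by alternating generalized least squares under the joint jackknife
covariance of the entries (tolerance $10^{-8}$, at most $10^4$
iterations, SVD initialization) and refers the residual quadratic form
to $\chi^2$ with $(|L|-1-k)(|R|-1-k)$ degrees of freedom.  The
$\chi^2$ reference is the standard practice for this test; a
Hotelling-style $F$ correction for the finite number of jackknife blocks
is available via `method = "hotelling"` and is slightly conservative.
Results are invariant to which population is listed first on either side
(a test asserts this), and a singular covariance is ridged by
$10^{-6}\times$ its mean diagonal with a flag in the output.  The full
entry covariance is the default weighting; `weighting = "diagonal"`
keeps only per-entry variances as a robustness check, since
$(|L|-1)(|R|-1)$ can approach the number of blocks.

`wave_scan()` applies the test to many candidate sets at ranks
$0..|L|-2$ and reports the smallest non-rejected rank plus one as the
number of streams, rejecting at $p < 0.01$ by default — the scan-level
convention for claiming an additional stream, stricter than a plain
0.05 because a scan reads many p-values.  Removing an outgroup that uniquely "tags" one stream
removes the evidence for it — the package's three-source fixture
reproduces this in kind: the triplet needs three streams with the full
outgroup set and only two once the discriminating outgroup is dropped.

## Admixture graphs

A graph is a rooted DAG whose drift edges carry lengths $c_e$ in
$F_{ST}\times 1000$ units and whose admixture nodes mix two parents with
proportions $(\alpha, 1-\alpha)$.  With $w_X(e)$ the probability that a
lineage from leaf $X$ traverses edge $e$ (products of admixture
proportions summed over root paths), the model predicts
$f_2(A,B) = \sum_e (w_A(e)-w_B(e))^2 c_e$, and f3/f4 follow from the f2
identities, so the model side satisfies them exactly.  This is the
standard small-drift linearization; it ignores the $O(F^2)$ attenuation
of heterozygosity along deep branches, which is also why fitted edge
lengths on very drifted lineages should be read qualitatively.

### Fitting

`fit_graph()` matches observed leaf-pair f2 statistics (with their full
jackknife covariance, ridge-regularized as above) to the model
prediction.  Observed statistics are converted to drift units by
dividing by $\hat\lambda$, the mean unbiased $p(1-p)$ across leaf
populations — a heterozygosity normalizer that makes fitted lengths
comparable to $F_{ST}\times 1000$; residual Z-scores do not depend on
it.  For fixed admixture proportions the prediction is linear in the
drift lengths, which are solved by whitened nonnegative least squares;
proportions are then optimized by bounded quasi-Newton search with
seeded random restarts (10 by default) to guard the nonconvex
$\alpha$ landscape.  Because some edge combinations are only jointly
identifiable from f2 (the two branches meeting at the root are the
canonical case), the constrained solve adds an infinitesimal Tikhonov
term that makes the solution unique without affecting identifiable
edges; unidentifiable splits should be interpreted as sums.

Fit quality is summarized by the residual table over **all** f2, f3 and
f4 combinations of the leaves, each compared with its model expectation
and scaled by its own jackknife SE; `worst_z` is the largest |Z|.  The
package follows the conventional retention rule — a topology "fits"
when no residual exceeds $|Z| = 3.5$ — and the extra-edge rule: an added
admixture event is kept only when it lowers the maximum |Z| by more
than 0.3 (`compare_with_edge()`, applied per comparison; sequences of
edge decisions are composed by the caller).  Terminal edges of
single-sample pseudo-haploid populations absorb residual sampling noise
and are flagged conceptually untrustworthy; do not interpret them.

`edge_jackknife()` re-fits the graph with each of 100 equal-count blocks
deleted (warm-starting from the full solution and reusing its weighting)
and reports per-edge SEs and Z-scores from zero.  A fitted edge whose
Z-score from zero is small indicates the data do not require drift
there — the diagnostic used to ask whether an admixture source shares
real drift with its sister population.  Note an identifiability caveat
established while designing the fixtures: a *terminal* zero-length edge
private to an admixture source is exactly collinear with the mixture
leaf's own terminal edge under any f2-based basis; the testable quantity
is the *shared* edge above the source/sister split, which is identified
through the f2 between the sister and the admixed leaf.

`graft_search()` implements the greedy extension strategy: candidates
are grafted one at a time, first as unadmixed clades on every drift edge
(minimizing complexity), falling back to all 2-way admixed placements
only when no clade placement keeps `worst_z` at or below the threshold.
The search is deterministic given the candidate order, a canonical
attachment ordering, and the fit seed; surviving graphs are ordered by
admixture count, then worst |Z|, then attachment label.

## Low-dimensional views

`pca_fit()` computes principal components from reference (present-day,
diploid) samples only, with genotypes centred per SNP and scaled by
$\sqrt{p(1-p)}$ using the shrunk frequency $p = (1+\sum g)/(2+2n)$; SNPs
with zero variance or >50% reference missingness are dropped and
remaining missing reference entries are mean-imputed.  Ancient samples
are placed by `lsq_project()`: a least-squares solve restricted to the
sample's observed SNPs, which is exact for complete-data samples and
makes no imputation for missing ones.  Projections with fewer than
10,000 overlapping SNPs are flagged unreportable — with less overlap the
solve is dominated by noise.

`mds_from_f3()` applies classical (Torgerson) scaling to
$1 - f_3(O; i, j)$ dissimilarities — classical rather than
stress-minimizing because it is deterministic and exact on
Euclidean-realizable inputs.  `nj_from_f3()` runs neighbor joining on
$1/f_3$ distances and roots the tree on a designated outgroup; negative
branch lengths, which can arise when the distances are not additive, are
clamped to zero with the deficit moved onto the adjacent branches (the
standard display convention).

## The simulator

`simulate_frequencies()` draws an ancestral frequency per SNP uniformly
on $[0.05, 0.95]$ — a deliberate caricature of capture-panel
ascertainment that keeps sites polymorphic without modelling any real
ascertainment scheme — and propagates it down the graph: a drift edge of
length $c$ applies a Balding–Nichols beta draw with mean $p$ and
variance $(c/1000)\,p(1-p)$ (frequencies fixed at 0 or 1 stay fixed);
an admixture node takes the exact linear mixture of its parents.  Under
this law, f2 between two leaves equals the path sum of $c_e/1000$ times
the root heterozygosity to first order in drift, which is what ties the
simulator's units to the fitter's.  Two consequences the tests rely on:
the pairwise Hudson-type $F_{ST}$ ratio estimator returns the *mean* of
the two branch F's (not their sum), and deep statistics are attenuated
by roughly $\prod(1-F)$ along the path, so oracle comparisons at depth
use the attenuated expectation.

`sample_genotypes()` draws two binomial alleles per diploid genotype or
one per pseudo-haploid genotype and masks each entry independently at
the population's missing rate.  SNP positions are uniform over 22
synthetic 125-Mb autosomes (so a 5-Mb partition yields ~550 blocks at
any SNP count); a configurable fraction of SNPs (default 2/3, roughly
the genome-wide transition share) is flagged as transitions for the
transversions-only filter.  Every draw derives from one master seed with
named per-operation streams, so a truth record plus seed reproduces a
dataset bit for bit.

### Fixture scenarios and what they establish

The canned fixtures (`make_fixture()`) encode the structures the stack
must distinguish: `single_wave` (one stream; rank-0 calibration),
`two_wave` (two sources with a 40% admixture contrast and 40-unit source
drifts; rank-0 power), `three_source` (three sources, the third tagged
by a single discriminating outgroup; outgroup-sensitivity behaviour),
`star_radiation` (f4 null), and `anzick_affinity_toy` (a star plus an
extra lineage contributing 30% to two leaves; f4-scan ranking).  The
default sampling conditions are a desk-scale ancient-DNA panel: 5
pseudo-haploid individuals per group at 20% missingness, with a 10-
sample diploid outgroup panel at 2%.  Two further graphs support
parameter-recovery exercises: `alpha_recovery` (six leaves, one 30%
admixture event, drift lengths 5–50 units) and `zero_edge` (a
drift-free shared edge above an admixture source).  In
`alpha_recovery` the two sources attach next to leaf-anchored nodes on
opposite ends of the graph (~140 units of separation); with weakly
separated sources the proportion is structurally confounded with the
attachment-edge lengths, a property of the design rather than of the
estimator, and real analyses face the same limit.

Test problem sizes are chosen to hold Monte-Carlo error well below the
asserted margins while staying desk-scale: 50k SNPs × 100 replicates
for f4 calibration, 20k × 200 for rank-test calibration, 100k SNPs ×
100 blocks × 20 replicates for graph parameter recovery.

What passing these tests does **not** show: the simulator draws
independent SNPs (no linkage, so 5-Mb blocks are conservative on
synthetic data and their real-data value is untested here), models no
sequencing error, contamination or reference bias, and makes no attempt
at the real 1240k ascertainment, which shifts absolute f-statistic
magnitudes.  All assertions on synthetic data are therefore relative or
contrast-based; absolute magnitudes from real panels will differ.

## Known limitations

* The f2-basis GLS with a jackknife covariance estimated from the same
  data can be mildly anti-conservative when the number of basis
  statistics approaches the number of blocks; the diagonal-weighting
  flag and the Hotelling option exist for exactly that check.
* Graph fitting assumes the given topology; `worst_z` measures misfit
  but a fitting topology is not unique, and the graft search explores
  only greedy single-candidate extensions.
* Edge lengths on deeply drifted or single-sample pseudo-haploid
  terminal branches are inflated by unmodelled noise and should not be
  read quantitatively.
* EIGENSTRAT `.ind` files do not record ploidy; reading uses an
  explicit `ploidy` argument or infers pseudo-haploidy from the absence
  of heterozygous codes, which misclassifies a diploid sample that
  happens to carry none (pass `ploidy` explicitly for small datasets).
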