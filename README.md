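# driftwave

Allele-frequency based demographic inference for ancient-DNA genotype
panels, in R.

Population history leaves a signature in the covariance of allele
frequencies across populations.  driftwave implements the standard
statistics built on that signature and the inference layers on top of
them, for the setting where many samples are low-coverage ancient
individuals represented by a single randomly drawn allele per site
(pseudo-haploid 1240k-capture-style data):

* **f-statistics** — f2, f3 (including outgroup-f3 shared-drift
  matrices), f4 and D, with the "inbreed" heterozygosity correction
  required by pseudo-haploid data and weighted block-jackknife standard
  errors over 5-Mb genomic blocks.  The f4 summand is
  `(p_A - p_B)(p_X - p_Y)`; f2 subtracts the finite-sample bias terms
  `h/n` estimated from between-individual mismatches.
* **Ancestry-stream rank tests** — the matrix of
  `f4(l0, li; r0, rj)` statistics has rank `k` when the test
  populations derive from `k + 1` streams of ancestry relative to the
  outgroups; driftwave fits rank-constrained approximations under the
  joint jackknife covariance and tests them against a chi-square (or
  Hotelling-corrected F) reference, with scan drivers over many
  candidate sets and outgroup-sensitivity reruns.
* **Admixture graphs** — expected f-statistics from a parameterized
  rooted DAG (drift edges in F_ST x 1000 units, 2-parent nodes with
  mixture proportions), constrained GLS fitting with residual-Z reports
  against all f2/f3/f4 combinations, the |Z| <= 3.5 retention rule, the
  "keep an extra admixture edge only if it lowers max |Z| by > 0.3"
  decision rule, 100-block per-edge jackknife uncertainties, and a
  greedy graft search for extending a fitting skeleton.
* **Views** — PCA fitted on reference panels with least-squares
  projection of low-coverage samples (>= 10,000-SNP reporting rule),
  classical MDS of `1 - f3` dissimilarities, and neighbor-joining trees
  of `1 / f3` distances.
* **Simulator** — allele frequencies drifted down a known admixture
  graph (Balding–Nichols law, so edge units match the fitter's),
  sampled into pseudo-haploid/diploid genotype matrices with
  missingness, a chromosome layout supporting 5-Mb blocks, and
  transversion flags; plus EIGENSTRAT (.geno/.snp/.ind) reading and
  writing, transversion filtering, random haploidization and analysis
  grouping.

Everything downstream of a genotype matrix is exercisable at desk scale
with no external data: canned fixtures (`make_fixture()`) generate
datasets with one, two or three ancestry streams, star radiations, and
admixture-affinity structures with known truth.

## Worked example

Two ancient groups that look similar are tested for descending from one
versus two streams of ancestry relative to a panel of outgroups:

```r
library(driftwave)

fx <- make_fixture("two_wave", seed = 1, n_snps = 20000)
fx$dataset
#> genotype_dataset: 40 samples x 20000 SNPs (7 groups, 6543 transversion SNPs)

ft     <- allele_frequencies(fx$dataset)
blocks <- make_blocks(ft$snp)            # 5-Mb jackknife blocks

f_statistic(ft, "f4", c("O", "R3", "L1", "L2"), blocks)
#> f4(O, R3, L1, L2) = -0.00234516  SE 0.000715  Z -3.28  (19981 SNPs, 549 blocks)

fm <- build_f4_matrix(ft, c("L1", "L2"),
                      c("O", "R1", "R2", "R3", "R4"), blocks)
test_rank(fm, 0)
#> rank 0: statistic 52.357, dof 4, p = 1.161e-10

wave_scan(ft, list(c("L1", "L2")), c("O", "R1", "R2", "R3", "R4"), blocks)
#>     set size      p_rank0 n_streams error
#> 1 L1+L2    2 1.161425e-10         2  <NA>
```

The f4 statistic says L2 shares significantly more drift with the
outgroup R3's lineage than L1 does (Z = -3.28), and the rank test
rejects a single stream outright (p = 1.2e-10): the pair requires two
ancestry streams — which is how the fixture was simulated (L2 carries
40% ancestry from a second source).  `fit_graph()` would then estimate
that proportion from an explicit graph topology.

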