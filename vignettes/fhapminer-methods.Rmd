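---
title: "Family-based haplotype association mining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based haplotype association mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhapminer)
```

## The problem

Candidate-gene association studies with unrelated cases and controls are
vulnerable to population stratification, and haplotype phase estimated from
unrelated genotypes is uncertain. Pedigree data largely remove both
problems: transmission within a family is immune to stratification, and
family genotypes pin down phase far more reliably. Over a dense candidate
region spanning at most a few megabases, recombination within any one
family is rare enough to neglect, which makes exact phasing tractable.

`fhapminer` implements a three-stage pipeline for binary or quantitative
traits observed on loop-free pedigrees genotyped at L biallelic SNPs:

1. **Zero-recombination phasing.** All haplotype configurations consistent
   with the genotypes are derived exactly; one is drawn uniformly at random
   as the working solution.
2. **Founder haplotype scoring.** Each of the 2 x (number of founders)
   founder haplotypes in each family receives a phenotype score built from
   the trait values of its carriers.
3. **Similarity clustering and testing.** Founder haplotypes pooled across
   families (treated as unrelated population haplotypes) are clustered
   around each marker with a position-weighted similarity measure; each
   cluster's score mean is contrasted with the rest of the sample by a
   t-type Q statistic, and the best cluster per marker is tested with
   multiplicity control over markers.

A classical single-locus transmission disequilibrium test (`tdt()`) is
included as the comparison baseline, together with a pedigree simulator and
a study runner that reproduce the type-I error, power and mapping-precision
experiment designs the method is normally evaluated with.

## Zero-recombination phasing

Under zero recombination a child receives one entire haplotype from each
parent, so one binary inheritance variable per parent–child edge describes
transmission at every SNP simultaneously. We add one binary phase variable
per heterozygous (member, locus) cell, stating which allele lies on the
member's designated-first haplotype. Requiring each child's genotype to be
reproducible from its parents' haplotypes turns every (child, locus) cell
into an XOR constraint among at most three of these variables. The full
solution space is therefore the affine solution set of a linear system over
GF(2), which `phase_solve()` obtains by Gaussian elimination
(reduced row echelon form). Any algorithm producing the same solution set is
equivalent; we verify ours against a brute-force enumeration over all
founder phase assignments and transmission vectors on a thousand random
small pedigrees in the test suite.

Three conventions make the solution count well defined:

* **Canonicalization.** Each founder's first heterozygous locus is fixed
  with the smaller allele on the designated-first haplotype. This removes
  the two-fold per-founder phase-swap symmetry, so "number of solutions"
  means string-distinct configurations modulo that symmetry.
* **Degrees of freedom.** Free variables that only permute two identical
  haplotype copies (for example the transmission choice from an entirely
  homozygous parent) do not change any haplotype string. The reported
  degrees of freedom is the GF(2) rank of the map from free variables to
  phase variables, so `2^dof` equals the number of string-distinct
  configurations, and a fully homozygous pedigree has exactly one solution.
* **Uniform selection.** When `dof > 0`, `pick_config()` draws all free
  variables uniformly, which induces the uniform distribution over
  configurations. The choice of configuration matters only when `dof > 0`;
  scores may vary across draws, which is inherent to the method rather than
  a defect, and a fixed seed makes any analysis reproducible.

Missing genotypes and pedigrees with marriage or inbreeding loops are
rejected: the exact linear-system formulation relies on complete data and a
tree-shaped marriage graph. Families whose genotypes admit no
zero-recombination solution (typically genotyping error) fail loudly;
`fhapminer()` excludes such families with a warning and analyses the rest.

## Founder haplotype scores

Let \(Y_{ij}\) be the phenotype of member \(j\) in family \(i\) (1/0 for
affected/normal, or a quantitative value), \(\bar Y_i\) the family mean, and
\(c_{ij}(h_{ik}) \in \{0,1,2\}\) the number of copies of founder haplotype
\(h_{ik}\) that member \(j\) carries by descent. The default score is

\[ s_{ik} = \sum_j c_{ij}(h_{ik}) \, (Y_{ij} - \bar Y_i). \]

Using the copy count rather than a carrier indicator is deliberate: every
member distributes its deviation over exactly two founder haplotype copies,
so \(\sum_k s_{ik} = 0\) holds exactly in every family, including families
with homozygous-by-descent carriers. Members with missing phenotype are
excluded from both the mean and the sum. Identical haplotype strings from
different families remain distinct records with their own scores; the
pooled list is the input of the scan stage.

An alternative relative-risk style score is available
(`measure = "relative-risk"`): a carrier-weighted ratio of carriage among
high-trait versus low-trait members with a 1/2 pseudocount,
\((\sum_j c_{ij} I(Y_{ij} \ge t) + \tfrac12) / (\sum_j c_{ij} I(Y_{ij} < t)
+ \tfrac12)\). The published description of this measure gives only its
intent (a within-family relative risk with an indicator threshold \(t\)),
not an explicit formula, so this form is this package's declared
reconstruction; it is selectable but not the default, and results based on
it should be labelled as such.

## Similarity, clustering and the Q score

Around focal marker \(m\), two haplotypes are compared inside a window of
`W` markers centred on \(m\) (clipped at the panel ends, no padding):

\[ S = w_L \cdot L + w_N \cdot N, \]

where \(N\) counts positions with identical alleles in the window and
\(L\) is the length of the longest run of consecutive matches containing
the focal position (0 if the focal alleles differ). Both weights default
to 1. \(L\) is measured in marker counts, not map distance: genetic
distance plays no role in the similarity and is reserved for
mapping-precision reporting.

Clustering is density-based (DBSCAN) on the distance \(d = S_{max} - S\):
a haplotype is a core point when at least `minpts` haplotypes (itself
included) lie within distance eps of it, clusters are connected components
of core points plus their reachable border points, and the remainder is
noise. No package in our dependency stack provides DBSCAN, and the
neighbour-graph traversal is a dozen lines, so it is implemented directly.
Defaults are `minpts = max(2, ceiling(0.05 n))` and eps expressed as a
minimum similarity fraction `eps_frac = 0.8` of \(S_{max}\); neither value
is canonical, both are exposed as arguments, and every study-runner result
is a pure function of them plus the seed. The distance is not a metric and
DBSCAN does not require it to be.

Each cluster that leaves at least two scores on each side is evaluated by a
Q score. The published description — the deviation of the cluster's
phenotypic mean from the mean of all samples, as a t statistic — does not
fix the variance convention, so two flavours are provided:

* `qtype = "welch"` (default): Welch two-sample t between in-cluster and
  out-of-cluster scores, two-sided p from the Welch–Satterthwaite t
  distribution. Contrasting with the complement avoids counting the cluster
  members on both sides of the comparison.
* `qtype = "one-sample"`: cluster mean versus the overall mean, scaled by
  the cluster's own standard error. This variant is somewhat more
  conservative because the overall mean contains the cluster itself.

The marker's statistic is the cluster with the largest |Q| (ties broken by
smaller raw p, then larger cluster, then lexicographically smallest member
set, so scans are deterministic). Multiplicity over the L markers is
controlled by Bonferroni (default, and used throughout the simulation
studies for speed) or by a permutation null that shuffles scores against
haplotypes and recomputes the genome-wide maximum |Q| B times. Bonferroni
corrects over markers only — one max-Q test per marker; correcting over
markers x clusters would be more conservative and was the other defensible
reading.

## The TDT baseline

`tdt()` re-implements the classical single-locus transmission
disequilibrium test rather than wrapping an external program: for each SNP,
every heterozygous parent of every affected child contributes one
transmission tally, the transmitted allele being deduced from the child and
the other parent; triples in which parents and child are all heterozygous
for the same alleles are genuinely ambiguous and contribute 1/2 to each of
b and c. The statistic is \((b-c)^2/(b+c)\) on 1 df, Bonferroni-corrected
over SNPs. Affected children at all generations are counted, one tally per
parent-child pair; no within-family correlation correction is applied,
matching how the baseline is normally run in this design.

## The simulator and its scope

The simulator emulates the standard three-step design for this family of
methods:

1. **Structures.** With probability 52/65 a family has three generations
   (four grandparents, a parental couple in which the father descends from
   one grandparental couple and the mother from the other, and a sibship),
   otherwise two (a couple and a sibship). Sibship sizes follow a negative
   binomial (dispersion 8, mean 8.47) truncated so total sizes span 4–20;
   these two constants make the long-run mean family size 13, matching the
   published summary of the CEPH reference families (2 or 3 generations,
   4–20 members, average 13). Real structure files can be used instead by
   building `fhm_pedigree` skeletons directly.
2. **Gene dropping.** Founders draw two haplotypes i.i.d. from a population
   frequency table; children receive one whole haplotype from each parent
   by a fair coin. There is no recombination, no mutation, and the truth
   (haplotypes and descent) is retained as ground truth.
3. **Phenotypes and ascertainment.** Each member is independently affected
   with probability \(f_g\), where \(g\) is its risk-allele or
   risk-haplotype copy count and \((f_0, f_1, f_2)\) is the penetrance
   triple; families without any affected member are discarded until the
   target count is reached. In single-locus studies the risk SNP is removed
   before analysis, so detection must come from linkage disequilibrium with
   the remaining markers. Under the null model phenotypes are Bernoulli
   draws independent of genotype; the rate is the scenario prevalence
   (about 0.1 for the standard penetrance set C at risk frequency 0.1)
   rather than an arbitrary constant, so ascertainment behaves as in the
   alternative scenarios.

The analytic helpers `prevalence()`, `genotype_given_affected()` and
`relative_risks()` give the closed-form population quantities of a
penetrance triple under Hardy–Weinberg equilibrium; the three standard sets
A (0.05, 0.15, 0.25), B (0.01, 0.1, 0.15) and C (0.05, 0.3, 0.5) are
provided by `penetrance_sets()`.

Because the original population frequency tables behind the published
experiments live in supplementary material that is not redistributable
here, the package ships `synthetic_cf_panel()`: a deterministic synthetic
panel with the same summary structure (29 haplotypes over 19 SNPs, 22 rare
haplotypes sharing frequency 0.01786, block-wise LD, MAFs from about 0.02
to 0.47). It is a stand-in, not the real data: tests and studies run on it
exercise the machinery under realistic LD, but their numerical results are
not comparable cell-by-cell with tables computed on the real frequency
tables, which can be supplied as TSV files via `read_frequency_table()`.

What the simulator does *not* emulate: recombination and mutation within
families, genotyping error and missingness, covariates, age/sex effects,
and quantitative traits beyond the 1/0 coding (the scoring and scanning
stages accept continuous phenotypes, but the shipped experiment designs are
binary). Passing tests therefore demonstrate correctness of the machinery
under the stated model, not robustness to those real-data features.

## Study designs and problem sizes

`run_type1()` estimates the family-wise type-I error as the fraction of
null replicates with any Bonferroni-significant marker.
`run_power_single_locus()` takes each SNP in turn as the risk locus,
deletes it, and reports per-SNP power with Low/Medium/High MAF groups (cut
points 0.13 and 0.30, configurable). `run_power_rare_hap()` draws 10 random
risk sets of k rare haplotypes (frequency < 0.02) per k and averages power
over selections, with window 10 as the haplotype-study default.
`mapping_precision()` reports the cM distance between the smallest-p marker
and the true risk locus, ties broken by the lowest marker index. A
detection in a power replicate is *any* significant marker after
correction; location accuracy is reported separately by the precision
metric so the two are not conflated (`run_power_single_locus()` exposes
both).

Every stochastic step derives its stream from one root seed through
`derive_seed()` (structure, gene drop, phenotype, configuration pick,
permutation, replicate), so any table cell reproduces exactly from the root
seed and results do not depend on evaluation order.

The shipped test suite and acceptance script run these designs at
deliberately moderate sizes — e.g. 100 replicates of 50 pedigrees for level
control, 100 replicates per power cell on single SNPs, 40 replicates for
the rare-haplotype comparisons — which estimate rates to a few percentage
points (binomial SE); the full published-style grids over all SNPs,
penetrance sets and sample sizes are available through the same functions
at proportionally larger run times.

## Numerical and degenerate-input choices

* Zero-variance Q contrasts: equal means give Q = 0, p = 1; separated means
  with zero variance give infinite Q and p = 0.
* Clusters smaller than 2 or leaving fewer than 2 scores in the complement
  are not tested; a marker at which no cluster qualifies reports NA and
  never counts as significant.
* A window longer than the panel is clipped with a warning.
* Frequency tables must sum to 1 within 1e-6 unless renormalization is
  requested explicitly; duplicate haplotype strings are rejected.
* TDT with b + c = 0 reports chi-square 0, p = 1, flagged uninformative.
* Monomorphic SNPs are skipped (with a warning) in power scans.
* The enumeration of phase configurations refuses to materialize more than
  `2^20` solutions; the solution-space object itself is never large.

## Known limitations

Phase uncertainty is resolved by a uniform draw, not by population-informed
likelihood ranking; with many heterozygous founders the drawn configuration
can differ from the truth and dilute scores. The founder-haplotype pooling
treats the two haplotypes of one founder, and haplotypes of founders of the
same family, as independent, which is an approximation inherited from the
method. The window length is fixed per scan rather than adapted to local
LD. Missing genotypes, half-sibships and looped pedigrees are out of scope
for the phaser.
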