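---
title: "Detecting Dobzhansky-Muller incompatibilities from genotype-ratio distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Dobzhansky-Muller incompatibilities from genotype-ratio distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmiscan)
library(dplyr)
```

## The problem

When two genetically divergent populations are crossed, their hybrids can
suffer reduced fitness from Dobzhansky-Muller incompatibilities (DMIs):
deleterious epistatic interactions between alleles that never co-occurred in
either parental population. In organisms that can be crossed in the
laboratory — `dmiscan` is modelled on intercrosses between divergent
populations of the intertidal copepod *Tigriopus californicus* — DMIs leave a
statistical footprint in the genotype ratios of surviving hybrid offspring:

* **Single-locus distortion.** In an F2 intercross each marker should
  segregate 1:2:1 (P1/P1 : heterozygote : P2/P2); in a backcross, 1:1.
  Selective mortality of particular genotype classes bends these ratios.
* **Multi-locus nonindependence.** A DMI is an *interaction*, so, beyond
  marginal distortion, the joint genotype distribution across unlinked
  markers departs from independence.

A special feature of the motivating system is **achiasmatic female meiosis**:
females transmit each chromosome intact, without crossing over, while males
recombine. Whole chromosomes therefore cosegregate through the female side of
a cross, which both changes the statistical structure of backcross data and
gives experimental leverage — comparing recombinant (male-F1) with
nonrecombinant (female-F1) backcrosses separates effects that need an intact
multi-locus haplotype from single-locus effects.

`dmiscan` provides the statistics for all of this, together with a forward
simulator of the crossing designs so that every statistical property of the
pipeline can be validated on data whose generating process is known exactly.

## Single-locus statistics

For observed class counts $O = (n_0, n_1, n_2)$ and design proportions
$\pi$ (1:2:1 or 1:1), `gof_test()` computes the Pearson statistic
$X^2 = \sum_i (O_i - N\pi_i)^2 / N\pi_i$ over classes with $\pi_i > 0$, with
$\mathrm{df} = (\#\{\pi_i > 0\}) - 1$. Classes that are impossible under the
design (the absent homozygote of a backcross) are excluded structurally: an
observed count there is an error, not evidence.

`relative_viability()` rescales the homozygote classes against the
heterozygote reference so the Mendelian expectation is 1:

$$\hat w_{\text{hom}} = \frac{n_{\text{hom}}/e_{\text{hom}}}
 {n_{\text{het}}/e_{\text{het}}}
 \qquad (= 2\,n_{\text{hom}}/n_{\text{het}} \text{ for } 1{:}2{:}1),$$

with the delta-method standard error of a ratio of independent counts,
$\mathrm{SE} = \hat w \sqrt{1/n_{\text{hom}} + 1/n_{\text{het}}}$. The SE is
reported as missing when $n_{\text{hom}} = 0$ (the estimate itself is exactly
0 there, and the log-ratio variance is undefined). This estimator was chosen
because it is the unique heterozygote-referenced ratio estimate that
reproduces well-known small-count benchmark pairs exactly — counts
$(7, 8, 0)$ give $(1.75, 0)$ and $(3, 3, 1)$ give $(2.0, 0.67)$ — and it is
implemented as its own function so an alternative formulation can be swapped
in.

Two companions handle the awkward corners. `exact_multinomial_test()` is the
small-sample alternative (total multinomial probability of all outcomes no
more probable than the observed one; it equals exhaustive enumeration, which
the test suite verifies for all outcomes up to $N = 8$). It is capped at
$N = 200$ by default because enumeration grows quadratically and the
asymptotic test is accurate well before that. `heterogeneity_test()` compares
genotype ratios between groups (reciprocal crosses, sexes, temperatures) with
the textbook $r \times c$ contingency $X^2$; classes empty in every group are
collapsed first, and the degrees of freedom can be overridden explicitly when
a non-textbook convention must be matched.

## Interaction statistics that absorb lower-order structure

The naive approach — testing a 3x3 joint genotype table against the 1:2:1 x
1:2:1 product — confounds epistasis with single-locus distortion. The
two-locus statistic in `two_locus_test()` instead forms expectations from the
*observed* marginals, $E_{ij} = R_i C_j / n$. This is precisely what
"accounting for single-locus deviations first" means operationally: pure
viability selection acting independently at each locus moves the marginals
but leaves the table an outer product, so the statistic stays at its null
calibration. That is the central design property of the method, and the
acceptance suite verifies it by simulation: under strong but independent
selection at both loci ($w = (1,1,0.3)$ and $(0.4,1,1)$, $n = 120$, 2000
replicates) the rejection rate at $\alpha = 0.05$ stays inside the exact
binomial 99% envelope of 0.05.

For three loci, the analogous null is "all pairwise structure, no three-way
interaction". `ipf_fit_no_three_way()` fits it by iterative proportional
fitting to the three observed two-way margins — the unique maximum-entropy
table with the observed pairwise structure — and `three_locus_test()` takes
the Pearson residual statistic against that fit. IPF runs to a margin
tolerance of 1e-10 (capped at 1000 cycles, error on non-convergence); fitted
cells below 1e-12 are treated as structural zeros, excluded from the sum with
one df removed each, and a sparse-table warning is raised when any retained
expected cell is below 1.

**Degrees of freedom for the three-locus test.** The log-linear count for the
saturated-minus-pairwise model on a 3x3x3 table is $(3-1)^3 = 8$. The
published critical values this scan family is usually compared against,
however, are computed at 12 df. `three_locus_test()` therefore exposes a
`df_policy`: `"reported_12"` (default, so thresholds like
$X^2_{0.05/1780} = 42.4$ reproduce) and `"loglinear_8"`. The discrepancy is
real: under null simulation the mean of the statistic is about 8, not 12
(asserted in the test suite), so the 12-df convention is conservative. For
df-free inference, `permutation_p()` permutes one marker's genotype column
within the stratum — preserving every marginal, breaking joint structure —
and returns $(1 + \#\{X^2_{\text{perm}} \ge X^2_{\text{obs}}\})/(1 +
n_{\text{perm}})$.

## Multiple testing

Markers on the same chromosome are linked, so their nonindependence is
expected and uninformative about epistasis. `enumerate_tests()` therefore
restricts the scan family to tuples on pairwise distinct chromosomes by
default (`policy = "all"` exists for sensitivity analysis). On the default
25-marker/12-chromosome panel this gives 276 pairs and 1780 triples — the
elementary symmetric polynomials $e_2$ and $e_3$ of the per-chromosome marker
counts, which is how the tests cross-check the enumeration. Thresholds are
plain Bonferroni (`bonferroni_alpha()`), matching standard practice in this
literature; no sequential procedure is applied by default, though the scan
output carries raw p-values so Holm or BH can be layered on. Scans also flag
a relaxed $p < 0.001$ tier, the conventional "suggestive" reporting cut for
these designs.

## The simulator

`simulate_cross()` is a forward simulator of the crossing designs:

* **Genomes** are pairs of haplotypes (population-of-origin labels per
  marker). F1 hybrids are heterozygous everywhere; mutation and genotyping
  error are not modelled (a misclassification layer could be added, but the
  analyses target population-of-origin classes, not raw calls).
* **Recombination** is a per-chromosome Poisson crossover process on the
  genetic map (Haldane model, no interference), so two markers $d$ cM apart
  recombine with probability $r = (1 - e^{-2d/100})/2$. Females carry a
  `female_recombination` multiplier, default 0: chromosomes pass through
  females intact. The no-interference choice is the simplest model consistent
  with using map distances, and none of the statistics depend on
  interference.
* **Viability selection** multiplies per-locus fitness vectors and epistatic
  fitness tables (each normalised by its maximum) into a survival
  probability; offspring are drawn by rejection sampling until `n_offspring`
  survivors accumulate, with a cap of 1000 candidate draws per survivor so
  that a near-impossible model fails fast with a clear error instead of
  spinning.
* **Sex** is a fair coin by default; a polygenic option
  (`sex_model("polygenic")`, logistic in P2-allele dosage at chosen markers)
  exists solely so simulated data can exhibit genotype-sex associations for
  pipeline testing, not as a model of sex determination.
* **Designs**: the F1 x F1 intercross, all eight backcross types
  (`simulate_backcross_panel()`: F1 origin x F1 sex x recurrent population),
  and the two-generation backcross-then-intercross design
  (`simulate_bc2_intercross()`) in which only carriers heterozygous at a
  focal marker are propagated — with achiasmatic females this retains the
  *entire* focal chromosome heterozygous, which the tests assert exactly.

The default panel (`default_marker_panel()`) spreads 25 markers over 12
chromosomes with counts (1,3,5,3,2,2,1,4,1,1,1,1) and labels `1`, `2a`-`2c`,
`3a`-`3e`, ..., `12`. Positions are placeholders — 20 cM spacing within each
chromosome — and are documented as arbitrary; they drive linkage in the
simulator but are not estimates of any real map.

Everything is deterministic given the configuration: the seed is a required
field, and the pipeline tests assert byte-identical outputs across repeated
runs.

## What the synthetic data does and does not show

The simulator reproduces the statistical structure the analysis assumes:
Mendelian transmission, sex-limited recombination, viability selection acting
multiplicatively through specified loci, and the complete-case missingness
handling of the tabulations. It does **not** emulate genotyping error or
marker failure, maternal/clutch effects, temperature-dependent selection
(temperature is carried as metadata only, since no mechanism is specified for
it), density or culture-condition variation, or mitochondrial-nuclear
interactions beyond what a maternal-population-stratified fitness table can
express. Passing calibration on simulated data therefore demonstrates that
the statistics do what they claim under the stated model — not that real
crosses satisfy that model.

One property of the model is worth stating explicitly because it bounds what
a backcross contrast can show. Under a fully penetrant two-locus lethal
carried in coupling (both P2 alleles required), a nonrecombinant (female-F1)
backcross loses the entire P2-transmitting gamete class, producing extreme
1:1 distortion at the focal markers. The recombinant (male-F1) backcross is
also marginally distorted — survivors carry the P2 allele at a focal marker
with probability $r/(1+r) \le 1/3$ — so at large sample sizes *both* cross
types reject the 1:1 expectation and the qualitative "only nonrecombinant
crosses deviate" pattern appears only as a difference in magnitude
(noncentrality $\approx 4n(1/2 - r/(1+r))^2$ versus $n$), or at the modest
sample sizes and partial penetrance typical of real backcross data. The
acceptance script reports both rates so this contrast is measured, not
assumed.

## Numerical and design choices

* Genotype codes are `0/1/2/NA` with 0 = homozygous P1, fixed dataset-wide;
  TSV with `"NA"` is the canonical dialect, comma accepted on read.
* Complete-case handling lives in the counting layer (`marginal_counts()`,
  `joint_counts()`); I/O never drops rows.
* Scan ranking ties break lexicographically on marker ids after descending
  chi-squared.
* Scans never abort on a degenerate marker or tuple; the row is emitted with
  an explanatory `note` and missing statistics.
* Significance flags always accompany raw p-values and the threshold used,
  so reports can re-display but never re-threshold.
* Test problem sizes (2000 replicates for type-I calibration, 200 seeds for
  parameter recovery, 100 seeds for the backcross contrast, n of 120-1000
  per simulated cross) were chosen to make binomial envelopes tight enough
  to detect miscalibration of a few percentage points while keeping the
  default suite fast.

## Limitations

* The three-locus df convention is exposed but cannot be resolved
  statistically here; permutation p-values are the recommended arbiter for
  borderline triples.
* The exact multinomial test enumerates outcome vectors; it is intended for
  the small tables (N of tens) where the asymptotic test is doubtful.
* The pipeline analyses strata independently; pooling across reciprocal
  crosses is an explicit configuration choice, never implicit, because
  maternal background is confounded with cross direction.
* Relative-viability SEs are delta-method approximations and degrade at very
  small counts; the printed values remain exact ratios.
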