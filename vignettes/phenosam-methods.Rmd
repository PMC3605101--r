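---
title: "phenosam: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenosam: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosam)
options(phenosam.verbose = FALSE)
```

## The problem

Exercise-physiology and ageing cohorts often measure a *continuous*
phenotype per subject — percent change in lean mass after months of
resistance training, or chronological age across a deliberately wide
recruitment range — together with a genome-wide expression profile.
Dichotomizing such phenotypes (responder vs non-responder, young vs old)
throws away the information the study design worked hardest to collect.
phenosam implements the alternative: score every gene's *linear*
association with the phenotype, calibrate significance by permuting subject
labels, and interpret the resulting directional gene lists with
network-based regulator inference, positional enrichment and cross-cohort
replication.

## Quantitative SAM

For gene $i$ with expression $x_{ij}$ and phenotype $y_j$ over $n$
subjects, the score is

$$d_i = \frac{b_i}{s_i + s_0},$$

where $b_i$ is the least-squares slope of $x_i$ on $y$, $s_i$ its standard
error, and $s_0 \ge 0$ a "fudge factor" that prevents genes with tiny
variance from reaching huge scores on noise. With $s_0 = 0$, $d_i$ is
exactly the regression t-statistic; the paired variant uses the mean and
standard error of the subject-wise change (post − pre), and the two-class
variant the pooled-SE mean difference. These identities are asserted in the
test suite at $10^{-10}$.

**Tuning $s_0$** (`estimate_s0()`) follows the classic SAM rule: candidates
are the 0, 5, …, 100 percentiles of the $s_i$ distribution; for each
candidate the genes are sliced into quantile windows of $s$ and the median
absolute deviation of $d$ is computed per window; the winner minimizes the
coefficient of variation of these window MADs, i.e. makes the spread of $d$
maximally independent of $s$. Ties go to the smaller percentile, and with
fewer than two distinct $s$ values the median of $s$ is returned with a
warning. The default window count is 100, reduced automatically when there
are fewer than ~500 genes.

**Permutation FDR** (`permutation_fdr()`). The null is built by permuting
the subject labels: shuffling $y$ (quantitative), sign-flipping the
subject-wise differences (paired), or shuffling group labels (two-class).
When the number of distinct relabelings ($n!$, $2^n$, $\binom{n}{n_1}$)
does not exceed the permutation budget `B`, all of them are enumerated
exactly; otherwise `B` random relabelings are drawn, each from an
independent sub-seed derived from `(seed, permutation index)` so results
are reproducible and independent of evaluation order. For 100 thresholds
$\delta$ spanning $[0, \max|d|]$, the observed call count is
$R(\delta) = \#\{|d_i| \ge \delta\}$ (boundary ties are called), each
permutation contributes a false-call count $\#\{|d_i^*| \ge \delta\}$, and

$$\widehat{\mathrm{FDR}}(\delta) \;=\; \min\!\left(1,\;
  \frac{\overline{\#\{|d^*| \ge \delta\}}}{R(\delta)}\right),
  \qquad \tfrac{0}{0} := 0 .$$

The per-gene q-value is the smallest $\widehat{\mathrm{FDR}}(\delta)$ over
thresholds at which the gene is called; because a larger $|d|$ is called at
a superset of thresholds, q is non-increasing in $|d|$ by construction. No
correction for the proportion of true nulls is applied; plain SAM-style
q-values are reported.

**Mean, not median, pooling of permutation false counts.** The summary
over permutations is the *mean* false-call count by default, with the
median available via `fdr_summary = "median"`. The median — the summary
popularized by the original SAM report — is anti-conservative at the
extreme tail: at the threshold equal to the maximal observed score, about
half of all null permutations contain no exceedance at all, so the median
false count (and with it the top gene's q-value) collapses to zero in
roughly half of *pure-noise* datasets. We measured exactly this: under a
global null (1000 genes × 40 subjects, 200 permutations), the median
summary produced at least one q ≤ 0.05 call in about half of simulated
cohorts, while the mean summary produced essentially none. Since the
package's contract is that a 5% gate on pure noise should essentially never
fire, the mean is the default.

**Significance gating and responder filtering.** `select_significant()`
applies the conventional 5% FDR gate (configurable). For paired
differential analysis after an intervention, `filter_responders()` removes
subjects whose phenotype response does not exceed a threshold (strictly
greater than 0 by default), reflecting the logic that chronic differential
expression is only interpretable in subjects who actually adapted.

## Upstream-regulator inference

Given a signed regulator→target network (user-supplied, e.g. a curated
literature network), the signature of significant genes is compared with
each regulator's target set two ways:

* **Overlap p** — the right-tailed Fisher exact probability of the observed
  overlap, identical to the hypergeometric upper tail
  $P(X \ge k)$ on the background universe. The background is the
  intersection of measured genes with the network's gene universe,
  mirroring the mapping losses of real probe-to-database conversion (an
  alternative chip-wide background would make every overlap look more
  surprising; the mapped background is the conservative choice).
* **Activation z** — each overlapping target is *consistent* when
  edge sign × observed direction = +1;
  $z = (N^+ - N^-)/\sqrt{N^+ + N^-}$. $|z| \ge 2$ is the conventional
  activated/inhibited call; a positive z means the regulator's activity
  increases with the phenotype.

Gating is on the raw overlap p (default $p < 0.001$) as is conventional
for this analysis; a Benjamini–Hochberg column is emitted for information
only. Edge weights are not supported — the z is unweighted directional
consistency, because literature-confidence weights belong to proprietary
databases and are out of scope. Regulators with no target in the
background are untestable and excluded from ranking rather than given a
fake p of 1.

## Positional gene enrichment

Interest genes (e.g. the replicated age-correlated set) are tested for
chromosomal clustering. Per chromosome, with genes in start-coordinate
order, the *canonical* candidate regions are exactly the gene-index
intervals whose first and last genes are interest genes — a chromosome
with $m$ interest genes yields $\binom{m}{2} + m$ candidates, and
minimality ("no smaller region contains the same genes of interest")
holds by construction. Each candidate containing $k$ of $n$ genes is
scored with the hypergeometric upper tail against the genome-wide
background ($N$ annotated genes, $K$ interest genes). Six rules prune the
candidates; a region survives iff:

1. it contains at least two interest genes;
2. no smaller region contains the same interest genes (by construction);
3. no bigger candidate has more interest genes and the same number of
   non-interest genes (maximality among cost-free extensions);
4. no strictly containing candidate has a strictly higher interest
   fraction $k/n$;
5. no strictly contained candidate has a strictly smaller p;
6. it contains no strictly contained canonical sub-region with fewer
   interest genes than expected.

All comparisons are strict, so exact ties retain both regions; the audit
trail records the first failed rule for every rejected candidate. Two
genuinely open readings were settled as follows. Rule 3's "bigger region"
is operationalized as a containing candidate that adds interest genes at
zero non-interest cost, which is the only reading that makes rule 3
distinct from rule 4. Rule 6's "expected" count defaults to the
genome-wide rate $n_{sub} K/N$ (`baseline = "genome"`), the most literal
reading; a parent-region rate $n_{sub}\,k/n$ is available
(`baseline = "parent"`). Scoring uses the genome-wide background; the
per-chromosome alternative is intentionally not offered because it makes
p-values incomparable across chromosomes. No multiple-testing correction
is applied across regions (reported p-values are raw, with the default
report gate at $p \le 0.01$); an optional interest-label permutation null
(`perm_fdr = N` rounds) reports how often a scattered interest set of the
same size produces any gated region.

The whole scan is validated in the test suite against a literal
reference implementation that enumerates *every* interval and applies
every rule by explicit quantifier — exact set equality on random
chromosomes of up to 60 genes.

## Cross-cohort replication and PCA integration

`replicate_across_cohorts()` implements discovery-then-confirmation:
genes passing the discovery cohort's FDR gate are confirmed in an
independent cohort when present there, sign-consistent, and nominally
significant (two-sided regression p ≤ 0.05 by default). The confirmation
criterion is deliberately nominal rather than a second FDR gate: the
discovery gate already controls the family-wise burden, and the
confirmation tests only the discovered genes; a stricter both-cohorts-FDR
mode is obtained by passing a q-based score table instead.

For phenotype integration, heterogeneous physiological variables are
brought onto one scale by robust location/scale transformation —
$(x - \mathrm{median})/\mathrm{MAD}$ with the Gaussian-consistency
constant 1.4826 — after which `run_pca()` computes the singular value
decomposition of the column-centered subjects × variables matrix.
Variance fractions come from squared singular values; for reproducibility
each loading vector is flipped so its largest-magnitude entry is
positive. Constant variables (MAD = 0) are rejected by name rather than
silently dropped. `shared_variance_report()` then asks the study's
integrative question directly: which component carries the focus
phenotype, and how strongly does every other variable load on it.

## The synthetic-data layer

The generators are first-class, tested code; they define the conditions
under which the pipeline's statistical guarantees are stated.

* `simulate_cohort()` — the phenotype is drawn **uniformly** over its
  range (default −3 to 28, the span of lean-mass responses such training
  studies produce; age cohorts would use e.g. 18–78), because the target
  designs deliberately recruit a continuum rather than a bell curve; a
  Gaussian option exists. Planted genes receive
  $x_{ij} = \mu_i + s_i\,\beta\,y_j + \varepsilon_{ij}$ with Gaussian
  noise on the log2 scale (`noise_sd = 1`) and
  $\beta = \rho\,\sigma_\varepsilon / (\sigma_y \sqrt{1-\rho^2})$, so the
  planted *population correlation* is exactly `effect_rho` (default 0.6):
  parameterizing by correlation rather than slope keeps statistical power
  interpretable independently of the noise level. Defaults are 1000
  genes, 44 subjects, 50 planted. In paired mode the signal is placed on
  the post − pre change and the pre matrix is independent baseline noise,
  matching designs that correlate expression *change* with phenotype
  change. Gaussian residuals are a modeling assumption of the generator,
  not a claim about any particular chip technology.
* `simulate_network()` — one planted regulator draws its targets from the
  planted genes with edge signs matching the planted directions at rate
  `consistency`; decoys draw uniformly with random signs. The three
  generators use decorrelated per-module sub-seeds internally, so passing
  the same user seed to cohort and network generation cannot alias the
  decoy target draws onto the planted gene draws.
* `simulate_genome()` — four equal-sized synthetic chromosomes (the
  smallest structure that exercises per-chromosome logic) of sorted,
  non-overlapping intervals; `cluster_size` planted genes occupy
  consecutive slots at one random locus (the recorded planted region) and
  the rest scatter uniformly.

What the generator deliberately does **not** emulate: array-level batch
effects and chip outliers, probe-level structure, correlated co-expression
modules, heavy-tailed noise, and non-linear phenotype trajectories.
Passing tests therefore demonstrate the *statistical machinery* is correct
and calibrated under its stated model — not that any real cohort satisfies
that model. On real data the PA-presence filter, probe collapsing
(max-IQR representative by default, which avoids averaging probes of
different hybridization affinity) and the robust scaling exist precisely
because real arrays violate the clean model.

## Numerical choices and degenerate inputs

* Presence filtering defaults to Present in ≥ 25% of samples — a
  permissive threshold for detection-call filtering; it is configurable
  because no single fraction suits all chip generations.
* Missing expression values are rejected, never imputed.
* Delta grid: 100 evenly spaced thresholds on $[0, \max|d|]$, endpoint
  pinned exactly so the top gene is always called at the last threshold;
  calling is symmetric in $|d|$ (both directions reported together, as
  positive and negative correlates are equally of interest).
* Zero standard errors: a gene collinear with the phenotype has $s = 0$;
  with a user-chosen $s_0 = 0$ this is an error naming the gene, while
  inside the permutation pipeline raw slopes are assembled first and the
  check applies to the final $s_0$ actually used.
* q-values are capped at 1; 0/0 FDR ratios are defined as 0.
* PGE rule comparisons are strict inequalities; ties retain both regions.
* All scan outputs are invariant to input record order; this is asserted
  by tests for the network and annotation inputs.

## Problem sizes used by the test suite

The suite states its guarantees at desk scale: permutation calibration and
power use cohorts of 1000 genes × 40 subjects with 200 permutations over
20 seeds; exact-enumeration cross-checks use 2–25 genes over 4–6 subjects
where the full permutation group is computable; PGE oracle equivalence
uses chromosomes of ≤ 60 genes where the all-intervals reference is
affordable. These sizes were chosen so the whole suite completes in a few
minutes while keeping every Monte-Carlo check at the scale its acceptance
bound was derived for.

## Known limitations

* Only simple linear association per gene; no covariate adjustment,
  interaction terms, or moderated-variance empirical Bayes shrinkage.
* The activation z treats all edges equally; no literature-confidence
  weighting, and no mechanistic path analysis beyond direct targets.
* PGE reports raw p-values; the optional permutation null is a
  calibration report, not a corrected inference.
* Cytoband naming of enriched regions requires an external cytoband
  annotation and is not computed.
* The replication logic assumes both cohorts measured the same phenotype
  on comparable scales; no meta-analytic effect pooling is attempted.
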