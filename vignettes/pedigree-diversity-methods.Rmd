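---
title: "Pedigree-based diversity analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-based diversity analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedlion)
```

`pedlion` estimates the genetic state of a small captive population from
its studbook alone. This vignette is the package's account of the
underlying models, the conventions it adopts where the literature leaves
room, and what its validation on synthetic data does and does not
establish about real studbooks.

## The pedigree model and its founder conventions

A studbook is a table of animals with sire and dam identifiers, sex,
birth date, location and a flag marking the living, analysed subset (the
*reference population*). All parameters below treat the pedigree's
founders — animals with both parents unrecorded — as unrelated and
non-inbred. That assumption is the load-bearing one in every
pedigree-based analysis: if founders were in fact related, all reported
inbreeding and diversity-loss figures are underestimates.

Two conventions keep the bookkeeping exact:

* **Phantom founders.** An animal with exactly one recorded parent gets a
  unique phantom founder in the empty slot. Phantoms are never shared, so
  they introduce no spurious relatedness, and they make gene-flow
  accounting exact (founder contributions sum to 1 by construction).
  Phantoms count as *founders* for gene-origin parameters but as
  *unknown* for completeness measures — the first is a statement about
  gene pools, the second about record quality.
* **Referenced-but-undefined parents** become ordinary founder records
  (with a warning): they are recorded ancestors whose own parents are
  unknown, which is precisely the founder definition.

Validation is permissive by default — real studbooks contain sex-role
and date inconsistencies that should be surfaced, not fatal — and strict
mode turns those findings into errors for pipelines that need a clean
gate.

## Completeness

Four measures are computed per animal: the maximum and the fully traced
generation counts, the equivalent complete generations
$t = \sum_{\text{known ancestors}} (1/2)^n$ (one term per path), and the
completeness index, the harmonic mean of per-parental-line known-ancestor
proportions averaged over the first $d$ generations. The default depth is
$d = 5$, the conventional reporting window for studbooks; the harmonic
mean makes the index 0 whenever either parental line is entirely unknown,
which is the intended behaviour for a measure of *balanced* ancestral
knowledge. $t$ is computed by the linear-time recursion
$t(x) = \sum_{\text{known parents } p} \tfrac12 (1 + t(p))$, which equals
the path sum exactly; the test suite checks that equality against
explicit path enumeration.

## Kinship, inbreeding rates and effective size

The numerator relationship matrix is built by the tabular recursion over
a topological ordering ($a_{xy} = \tfrac12(a_{sy} + a_{dy})$,
$a_{xx} = 1 + \tfrac12 a_{sd}$). Relationship values are dyadic rationals
computed in double precision and never rounded internally. The classical
path-counting formula with the $(1+F_a)$ correction for inbred common
ancestors serves as an independent oracle in the tests, not as the
implementation — the two agree to machine precision on hundreds of random
pedigrees.

Individual increases in inbreeding use
$\Delta F_i = 1 - (1 - F_i)^{1/(t_i - 1)}$. The exponent uses $t - 1$
rather than $t$ because inbreeding can first arise in the second
generation: in an ideal population the expected inbreeding after $t$
discrete generations is $1 - (1 - \Delta F)^{t-1}$, so this form recovers
the per-generation rate without bias (the ideal-population recovery test
confirms it within a few percent at $N = 20$). Animals with $t \le 1$
have no defined rate; they are excluded from averages and reported in the
`n_used` counts rather than imputed, because silent imputation biases the
resulting effective size. The generation-mean form
$(\bar F_t - \bar F_{t-1})/(1 - \bar F_{t-1})$ is implemented separately
(`delta_f_generations()`): the two forms answer slightly different
questions and reconcile only on deep, evenly sampled pedigrees, so the
package exposes both rather than choosing silently.

Both effective-size estimators are restricted by default to the
reference population. The co-ancestry form averages
$\Delta c_{jk} = 1 - (1 - c_{jk})^{2/(g_j + g_k)}$ over all unordered
reference pairs; because it pools information across pairs it is the more
robust figure on shallow pedigrees, and on censored data the two
estimators can legitimately diverge (the individual form only sees
inbreeding that the recorded pedigree can detect).

## Gene-origin parameters

Founder contributions come from the downward gene-flow recursion; with
phantom founders in place they sum to 1 exactly (tested at $10^{-12}$).
The effective number of ancestors uses the iterative
marginal-contribution algorithm: each round selects the ancestor with the
largest contribution not yet explained, computed with previously selected
ancestors masked (acting as founders) and discounted by the fraction of
the candidate's own genome already explained. Ties are broken by earliest
topological position, making the selection deterministic. Selection stops
when the best marginal contribution falls below $10^{-9}$ — far below any
meaningful contribution in pedigrees of this size, so the cutoff affects
only degenerate tails.

Founder genome equivalents are reported two ways:

* `"coancestry"` (default, deterministic): $f_g = 1/(2\bar f)$ with
  $\bar f$ the mean co-ancestry over all reference pairs including self
  pairs. This is the exact definition.
* `"genedrop"` (Monte Carlo): two uniquely labelled alleles per founder
  are segregated through the pedigree. The primary gene-drop $f_g$ is
  $1/(2 \cdot \mathbb{E}[\text{founder-allele homozygosity}])$, whose
  expectation equals $\bar f$ exactly, so the two methods agree within
  Monte-Carlo error (the acceptance suite requires 2% at $10^5$
  replicates). The classical retention approximation
  $f_g \approx 1/\sum_j p_j^2 / r_j$ is also returned
  (`fg_retention`, with the per-founder allele retention $r_j$) because
  the retention vector itself is diagnostically useful; on very small
  pedigrees this approximation is visibly biased upward (e.g. 1.50
  vs. the exact 1.33 on a two-full-sib reference), which is why it is not
  the primary estimate.

The diversity-loss partition is exact by construction:
$1 - GD = (1 - GD^*) + (GD^* - GD)$ with $GD = 1 - 1/(2f_g)$ and
$GD^* = 1 - 1/(2f_e)$ — total loss splits into founder-imbalance loss and
drift loss. The theoretical ordering $f_a \le f_e \le f$ is asserted on
every fixture; a violation is treated as a bug, not a data feature. A
single reference set is used per report: mixing reference sets across
parameters can produce apparent ordering violations and is deliberately
not supported.

## Generation intervals

Ages are differences of birth dates divided by 365.25 days. The
`"reproducers"` mode keeps only offspring that themselves have offspring
— the classical definition based on parents of the next breeding
generation — while `"all"` ignores reproductive fate. Pairs with missing
dates or unknown offspring sex are excluded *and counted* so users can
audit how much data supported each pathway; negative ages are excluded
with a warning rather than clamped, because they are data errors that
validation owns. Year-only birth dates resolve to July 1 (the annual
midpoint), which leaves age differences unbiased on average.

## Structure

Subpopulations are location groups of the reference animals. Mean
co-ancestries $f_{ij}$ include self pairs within groups, so singleton
groups are well defined. Pairwise differentiation uses the Nei
minimum-distance form on co-ancestries,
$F_{ST,ij} = \big(\tfrac{f_{ii}+f_{jj}}{2} - f_{ij}\big) \big/
\big(1 - \tfrac{f_{ii}+f_{jj}}{2}\big)$, clamped to $[0,1]$. This
estimator is standard for pedigree co-ancestry partitions, is 0 for
identical groups and 1 for unrelated non-inbred singletons, and decreases
monotonically as between-group co-ancestry rises; the estimator name is
recorded in report metadata since pedigree-FST variants differ across
software. The dendrogram is average-linkage (UPGMA) clustering of the FST
matrix, exported as Newick. The PCA double-centers the relationship
matrix and scales eigenvectors by $\sqrt{\lambda}$ — treating **A** as a
similarity so that coordinates embed genetic distance — rather than
column-standardizing, which would distort relative relatedness.

## Mating plans

Candidates are grouped by average relatedness at 4% and 12.5% (boundary
values fall in the middle group; the thresholds are conventional
studbook-management cutoffs, configurable). Pair recommendation minimizes
pair kinship — which *is* the predicted offspring inbreeding — under a
ceiling of 0.0625 (first-cousin kinship) and a per-animal use limit. The
default matcher is greedy over pairs sorted by kinship with ties broken
by id (transparent and deterministic); an exact matcher (maximize pair
count, then minimize total kinship, via bitmask dynamic programming) is
available for instances with at most 10 females, and the tests verify
greedy against exhaustive enumeration on small cases. The pairing
objective is an implementation choice of this package: group membership
is the principled part, the matcher is a convenience.

## The synthetic studbook generator

The generator exists so that every estimator can be validated against
known truth. It emulates the features the estimators care about:

* a founder cohort followed by discrete offspring generations under a
  configurable mating policy (`random`, `full_sib_bias`, `min_kinship`),
  Poisson litter sums, a sex ratio, parental ages
  (normal, mean 6.5 y, SD 2.5 y, truncated at 2 y — large-felid-like
  values), locations with transfer probability;
* an *ideal-population mode* (constant size $N$, random union of gametes,
  balanced sexes) in which theory fixes $\Delta F = 1/(2N)$ per
  generation — the headline parameter-recovery target;
* *censoring*: parent links are deleted with per-cohort probabilities,
  indexed by backward birth cohort (youngest = 1). A parent link belongs
  to one pedigree row while "ancestor depth" is relative to each
  descendant, so a literal per-depth deletion probability is ill-defined
  on a shared pedigree; cohort indexing coincides with ancestor depth for
  the youngest animals and yields the closed-form expectation
  $\prod_{b \le g}(1 - s_b)$ for the completeness profile at depth $g$,
  which the tests check.

The shipped preset (`paper_shape_config()`) produces a studbook-shaped
population: ~450 animals over 7 generations, ~20% flagged as a living
reference drawn from the youngest two cohorts, a dozen locations, and a
censoring schedule under which first-generation completeness is ~73% and
falls to near zero by the fifth generation. Ground truth (cohorts, true
founder contributions, uncensored inbreeding) is recorded *before*
censoring. Problem sizes used in the validation suite — pedigrees of up
to ~12 animals for oracle equivalence, 50 replicates of $N = 20$ over 10
generations for parameter recovery — were chosen as the smallest sizes at
which the checked quantities are statistically stable.

What the generator does **not** emulate: mortality and litter
seasonality, age-structured overlapping-generation demography,
non-random association between censoring and relatedness (in real
studbooks missing parents are *not* missing at random), and founder
relatedness. Passing tests therefore establish the correctness of the
estimators given a pedigree, not the accuracy of any particular real
studbook's figures.

## Numerical choices and limitations

* Relationship values are exact dyadic rationals carried in doubles;
  reports round to 4 significant digits only at output.
* Positive semi-definiteness of **A** is asserted with an eigenvalue
  floor of $-10^{-8}$.
* Infinite effective sizes (zero mean increase) are reported as `Inf`,
  never clamped.
* The dense relationship matrix is $O(n^2)$ memory; comfortable to a few
  thousand animals, which covers studbooks by a wide margin.
* Inbreeding-class edges default to $[0, 0.01)$, $[0.01, 0.13)$,
  $[0.13, 1]$ — the conventional none / mild / high split. A nominal
  "$F \le 0$" lowest class is interpreted as $F = 0$, since negative
  pedigree inbreeding is impossible.
* All percentages in reports appear as both fraction and percent.

The package reports no empirical constant that its own tests or the
acceptance script do not compute at run time.
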