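# pedlion

Pedigree-based genetic diversity analysis for small captive populations
managed through studbooks — zoo breeding programmes, conservation herds,
rescued remnant lineages. When molecular data are unavailable, the
studbook is the only window onto a population's genetic state, and a
standard battery of genealogical parameters quantifies how much diversity
a captive group retains and how fast it is losing it.

`pedlion` implements that battery end to end on plain delimited studbook
tables:

* **Pedigree handling** — parsing with configurable missing-value codes,
  phantom founders for single missing parent slots, topological ordering,
  validation (cycles, sex roles, birth-date ordering), reference-population
  extraction with ancestor closure.
* **Completeness** — maximum / fully traced / equivalent generations and
  the MacCluer completeness index `PCI = 2·Cp·Cm/(Cp + Cm)`, per animal
  and as per-generation profiles.
* **Kinship** — Wright's numerator relationship matrix **A** by the
  tabular method; inbreeding `F_i = a_ii − 1`; average relatedness
  `AR_i = (1/2n) Σ_j a_ij`; individual increase in inbreeding
  `ΔF_i = 1 − (1 − F_i)^{1/(t_i−1)}` with `t` the equivalent complete
  generations; and two effective-size estimators,
  `N̄e = 1/(2·mean ΔF_i)` and the pairwise co-ancestry form
  `N̄e_c = 1/(2·mean Δc_jk)` with
  `Δc_jk = 1 − (1 − c_jk)^{2/(g_j+g_k)}`.
* **Gene origin** — founder contributions `q_k` by gene-flow recursion;
  effective number of founders `f_e = 1/Σ q_k²`; effective number of
  ancestors `f_a = 1/Σ p_j²` from iterative marginal contributions
  (bottleneck-sensitive); founder genome equivalents `f_g` both
  deterministically from mean co-ancestry (`f_g = 1/(2·f̄)`) and by
  Monte-Carlo gene dropping with per-founder allele retention; the
  partition of diversity loss `1 − GD = (1 − GD*) + (GD* − GD)` into
  founder-imbalance and drift components.
* **Generation intervals** — mean parental age at offspring birth along
  the father-son, father-daughter, mother-son and mother-daughter
  pathways, for all offspring or only those that themselves reproduced.
* **Structure** — subpopulation mean co-ancestries, pairwise pedigree FST
  (Nei minimum distance on co-ancestries), UPGMA dendrograms exported as
  Newick, and PCA of the double-centered relationship matrix.
* **Mating plans** — AR-threshold candidate groups (< 4%, 4–12.5%,
  \> 12.5%) and minimum-kinship pair recommendation under a kinship
  ceiling, greedy or exactly matched on small instances.
* **Synthetic studbooks** — a simulator with known ground truth (true
  founder contributions, realized inbreeding, ideal-population mode with
  `ΔF = 1/(2N)`), plus a cohort-indexed censoring model that reproduces
  the declining completeness curves of real studbooks. Every estimator in
  the package is validated against it.

## Worked example

The package ships a small synthetic studbook (67 animals after phantom
creation, 35 of them flagged as the living reference population):

```r
library(pedlion)
sb  <- read_pedigree(system.file("extdata", "studbook_example.csv",
                                 package = "pedlion"))
ref <- reference_ids(sb)

relationship_matrix(sb, ref)
#> Kinship summary for 35 animals
#>   mean F  = 0.0080   mean AR = 0.0395
#>   mean dF = 0.0093 (over 24 animals with t > 1)

ne_estimates(sb, ref)
#> Ne (individual dF): 54.02  [24 animals]
#> Ne (co-ancestry):   17.40  [589 pairs]

gene_origin_report(sb, ref, replicates = 5000, seed = 1)
#> Gene-origin report: n = 35, f = 25
#>   fe = 18.52   fa = 14.56   n50 = 6
#>   fg = 9.40 (co-ancestry), 9.38 (gene drop)
#>   diversity loss: total 5.32% = founder 2.70% + drift 2.62%
```

Reading: the 35 living animals descend from 25 contributing founders, but
unequal founder use leaves the diversity of only ~18.5 equally
contributing founders (`fe`), a recent bottleneck narrows that to ~14.6
ancestors (`fa`), and drift plus allele loss reduce it to ~9.4 founder
genomes (`fg`); 5.3% of the founders' heterozygosity has already been
lost. The co-ancestry effective size (~17) is the drift-relevant figure —
well under the N e = 50 danger threshold for inbreeding effects — while
the individual-inbreeding estimate is larger here because the shallow,
heavily censored pedigree under-detects inbreeding relative to
co-ancestry.

A mating plan from the same objects:

```r
classify_by_ar(average_relatedness(sb)[ref])
#> Mating groups (AR < 0.04 | 0.04-0.125 | > 0.125): 18 / 17 / 0 animals

recommend_pairs(sb)   # min-kinship pairs among the AR < 4% group
#>     male female kinship predicted_F
#> 1 G2-014 G2-002       0           0
#> ...
```

`full_report(ped, dir)` runs every stage on one pedigree and writes a
directory of delimited tables, a Newick tree and a JSON index;
`simulate_pedigree(paper_shape_config())` generates a ~450-animal
studbook-shaped population to try it on.

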