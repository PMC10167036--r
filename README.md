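# hgonet

Coexpression screening and reversible kinetics of the geranylhydroquinone
oxidoreductase branch point.

In boraginaceous plants the biosyntheses of shikonin (red naphthoquinone
pigments) and shikonofuran derivatives diverge at geranylhydroquinone
(GHQ). The branch is controlled by an NADP(H)-dependent oxidoreductase of
the cinnamyl alcohol dehydrogenase family (AeHGO) that interconverts three
compounds — the (Z)- and (E)-isomers of 3''-hydroxy-GHQ and their common
aldehyde (E)-3''-oxo-GHQ — through two reversible reactions:

```
(Z)-3''-OH-GHQ + NADP+  <=>  (E)-3''-oxo-GHQ + NADPH
(E)-3''-OH-GHQ + NADP+  <=>  (E)-3''-oxo-GHQ + NADPH
```

hgonet implements, as tested R code, the three computational pillars of
the workflow that discovers and characterizes such an enzyme:

* **Coexpression candidate screen** over temporal FPKM matrices
  (SP / SD cell lines, 12–36 h methyl-jasmonate time course): abundance
  filter (FPKM ≥ 30 at the per-gene maximum), fuzzy c-means clustering of
  standardized profiles (c = 12, membership core ≥ 0.7), marker-guided
  cluster selection, and an exact affine-gap Smith–Waterman homology
  filter (BLOSUM62, gap 11/1) — `run_screen()`.
* **Enzyme kinetics**: Michaelis–Menten v = Vmax·S/(Km+S) and
  substrate-inhibition v = Vmax·S/(Km+S+S²/Ki) fitting by bounded
  Levenberg–Marquardt with analytic Jacobians, multi-start, Gauss–Newton
  standard errors and a Ki-identifiability diagnostic; unit arithmetic
  kcat = Vmax·M·1e-6 linking specific activity, turnover and catalytic
  efficiency — `fit_michaelis_menten()`, `fit_substrate_inhibition()`,
  `infer_molar_mass()`.
* **Reaction-network model**: the two reversible bi-substrate
  Michaelis–Menten fluxes above with exact Haldane closure (net flux
  vanishes at the configured Keq), NADP(H) recycling, an optional
  enzyme-retained ("channeled") NADPH pool and a competing NADPH sink —
  `simulate_network()`, `run_sink_experiment()`.

Synthetic-data generators (`synth_screen_study()`,
`generate_initial_rates()`, `generate_condition_profiles()`) plant
recoverable ground truth for every stage, so the whole pipeline is
testable without downloads. Exact-mass helpers (`monoisotopic_mass()`,
`deprotonated_mz()`) check the product-identity evidence (C16H20O3,
[M-H]⁻ = 259.1).

## Worked example

```r
library(hgonet)

## 1. the screen on a planted 5000-gene study at 20 % expression noise
study <- synth_screen_study(n_genes = 5000, noise_cv = 0.2, seed = 1)
tab <- run_screen(study$matrix, study$sequences, study$marker_sets,
                  screen_config(seed = 1), study$queries)
tab
#> candidate screen result
#>   genes: 5000 -> abundance 3500 -> cluster 820 -> candidates 9
#>   candidates:
#>    gene_id cluster membership best_score best_query
#>  gene00002      10  0.9808543       2962   ADH_seed
#>  ...
screen_precision_recall(tab, study$candidate_ids)[c("precision", "recall")]
#> $precision [1] 1        $recall [1] 0.9
```

5000 genes enter; 3500 clear the abundance filter; 820 sit in the two
marker-selected clusters with core membership ≥ 0.7; 9 of the 10 planted
ADH-like candidates survive the homology filter (one falls below the
membership core at this noise level) with no false positives.

```r
## 2. kinetics: triplicate noisy assay, fitted and converted to kcat
d <- generate_initial_rates(list(Km = 24.68, Vmax = 63.47),
                            c(3, 5, 10, 25, 50, 100, 200),
                            noise_cv = 0.05, seed = 1, replicates = 3)
fit_michaelis_menten(d, molar_mass = 40679)
#> Michaelis-Menten fit (21 points)
#>   Km    25.89 +/- 1.44 uM
#>   Vmax  65.32 +/- 1.14 pkat/ug
#>   kcat  2.657 1/s (kcat/Km 0.1026 1/uM/s)
#>   RSS 49.62
```

The fitted Km/Vmax sit within two standard errors of the generating
values (24.68 µM, 63.47 pkat/µg); the derived turnover matches the
published 2.58 ± 0.15 1/s for the (Z)-alcohol.

```r
## 3. the reversible network: oxidation time course and the sink experiment
sim <- simulate_network(network_params(), network_scenario("fig4E"))
round(100 * endpoint_composition(sim), 1)
#> ZOH EOH OXO
#>  33  40  27
run_sink_experiment()
#>   free_pool_sink     ZOH= 8.4% EOH= 9.9% OXO=81.7%
#>   channeled_sink     ZOH=33.0% EOH=40.0% OXO=27.0%
#>   max endpoint shift: free_pool 54.70 points, channeled 0.00 points
```

Starting from 200 µM (Z)-alcohol with 500 µM NADP⁺, the 25-minute mixture
is 33/40/27 % (Z)-alcohol/(E)-alcohol/aldehyde. A competing NADPH sink
collapses the mixture toward the aldehyde when the cofactor is released
to the bulk, but changes nothing when newly formed NADPH is retained at
the active center — the computational counterpart of the flavin-reductase
competition experiment.

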