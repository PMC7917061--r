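# cdmdim

Tools for deciding **how many latent attributes** underlie dichotomous
cognitive-diagnosis (CDM) data.

Cognitive diagnosis models (DINA, G-DINA) classify respondents into binary
attribute profiles through a J×K Q-matrix, and every empirical Q-matrix
estimation or validation method takes the number of attributes K as given.
cdmdim is for psychometricians and applied researchers who need to *choose* K:
it implements the dimensionality-assessment toolbox from the factor-analysis
tradition adapted to dichotomous CDM data, a CDM-native model-comparison
procedure, and a Monte Carlo harness for studying all of them.

## What is inside

* **Models** — DINA (`P_j(α) = g_j^(1-η)(1-s_j)^η`) and saturated G-DINA
  (`P_j(α*) = δ_j0 + Σ δ_jk α_k + Σ δ_jkk' α_k α_k' + ...`) estimated by
  marginal maximum likelihood EM over all 2^K latent classes (`fit_em`),
  with AIC/BIC (`information_criteria`) and absolute-fit residuals
  (`residual_stats`).
* **Simulator** — the full 972-condition factorial design (`sim_conditions`):
  K ∈ {4,5,6}, item quality ∈ {.40,.60,.80}, N ∈ {500,1000,2000}, J/K ∈ {4,8},
  attribute correlation ∈ {0,.30,.60}, thresholds ∈ {0,.50,1}, DINA/G-DINA;
  constrained random Q-matrices, thresholded equicorrelated normal profiles,
  banded item quality with monotonicity (`gen_dataset`).
* **Dimensionality statistics** — parallel analysis with random column
  permutation (Pearson/tetrachoric × mean/95th percentile), Velicer's MAP,
  very simple structure (v = 1, 2), DETECT, and the empirical Kaiser
  criterion (`assess_dimensionality`).
* **Q-matrix tools** — tetrachoric correlations (`tetrachoric_matrix`),
  discrete-factor-loading estimation (`dfl_estimate`), Hull/PVAF validation
  (`hull_validate`), and recovery scoring (`qrr`).
* **Model comparison** — fit candidates for K = 1..9 on empirically estimated
  and validated Q-matrices; select K by AIC, BIC, or pairwise residual counts
  (`mc_select`), and combine methods with the recommended decision guidelines
  (`combine_rules`).
* **Study harness** — hit rate / close hit rate / bias / RMSE, agreement
  metrics, partial eta-squared effect sizes, and a reproducible study runner
  (`run_study`, `study_metrics`, `study_agreement`).

A thin command-line interface (`inst/cli/cdmdim`) exposes `simulate`,
`assess`, `mc-select`, `study`, and `report` subcommands.

## Worked example

Simulate a four-attribute G-DINA dataset and ask several methods for K:

```r
library(cdmdim)
cn  <- sim_condition(K = 4, IQ = 0.8, N = 1000, JK = 4,
                     AC = 0.30, AT = 0.50, M = "GDINA")
sim <- gen_dataset(cn, seed = 42)

set.seed(42)
sugs <- assess_dimensionality(sim$responses,
                              methods = c("PA_rm", "MAP", "DETECT", "EKC"))
#> PA_rm suggests 4 dimension(s)
#> MAP suggests 4 dimension(s)
#> DETECT suggests 4 dimension(s)
#> EKC suggests 4 dimension(s)

set.seed(42)
mc <- mc_select(sim$responses, model = "GDINA", K_range = 1:6)
#> Model-comparison dimensionality assessment (GDINA)
#>  K   loglik n_params     AIC     BIC      min_p_r items_r converged
#>  1 -9633.05       33 19332.1 19494.0 1.57276e-190      16      TRUE
#>  2 -9276.59       35 18623.2 18795.0  6.55322e-91      16      TRUE
#>  3 -8755.02       49 17608.0 17848.5  1.85016e-24       8      TRUE
#>  4 -8484.00       65 17098.0 17417.0  6.26652e-03       2      TRUE
#>  5 -8500.58       83 17167.2 17574.5  2.33527e-07       7      TRUE
#>  6 -8440.32      127 17134.6 17757.9  3.25778e-03       2      TRUE
#> Suggested K: AIC = 4, BIC = 4, r = 4

combine_rules(c(PA_rm = 4, MC_AIC = 4, DETECT = 4))
#> $step: "a"  $decision: "retain"  $K: 4
```

Reading the table: each row is a candidate dimensionality; `loglik`,
`n_params`, `AIC`, `BIC` describe the fitted CDM under the DFL+Hull Q-matrix
for that K; `items_r` counts items with at least one significant pairwise
correlation residual (Bonferroni-corrected per item). All three selection
rules land on the generating K = 4, and the validated K = 4 Q-matrix
recovers 96.9% of the true q-entries here (`qrr(mc$Q[["4"]], sim$Q)`).

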