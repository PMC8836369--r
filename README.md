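# ccsnet

Reconstructing an unknown, undirected, unweighted network from the
dynamics its nodes exhibit — without ever observing an edge.

`ccsnet` targets the evolutionary-game setting: `N` agents on a hidden
graph repeatedly play a prisoner's dilemma (strategies C, D, TFT, WSLS,
and extortionate ZD) against their neighbours, and we observe only each
agent's strategy `s_i(t)` and accumulated payoff `y_i(t)` for `M` rounds.
Because the payoff is a sum of pairwise scores over the unknown
neighbourhood,

```
y_i(t) = Σ_j u(s_i(t), s_j(t)) · x_ij ,        x_ij ∈ {0, 1},
```

each node defines a linear system `y = F x` with a binary, sparse unknown
— a compressed-sensing problem with hard 0/1 structure. The package
implements and combines four per-node recovery engines:

* **ICS** — the exact 0–1 program `min Σx  s.t. ‖Fx − y‖∞ ≤ tol`,
  solved by an authored branch-and-bound with counting propagators over an
  authored bounded-variable simplex. Threshold-free: the output is already
  binary.
* **QCS** — the concave program `min Σ x(1−x)` over the feasibility
  polytope, driven to binary vertices by successive linearization
  (Frank–Wolfe), with randomized restarts.
* **CS** — L1 basis pursuit (one LP), and **LASSO** — non-negative
  penalized regression via `glmnet`, as baselines.
* **CCS** — the combined pipeline: a preliminary exact pass estimates the
  mean degree; the payoff-variance index (VR) classifies the topology and
  flags the hubs; fitted sample-capacity thresholds `M1 ≤ M3 ≤ M2` then
  dispatch each node to the solver that wins in its regime (QCS when data
  are scarce or the node is a hub, the exact solver otherwise).

Simulators for the game dynamics (synchronous Fermi imitation, periodic
strategy redraws, observation noise) and for Kuramoto oscillator networks
generate study data; evaluation tools score reconstructions (success rate
`SR = SREL·SRNC`, AUROC, AUPR), track per-node correct-recovery
frequencies, and regress accuracy on the payoff-diversity diagnostics
NDP and MF.

## Worked example

```r
library(ccsnet)

net <- generate_network("small_world", 30, 4, seed = 51)
tab <- payoff_table(c("C", "D"), b = 1.5, c = 1)
tr  <- simulate_game(net, tab, rounds = 40, seed = 51)

fit <- reconstruct_ccs(tr)
fit
#> Network reconstruction: 30 nodes, 40 samples; 60 inferred edges
#> estimated <k> = 4; type = homogeneous
#> solvers: ICS=30

score_reconstruction(fit, net)
#> # A tibble: 1 × 9
#>      tp    fp    tn    fn  srel  srnc    sr auroc  aupr
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1    60     0   375     0     1     1     1     1     1
```

Forty noiseless rounds are ample for a 30-node ring: the preliminary
exact pass already recovers every neighbourhood, the estimated mean
degree (4) and homogeneous classification route all nodes to the exact
solver, and all 60 true edges are found with no false positives
(`sr = srel · srnc = 1`). With fewer rounds or a hub-rich topology the
provenance column of `tidy(fit)` shows the mixed ICS/QCS dispatch, and
`autoplot(vr_profile(tr))` shows the VR index that drives it.

The payoff-diversity diagnostics work standalone:

```r
ndp(payoff_table(c("C", "D", "WSLS")))   # 8 distinct payoff values
glance(diversity_analysis(diversity_benchmark()))$r.squared  # 0.9326
```

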