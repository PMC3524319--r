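# primingscreen

Cellular priming (preconditioning) is the amplified response to a
high-dose stimulus after pretreatment with a dose too low to trigger a
visible response on its own — the classic example being macrophages
primed with sub-activating interferon-γ (0.15 µg/L) that then
over-respond to an activating dose (5 µg/L). `primingscreen` is an R
package for detecting priming and classifying its mechanism, written
for computational biologists analysing dose–time-course designs.

It implements, end to end:

* **The priming criterion.** A readout x₃ is primed when (1) low dose
  (LD) alone leaves it silent (max < 0.1 in reduced units), (2) high
  dose (HD) alone activates it, and (3) sequential LD+HD exceeds the HD
  response by ≥ 50%: `max(x₃)_LD+HD ≥ 1.5 · max(x₃)_HD`.
* **The three-mechanism classifier** on summary features with
  resolution cutoff δ = 0.1: Suppressor Deactivation
  (Δss x₁,LD < −δ for an inhibitor of the readout), Pathway Synergy
  (Δss x₂,LD > δ and Δmax x₂,LD+HD − Δmax x₂,HD > δ) and Activator
  Induction (Δss x₂,LD > δ with |Δmax difference| ≤ δ).
* **A three-node motif simulator** — stimulus S driving two parallel
  pathways x₁, x₂ that converge on x₃, with bounded Hill kinetics
  `dxᵢ/dt = kᵢAᵢ(1−xᵢ) − γᵢ(1+Iᵢ)xᵢ` — plus a seeded two-stage
  Metropolis search over 14 free parameters that recovers primed
  parameter sets and their mechanism regions at desk scale.
* **A time-course expression screening pipeline** (detection-call
  filter, fold changes, Welch tests with Benjamini–Hochberg FDR,
  LD-response and early/late/persistent dynamics classes, readout
  identification, dynamics-reshuffling analysis, mechanism roles).
* **A signed-network motif matcher** that maps role-annotated genes
  onto user-supplied regulatory edge lists and emits candidate
  PS/AI/SD priming motifs.
* **A 36-species, 50-parameter interferon-γ Jak/STAT kinetic model**
  with the prime–wash–restimulate protocol (0.15 µg/L × 72 h, 10-min
  wash, 5 µg/L × 48 h) and priming readouts phospho-STAT1 dimer and
  IRF-1.
* **A seeded synthetic-data generator** emulating a six-condition,
  three-pool, 12,000-probe microarray design with planted gene classes,
  so every stage is testable offline.

## Worked example

Classify the mechanism of the shipped pathway-synergy exemplar:

```r
library(primingscreen)

ex <- generate_trinode_exemplars()$PS
f <- trinode_features(ex)          # simulate all four arms, extract features
print(f)
#> <priming_features> readout = x3
#>               x1     x2     x3
#> dss_ld    0.0048 0.2896 0.0675
#> dmax_hd   0.5559 0.3194 0.1318
#> dmax_ldhd 0.5559 0.4535 0.2275
#> readout max: LD 0.0679 | HD 0.1318 | LD+HD 0.2275
evaluate_priming(f)
#> <priming_verdict> PRIMED - ok
classify_mechanism(f, graph = trinode_signed_graph(ex$topology))
#> <mechanism_label> PS
#>   - x2: dss_ld = 0.290 > delta and dmax(LD+HD) - dmax(HD) = 0.134 > delta (synergy)
```

The low dose leaves the readout at 0.068 (below the 0.1 bound), the
high dose reaches 0.132, and the primed arm reaches 0.228 — a 73%
excess over HD alone, carried by the slow low-threshold x₂ pathway
whose level the pretreatment raises by 0.29.

Screen a synthetic six-condition expression experiment and match roles
onto a network:

```r
g <- generate_expression(synthetic_spec(), seed = 42)
scr <- screen_expression(g$es)
print(scr)
#> <priming_screen> 11400 probes after detection-call filter
#>   non-trivial dynamics: 252
#>   LD-induced: 27 | LD-reduced: 18
#>   readouts: relaxed 57 | strict 50

net <- generate_network(n_ps = 3, n_ai = 2, n_sd = 2, seed = 1)
find_motifs(net$graph, net$roles, readouts = "R1")[, c("x1", "x2", "x3", "mechanism")]
```

Run the Jak/STAT priming protocol:

```r
m <- jakstat_model()
sim <- simulate_jakstat(m)
priming_readout_report(sim, "STAT1sD")$peak_ratio   # ~1.84
priming_readout_report(sim, "IRF1")$peak_ratio      # ~1.94
```

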