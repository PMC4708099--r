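# hnmmc

Coarse-grained **hierarchical natural-move Monte Carlo** simulation of
peptide detachment from MHC class I binding grooves, with the trajectory
analytics needed to turn detachment behaviour into binder/non-binder
predictions.

Class I MHC molecules present short peptides in a groove formed by two
kinked α-helices above a β-sheet floor; whether a peptide stays bound
decides whether it can trigger a T-cell response. All-atom molecular
dynamics cannot reach full-detachment timescales, so this package combines
three accelerations:

1. **3-point coarse graining** — each residue becomes a Cα bead, a carbonyl
   O bead and a side-chain-centroid bead; energies come from a
   distance-binned knowledge-based pair potential whose short-range part is
   damped by `s(r) = s0 + (1 − s0)(r/r0)^6` for `r < r0` (defaults
   `s0 = 0.15`, `r0 = 0.7` nm; `s ≡ 1` beyond).
2. **Natural moves on a region hierarchy** — rigid translations/rotations
   of whole structural regions (the β-floor, kink-split helix halves, whole
   helices, the peptide and its sub-regions; exactly 7 MHC nodes), with
   CCD-style chain closure repairing the backbone at region boundaries and
   Metropolis acceptance.
3. **Periodic simulated annealing** —
   `T(k) = s_T + (A/2)(1 + cos(2πk/Ω))` with defaults A = 600 K, Ω = 5000
   steps, s_T = 0 over 100 000 steps.

Detachment is monitored by three clamped Cα–Cα probes (peptide N/middle/C
terminus against the groove floor, 3 nm full-detachment ceiling). Per
peptide, replicas with different seeds yield a **detachment score** (mean
clamped probe distance), **pathway classes** (N-first / C-first /
simultaneous / stable), an **AROC** against binder/non-binder labels
(non-binder = positive class), Pearson correlation against log10 IC50, and
a **bootstrap analysis** of how the AROC's spread shrinks with replica
count.

Everything is testable offline: `make_toy_complex()` builds a desk-scale
groove–peptide complex and `make_go_potential()` a Gō-style native-contact
potential in which anchor strength — the driver of real pMHC binding at
peptide positions 2 and 9 — is dialled in exactly.

## Worked example

Simulate a two-anchor (binder-like) and an anchorless (non-binder-like)
toy peptide, 8 replicas of 20 000 annealed steps each:

```r
library(hnmmc)

run_system <- function(spec, seed) {
  cx <- make_toy_complex(spec)
  go <- make_go_potential(cx)
  run_replicas(go$structure, cx$hierarchy, go$potential, cx$probes,
               anneal_schedule(total_steps = 20000),
               n_replicas = 8, base_seed = seed, probe_stride = 100)
}
anchored <- run_system(toy_spec(), 100)                      # anchors at 2 and 9
anchorless <- run_system(toy_spec(anchor_depth = -0.4), 100) # no anchor advantage

detachment_score(anchored)
#> [1] 1.158622
detachment_score(anchorless)
#> [1] 1.583811
table(classify_pathways(anchored, threshold = 2.2, margin = 10))
#>
#>            stable           N-first           C-first simultaneous-ends
#>                 8                 0                 0                 0
#>      middle-first       ends-inward
#>                 0                 0
table(classify_pathways(anchorless, threshold = 2.2, margin = 10))
#>
#>            stable           N-first           C-first simultaneous-ends
#>                 4                 2                 1                 1
#>      middle-first       ends-inward
#>                 0                 0
```

The anchored peptide stays bound in every replica (score ≈ 1.16 nm, the
bound-pose probe distance); the anchorless one detaches in half of these 8 replicas (and in three quarters of the 20-replica acceptance runs),
always starting from an end — never from the middle — and its score rises
toward the 3 nm ceiling. Scoring many peptides this way feeds directly into
`auroc()`, `pearson_r()` and `bootstrap_auroc_sd()`:

```r
scores <- c(detachment_score(anchored), detachment_score(anchorless))
auroc(scores, c("binder", "non-binder"))
#> [1] 1
```

Real structures enter through `coarse_grain_structure("file.pdb")`,
`build_pmhc_hierarchy()` (helix ranges and kink positions are config
inputs) and `read_pair_potential()` for a knowledge-based table. A
command-line wrapper with `coarse-grain`, `synth`, `run`, `analyze`, `roc`,
`bootstrap` and `campaign` subcommands is installed at
`system.file("cli/hnmmc", package = "hnmmc")`, and `run_campaign()` drives
the whole threading → replicas → scoring → ROC pipeline from one YAML
config with a manifest and resumability.

See the methods vignette (`vignettes/hnmmc-methods.Rmd`) for the model,
the closure algorithm, all tunable parameters and the design rationale of
the synthetic fixtures.

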