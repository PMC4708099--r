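---
title: "Coarse-grained natural-move Monte Carlo for peptide-MHC detachment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained natural-move Monte Carlo for peptide-MHC detachment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnmmc)
```

## The problem

Peptides presented by class I major histocompatibility complexes (MHC) sit in
a groove formed by two kinked alpha-helices above a beta-sheet floor. Whether
a peptide stays bound determines whether it can be presented to T cells, but
all-atom molecular dynamics cannot reach the timescale of full peptide
detachment. This package trades atomistic detail for sampling power:
a 3-point-per-residue coarse-grained model, collective rigid-body moves on a
hierarchy of structural regions, and repeated simulated annealing. The
trajectories it produces are analysed for *how* and *how fast* peptides leave
the groove, and those detachment statistics are compared against
binder/non-binder labels.

## The coarse-grained model

Every residue is reduced to at most three beads: the alpha-carbon (`CA`), the
carbonyl oxygen (`O`) and the unweighted centroid of the side-chain heavy
atoms (`SC`; glycine has none). "Unweighted centroid" is a deliberate
reading of "centre of the side chain": no mass or volume weighting, every
heavy atom from the Cbeta outward counts equally. All coordinates are in
nanometres internally; PDB Angstroms are converted on read and write.

Energies come from a distance-binned pair potential over bead-type pairs,
in dimensionless units of $k_B T_{\mathrm{ref}}$ with
$T_{\mathrm{ref}} = 300$ K — knowledge-based potentials carry no absolute
energy scale, so the Metropolis rule uses $\beta(T) = T_{\mathrm{ref}}/T$.
Bins are half-open with width 0.05 nm and a 1.5 nm cutoff by default;
intra-residue and sequence-adjacent pairs ($|i-j| \le 2$ within a chain) are
excluded, which is standard coarse-grained practice. Because a coarse
potential cannot represent excluded volume exactly, all pair energies are
damped at short range by

$$s(r) = \begin{cases} s_0 + (1-s_0)\,(r/r_0)^6 & r < r_0 \\ 1 & r \ge r_0
\end{cases}$$

with $s_0 = 0.15$ and $r_0 = 0.7$ nm (about the size of a large amino acid).
The floor $s_0$ keeps short-range minima shallow enough that a small peptide
can escape them; beyond $r_0$ the tabulated potential is untouched. The
published table behind the original 3-point potential is not redistributable,
so tables are pluggable inputs: `read_pair_potential()` loads a user table,
`default_pair_potential()` provides a neutral excluded-volume-plus-weak-
attraction stand-in for exploration, and all science-facing tests use
Go-style tables built by `make_go_potential()` where the ground truth is
known by construction.

## Natural moves and the region hierarchy

Rather than moving atoms individually, the sampler proposes rigid-body
translations and rotations of *regions* — contiguous residue stretches — and
*super-regions* grouping them. The default pMHC decomposition
(`build_pmhc_hierarchy()`) has exactly seven MHC nodes: the beta-sheet floor,
and per helix a whole-helix super-region over two leaf regions split at the
conserved helix kink. The peptide moves as a whole and in three sub-regions
(residues 1-3, 4-6, 7-9 of a 9-mer; the paper-style sub-region boundaries
are configurable since no published split exists). The alpha-3 domain and
beta-2-microglobulin, when present, belong to no region: they contribute to
the energy but never move. Kink positions are config inputs, not constants.

Per node the proposal is symmetric: translation uniform in
$[-t_{\max}, t_{\max}]^3$, rotation axis uniform on the sphere, angle
uniform in $[-\theta_{\max}, \theta_{\max}]$, pivot at the node's CA
centroid. Defaults are $t_{\max} = 0.05$ nm and $\theta_{\max} = 5^\circ$
(the whole-peptide node gets twice both, so the peptide explores faster than
the receptor scaffold); nodes are selected uniformly by default, with
configurable weights. These amplitudes are design choices — no published
values exist — kept small enough that chain closure almost always succeeds.

### Chain closure

A rigid region move breaks the backbone at the region boundaries. Closure is
cyclic-coordinate-descent style: up to three residues flanking each break
rotate about CA-CA virtual bonds, each rotation solved in closed form for
the angle that best restores the broken CA-CA virtual bond to its pre-move
length (tolerance 0.02 nm, at most 30 sweeps, per-axis rotations capped at
1 rad). Rotation axes pass through CA positions, so every other virtual bond
is preserved exactly; O and SC beads ride rigidly with their residues. Two
special cases are handled explicitly:

* a flank of one or two residues running to a chain terminus has no usable
  CCD axis (every candidate axis passes through the bead that must move);
  such flanks close exactly as a rigid hinge rotating about the terminal CA,
  with a rigid translation fallback when the hinge cannot reach. Flanks of
  three or more residues always use CCD — an earlier design that moved whole
  terminal flanks rigidly made the peptide middle artificially mobile, since
  a middle sub-region move simply dragged both ends along;
* a non-converged closure flags the proposal and the sampler auto-rejects
  it. At default amplitudes a few percent of proposals are rejected this
  way; these rejections only reduce the effective mobility of the affected
  node.

### Temperature modulation

The annealing schedule is periodic:
$T(k) = s_T + \tfrac{A}{2}\left(1 + \cos\tfrac{2\pi k}{\Omega}\right)$, with
amplitude $A = 600$ K, period $\Omega = 5000$ steps, shift $s_T = 0$ K and
100 000 steps by default. The published description fixes the amplitude,
period, shift and step count but not the functional form; the cosine form
satisfies every stated constraint (periodic, maximum $s_T + A$, minimum
$s_T$) and is isolated behind `anneal_schedule()` so alternatives can be
swapped in. Each period heats the complex enough to escape minima, then
quenches it into the nearest low-energy state; at $T = 0$ uphill moves are
rejected outright.

The incremental (moved-region-only) energy used in the Metropolis test is
checked against a full recompute every 2000 steps; disagreement beyond
1e-6 relative aborts the run, since it can only mean a delta-energy defect.
Runs are bit-reproducible for a fixed seed (all randomness flows through R's
RNG, also inside the compiled sampler); replica $i$ of `run_replicas()` uses
`base_seed + i`.

## Detachment analytics

Three CA-CA probes track the peptide relative to the binding floor: N
terminus, middle and C terminus (residues 1/5/9 against MHC floor residues
99/28/117 for an HLA-A*02:01-style complex). Distances above 3 nm mean full
detachment and are clamped to 3 nm. Per peptide, the *detachment score* is
the mean clamped probe distance over probes, snapshots and replicas — the
published description says "average distance" without fixing the probe set
or window, so both are options (`probes`, `tail_frac`), with the
all-probes/all-steps default. Larger scores mean faster detachment, so the
non-binder is the positive class in the ROC analysis (Mann-Whitney
formulation, ties counted one half). Affinity correlations use
log10 IC50 by default, the conventional scale for binding assays, with a
500 nM binder threshold when only IC50 values are given.

Pathway classification assigns each replica the probe order in which
detachment starts: a probe's detachment time is the first snapshot where its
clamped distance exceeds a threshold (default 2 nm) and stays above it for a
persistence window (default 10 snapshots). Classes are `stable`, `N-first`,
`C-first`, `simultaneous-ends` (ends within a tie margin, default 5
snapshots) and `middle-first` (middle leading both ends by more than the
margin). The published rules are not exhaustive; where no rule matches, the
earlier end wins, so `middle-first` is only ever produced by a decisive
middle lead. An `ends-inward` level (middle leaving with both ends pinned,
bending inward) exists in the taxonomy for completeness but is not
distinguishable from `middle-first` by threshold times alone and is never
assigned.

The bootstrap replica-count study (`bootstrap_auroc_sd()`) quantifies how
many replicas a reliable binder/non-binder call needs: for each candidate
replica count $n$, peptide scores are re-averaged from $n$ replicas drawn
with replacement, the AROC recomputed, and the standard deviation over $B$
such draws reported.

## The synthetic fixtures, and what they do and do not show

`make_toy_complex()` builds a desk-scale groove: two pleated helix rails and
a pleated floor strip in one receptor chain (connected by short linkers),
walls of fixed beads closing both groove mouths, and a 9-mer peptide bound
in a bent pose whose ends sit about 0.2 nm closer to the floor than its
middle. Three geometry details matter and are deliberate:

* the **pleat** (alternating 0.08 nm offsets of the CA trace) mirrors the
  local curvature of real helices and strands; on perfectly straight chains
  every closure axis passes through the bead the closure must move, and CCD
  has no leverage;
* the **walls** stand in for the closed ends of the class I groove (A and F
  pockets). Without them the peptide escapes by sliding along the groove
  axis, a mode real grooves forbid, and one that reads as middle-first
  threshold crossing because the middle probe starts highest;
* the **bent pose** reproduces the crystallographic geometry that makes the
  middle probe's initial distance the largest of the three.

`make_go_potential()` rewards only contacts present in the initial pose:
receptor-receptor contacts strongly (depth $-8\,k_BT_{\mathrm{ref}}$, keeps
the fold), peptide-receptor SC-SC contacts at the anchor positions deeply
(default $-8$) and elsewhere weakly (default $-0.4$). The depths are
fixture-tuned so that, under the default annealing schedule and 20 000-step
desk-scale runs, a two-anchor peptide stays bound while an anchorless one
detaches — this is constructed ground truth for exercising the contracts,
not a claim about real energetics. With `respect_sequence = TRUE` an anchor
position only counts when the residue there is a preferred anchor residue
(L/M/I at position 2, V/L/I at the C-terminus), which lets threaded peptide
sequences map onto binder/non-binder ground truth. An optional narrow-band
stiffness term on intra-peptide (i, i+3) CA pairs is available (off by
default) to penalise sharp backbone bending.

When classifying pathways on these fixtures the tests use a detachment
threshold of 2.2 nm and a tie margin of 10 snapshots rather than the package
defaults (2.0 nm, 5 snapshots). Both recalibrations follow from the fixture
scale, not from the classifier: transient bound-state excursions of the toy
reach just past 2 nm without detaching, so the threshold must sit above
them, and the middle probe's 0.2 nm geometric head start corresponds to
roughly nine 100-step snapshots at typical escape speeds, so a smaller
margin would read the bent-pose offset, not the release order.

Passing fixture tests show that the sampler, closure, energetics and
analytics compose correctly and reproduce the qualitative anchor phenomenology
(anchored peptides stay; anchorless peptides leave end-first, never
middle-first). They do not show that the package predicts real pMHC binding:
that requires a real structure, a real knowledge-based table and thousands
of long replicas.

`make_synthetic_replicas()` generates the statistical shape of detachment
trajectories directly (binders: baseline plus Gaussian noise; non-binders: a
per-replica-jittered logistic rise to the 3 nm ceiling) for testing the
analysis stack without any sampling. Defaults mirror the study conditions —
100 replicas per peptide, a 200-point snapshot grid standing for a strided
100 000-step run, baselines 1.08/1.31/1.09 nm matching the initial probe
distances, 0.15 nm noise.

## Numerical and design choices

* Bin lookup is half-open, `[k w, (k+1) w)`; a distance exactly at the
  cutoff scores zero.
* Proposals at amplitude zero are exact identities; the proposal
  distribution is symmetric, so Metropolis acceptance alone enforces
  detailed balance at fixed temperature (verified against the analytic
  Boltzmann ratio of a two-well system in the tests).
* `Region` objects are contiguous by contract; internally the beta-floor
  node may span several sequence segments (the floor is the complement of
  the two helices), and closure handles each segment boundary independently.
* Missing side chains in input PDBs fall back to the glycine rule with a
  message; alternate locations resolve to the highest occupancy; insertion
  codes trigger sequential renumbering.
* Threading onto a glycine template position rebuilds the side-chain
  direction from the local backbone (CA versus the midpoint of the flanking
  CAs; CA->O at a terminus).
* Problem sizes in the test-suite: the anchor-contrast experiments run
  20 replicas of 20 000 steps per system; the Boltzmann check runs one
  400 000-step fixed-temperature chain; the bootstrap check uses 12 peptides
  with 100 synthetic replicas and B = 500. These sizes were chosen as the
  smallest at which the corresponding statistical assertions are stable
  across seeds.

## Known limitations

* The annealing functional form and the per-node move amplitudes are
  educated defaults behind configuration, not published values.
* The chain-closure algorithm is a deterministic CCD variant, not the
  original stochastic closure, whose details are unpublished; closure
  failures bias sampling only by rejecting the affected proposals.
* The shipped default potential is a neutral placeholder; quantitative work
  requires a real knowledge-based table in the documented format.
* `run_replicas()` executes serially; replicas are seeded independently so
  the results are identical to any parallel execution order.
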