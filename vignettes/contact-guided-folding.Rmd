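---
title: "Contact-guided coarse-grained folding: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-guided coarse-grained folding: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confold)
```

## The problem

Ab initio protein structure prediction from sequence alone fails for most
targets with complicated topologies, because generic knowledge-based force
fields rarely capture the long-range residue–residue interactions that define
a fold. Sequence-based contact prediction — deep-learning and coevolution
methods that estimate, for each residue pair, the probability that their
C&beta; atoms lie within 8 Å — supplies exactly that missing long-range
information, but predicted maps are noisy, and different predictors fail in
different ways. `confold` implements a complete desk-scale engine for folding
with such noisy maps: consensus selection of contacts from a multi-predictor
ensemble, a smooth three-gradient restraint potential embedded in a
coarse-grained force field, fragment-assembly replica-exchange Monte Carlo
(REMC) sampling, SPICKER-style decoy clustering, and the standard evaluation
metrics (TM-score, C&alpha;-RMSD, contact precision by separation class,
restraint satisfaction). A fixtures module generates every input the pipeline
needs — synthetic folds, calibrated noisy contact ensembles, alignments with
controlled effective depth, and a miniature fragment source library — so the
whole method can be exercised end-to-end, reproducibly, on one CPU.

## Contact selection

Predictors are grouped into four reliability tiers (very high, high, medium,
low), reflecting how such programs rank on large benchmark sets; the default
table routes NeBcon/ResPRE/DeepPLM to "very high" down to
GREMLIN/CCMpred/FreeContact as "low", and unknown predictor identifiers fall
back to "medium". Selection walks the tiers from most to least reliable.
Within a tier all maps are pooled (duplicate pairs keep the maximal
confidence), pairs must clear an alignment-depth-dependent confidence cutoff

$$c_{\min}(t, N_f) = b_t \left(1 + \frac{1}{1 + N_f / 15}\right),$$

with per-tier bases $b_t = (0.15, 0.20, 0.25, 0.30)$, and each tier may
contribute up to its quota of $(1.0, 0.8, 0.4, 0.2) \cdot L$ pairs — more
contacts from more reliable predictors, about $2.4L$ in total. Unused quota
passes down to the next tier. $N_f$ is the effective alignment depth,

$$N_f = \frac{1}{\sqrt{L}} \sum_n \frac{1}{1 + m_n},$$

where $m_n$ counts other rows with &ge;80% identity over mutually aligned
columns; the cutoff roughly doubles as $N_f \to 0$, encoding that
shallow-alignment predictions need much higher confidence to reach ~50%
expected precision. The cutoff bases were calibrated on the package's
calibrated-confidence fixtures so that selected contacts are enriched
relative to the unselected pool. Each selected restraint carries a well depth
$U_{ij} = w_{con} \cdot \text{confidence}$, so the simulation preferentially
satisfies confident contacts.

## The three-gradient restraint potential

Each restraint contributes, as a function of the model's virtual-C&beta;
distance $d$,

$$E_{con}(d) = \begin{cases}
-U_{ij} & d < 8 \\
-\tfrac{1}{2} U_{ij}\left[1 - \sin\!\left(\frac{d - (8+D)/2}{d_b}\pi\right)\right] & 8 \le d < D\\
+\tfrac{1}{2} U_{ij}\left[1 + \sin\!\left(\frac{d - (D+80)/2}{80-D}\pi\right)\right] & D \le d \le 80\\
+U_{ij} & d > 80
\end{cases}$$

with $D = 8 + d_b$. The curve is continuous with zero slope at 8, $D$ and
80 Å: a flat well below the 8 Å contact definition (binary contact
predictions carry no sub-well information), a strong pull from 8 Å to $D$, a
deliberately weak pull from $D$ to 80 Å so that false positives cannot
overpack the chain, and a flat plateau beyond 80 Å. The gradient width $d_b$
is the only free parameter: 6 Å for targets under 100 residues, 12 Å above
200, and a linear bridge in between (the minimal monotone interpolation
between the two published anchor values).

## The coarse-grained force field

The chain is a C&alpha; trace; each residue's virtual C&beta; is placed
1.53 Å from the C&alpha; by tilting the outward bisector of the local
three-residue frame 37.6&deg; out of plane (glycine and chain termini use the
C&alpha; itself). The total energy is

$$E = w_{con} E_{con} + w_{dp} E_{dp} + w_{ca} E_{c\alpha} + w_{ev} E_{ev} + w_{ss} E_{ss} + w_{rg} E_{rg}$$

* $E_{dp}$ — fragment distance-profile term: for profiled pairs,
  $-\log[(h(d)+\varepsilon)/(h_{\max}+\varepsilon)]$ on the 0.5 Å-binned,
  peak-preserving smoothed histogram, zero outside the support and above
  20 Å ($\varepsilon = 10^{-3}$).
* $E_{c\alpha}$ — quadratic penalty $(d-4)^2$ for adjacent C&alpha; pairs
  stretched beyond 4 Å; fragment moves can break the backbone and this term
  heals it. The ramp form is our choice; a smooth ramp behaves well under
  Metropolis sampling.
* $E_{ev}$ — excluded volume, $(3.6-d)^2$ for non-bonded C&alpha; pairs
  closer than 3.6 Å.
* $E_{ss}$ — secondary-structure bias: for confidently predicted helix or
  strand residues whose angle stencil lies entirely in one SSE,
  $(\theta-\theta_0)^2 + (1-\cos(\tau-\tau_0))$ toward ideal pseudo bond
  angles and torsions (helix 91&deg;/50&deg;, strand 123&deg;/&minus;165&deg;;
  these give 1.5 and 3.3 Å rise per residue under a 3.8 Å virtual bond).
  Block-edge residues have no ideal angle (their stencils straddle a loop)
  and carry no bias.
* $E_{rg}$ — a quadratic band holding the radius of gyration within
  &plusmn;15% of $2.2 L^{0.38}$.

Weights default to $(w_{con}, w_{dp}, w_{ca}, w_{ev}, w_{ss}, w_{rg}) =
(1, 3.00, 1, 1, 0.5, 0.2)$. The distance-profile weight 3.00 is the
published operating point that lets fragment statistics veto false-positive
contacts; the remaining weights are generic-term calibrations made on the
package's fixtures. The excluded-volume, SS-bias and gyration terms are
minimal chain physics of our own design — stand-ins for the full inherent
knowledge-based force field of a production fragment-assembly program, which
is far richer (pairwise atomic statistics, solvation, hydrogen bonding, SSE
packing) and out of scope here.

```{r econ-curve, fig.width = 6, fig.height = 3.5}
d <- seq(0, 90, by = 0.1)
plot(d, econ(d, U = 1, d_b = 6), type = "l", xlab = "C-beta distance (A)",
     ylab = "E_con", main = "Three-gradient restraint (U = 1, d_b = 6)")
abline(v = c(8, 14, 80), lty = 3)
```

## Fragments and distance profiles

Fragment libraries are built by gapless threading: every window of every
library structure is scored against every query (position, length) slot,
lengths 1–20, by mean BLOSUM62 substitution score plus a secondary-structure
match fraction (weight 1.0), keeping the top 200 windows per slot. This
substitution+SS score is a deliberately profile-free analogue of
profile-based threading — the synthetic fixtures have no deep alignments to
build profiles from, and their SSE-biased sequence alphabets make the
substitution signal informative. Library structures with more than 30%
global-alignment sequence identity to the query are removed first (strictly
greater than 30%: a structure at exactly the threshold is retained), so the
statistics cannot be contaminated by homologues of the target. Library
secondary structure is assigned geometrically from pseudo bond-angle/torsion
ranges.

Distance profiles are derived from co-sourced fragments: for positions $i$
and $j$ whose top-ranked fragments come from the same source structure with
a consistent register (equal source offset, i.e. one gapless placement
covers both), the source's $d_{ij}$ enters a 0.5 Å histogram. A profile
becomes an energy term only if its modal bin lies below 9 Å, it holds at
least 8 observations, and at least 60% of its mass lies within 1 Å of the
mode. The latter two conditions, and a restriction to sequence separations
&le;23, are desk-scale guards: with a ~30-structure toy library, co-sourced
placements at long range reflect the library folds' global topology rather
than any query-specific signal, and diffuse histograms would only inject
noise. Long-range geometry is therefore left entirely to the contact
restraints — which is the method's point.

## Replica-exchange fragment assembly

Sampling is REMC over a geometric temperature ladder (defaults 0.02–2.5 in
energy units, 8 replicas in the desk preset, 40 at production scale). Each
cycle every replica attempts $\mathrm{round}(30\sqrt{L})$ Metropolis moves,
then adjacent replicas swap configurations with probability
$\min[1, \exp((1/T_k - 1/T_{k+1})(E_k - E_{k+1}))]$, with odd/even pairing
alternating between cycles. The move set has three levels:

* residue level — M1 torsion perturbation, M2 single-residue displacement,
  M3 bond-angle perturbation, M4 reset of a residue to its SS-ideal angles;
* segmental level — M5 fragment substitution (a library fragment is
  superposed onto the window it replaces), M6 crankshaft, M7 rigid segment
  shift, M8 loop re-draw with rigid re-attachment of the downstream chain;
* topology level — M9 terminal-tail hinge rotation (pivots are biased
  toward loop residues, where real hinges live), M10 rigid SSE translation,
  M11 rigid SSE rotation about its own axis.

These definitions are our own: published move sets for fragment-assembly
samplers are described only at this level of granularity, so the package
commits to one concrete, reversible realisation and documents it. Every
accepted move keeps adjacent C&alpha; distances inside [3.4, 4.2] Å —
proposals that would violate the bound are flagged rejections. Move
magnitudes anneal with temperature as $\max(0.35, \sqrt{T/T_{\max}})$ and
level probabilities interpolate from (0.65, 0.30, 0.05)
residue/segmental/topology at the coldest replica to (0.40, 0.35, 0.25) at
the warmest: cold replicas refine, warm replicas restructure. Simulations
start from an extended chain with SS-ideal angles at confidently predicted
positions. Each replica draws from its own deterministic RNG stream derived
from the master seed (splitmix64 into xoshiro256+), so runs are bit-exactly
reproducible and replica-count changes do not shift streams. Energies are
updated incrementally per move — only interactions touching the moved window
are re-evaluated, with the global gyration term recomputed in full — and
refreshed from a complete evaluation once per cycle.

Snapshots are taken from the low-temperature half of the ladder at a fixed
cycle stride, after discarding the first 30% of cycles as equilibration.
Trajectory statistics (for example the rank correlation between cycle and
restraint satisfaction) likewise discard the first 10% of cycles, the
package's standard burn-in convention, because every run — guided or not —
compacts from the extended start during early cycles.

## Model selection

Decoys are clustered by iterative densest-ball clustering on the pairwise
C&alpha;-RMSD matrix: find the decoy with the most neighbours within the
cutoff, form a cluster, remove it, repeat (at most five clusters). The
cutoff auto-scales within [2.5, 8] Å until the largest cluster holds 10–70%
of the decoys. Clusters are ranked by size — the largest cluster is the
lowest-free-energy basin — with ties broken by lower mean energy. Each
cluster's medoid (member minimising summed RMSD to co-members) anchors a
superposition of all members, whose average is the reported centroid model;
averaging cancels the thermal noise of basin members. Final models are
selected from the coldest replica's snapshots; the warmer low-half replicas
remain in the decoy set for trajectory statistics. The production systems
this mirrors refine centroids with all-atom molecular dynamics; here that
stage is a documented no-op hook.

## Evaluation

TM-score uses the standard normalisation $d_0 = 1.24(L-15)^{1/3} - 1.8$
(floored at 0.5 Å) over iteratively refined superpositions seeded from
contiguous windows; scores above 0.5 indicate a correct fold. RMSD is the
least-squares C&alpha; superposition. Contact precision counts a prediction
correct if the native virtual-C&beta; distance is below 8 Å, with separation
classes short 6–11, medium 12–23, long &ge;24 (the community convention).
Satisfaction is the fraction of selected restraints realised below 8 Å in a
model. The test suite cross-checks these implementations against independent
oracles: quaternion (Horn) superposition for RMSD and an exhaustive-seed
TM scorer.

## What the fixtures emulate — and what they do not

`make_toy_structure` builds ideal-geometry folds: SSE blocks with exact
ideal pseudo-angles, packed with alternating direction at type-dependent
spacing (helix–helix 9.5 Å, strand–strand 4.9 Å, mixed 10 Å — chosen so
inter-block C&beta; contacts are realised). Bundles of three or more blocks
close into a regular polygon, so the first and last SSE also pack — a
three-helix bundle has all three interfaces and genuine long-range
contacts — while hairpins and sandwiches stay sequential. Blocks are joined
by equal-bond circular-arc loops that bow away from the packed core; all
bonds are 3.8 ± 0.01 Å and a small seeded tilt/jitter varies each
realisation. `corrupt_contacts` plants
an exact-count composition (precision &times; count true contacts, the rest
non-native pairs drawn from the native separation distribution, so
separation alone cannot identify decoys) with logistically calibrated
confidences: higher confidence means more likely correct, the property the
well-depth design exploits. `make_synthetic_msa` reaches a target effective
depth with mutually dissimilar rows, each contributing $1/\sqrt{L}$ to
$N_f$. `make_mini_library` emulates a non-redundant template library with a
few dozen varied toy folds.

Toy folds are much more regular than real proteins: ideal SSEs, no side
chains, clean contact interfaces, and a native contact density of only about
0.5–0.8 per residue at separations &ge;6 (real globular proteins support the
full 2.4 per-residue selection budget; toy targets cannot, so high-precision
fixtures cap the emitted coverage at what the native map affords). Passing
tests on these fixtures therefore demonstrate the machinery — selection
enrichment, restraint satisfaction dynamics, guided-over-unguided gains,
noise tolerance trends — not production accuracy on real targets, which
additionally depends on the full inherent force field and PDB-scale fragment
libraries. For the same reason the contact maps extracted from desk-scale
models plateau below the accuracy of high-precision inputs: extraction
accuracy is bounded by model quality, and a minimal force field at desk
sampling scale yields models around TM 0.35–0.55 on these fixtures.

## Problem sizes and presets

The desk preset — 8 replicas, 100 cycles, one run per seed, snapshots from
the coldest half at stride 1 — folds a 52-residue bundle in a few seconds
and keeps complete multi-target experiments (for example ten targets across
a four-point precision grid) in the minutes range on one CPU. The paper-scale
preset (40 replicas, 500 cycles, 5 runs, 50 CPU-hour wall-clock cap) is the
published production protocol and is available via
`fold_config("paper")`. The packaged test-suite and acceptance computations
use the desk preset with targets of 28–100 residues and a 30-structure
source library, the package's chosen desk-scale study conditions.

## Numerical choices and degenerate inputs

Histogram bins are 0.5 Å on [0, 40); distances at a bin edge fall into the
upper bin. Ties in consensus ranking break by larger sequence separation,
then lexicographically. Cluster-size ties break by lower mean energy.
Glycine has no C&beta;: the C&alpha; stands in. Collinear triples in the
C&beta; construction and in angle-based moves are detected and left
unperturbed (the move reports a flagged rejection). An ensemble in which no
contact clears its cutoff yields an empty restraint set, and the pipeline
runs unguided — the inherent-terms-only behaviour — flagging the run in its
manifest. A single decoy clusters trivially; an empty fragment library
simply disables fragment moves and profiles.

## Known limitations

The inherent force field is minimal; absolute model quality on real
sequences is far below production fragment-assembly systems. Profiles are
restricted to medium-range separations at desk scale. The TM-score search,
while agreeing with an exhaustive-seed oracle on test decoys, is a heuristic
and can in principle miss the optimal superposition for pathological pairs.
Multi-chain structures, insertion codes and mmCIF input are unsupported.
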