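---
title: "A mass-spring, polar-transport model of sepal positioning in the floral meristem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mass-spring, polar-transport model of sepal positioning in the floral meristem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meristemsim)
```

## The system being modelled

A stage-2 *Arabidopsis* floral meristem initiates sepal primordia where
auxin concentrates. In the wild type four maxima appear at even angular
spacing; under elevated auxin-production noise (the *drmy1* condition) the
number and placement of maxima become variable, and this variability
requires the boundary factor CUC1, whose only modelled action is to make
PIN1 repolarisation more sensitive to auxin differences between neighbours.
`meristemsim` implements the meristem as a flat disk of polygonal cells that
grows, divides, and runs an auxin–CUC1–PIN1 circuit, together with the
statistics used to score robustness of the resulting pattern.

## Model structure

### Mechanics

Cell walls are subdivided into segments of at most 1 µm, each a linear
spring. The force on vertex $v$ from its spring neighbours $N_v$ is

$$\mathbf{F}_v = \sum_{n \in N_v} k\left(\frac{\lVert \mathbf{p}_n -
\mathbf{p}_v\rVert}{L_{v:n}} - 1\right)\frac{\mathbf{p}_n -
\mathbf{p}_v}{\lVert \mathbf{p}_n - \mathbf{p}_v \rVert},$$

with $L_{v:n}$ the rest length. Uniform turgor pressure is applied as a
normal force on boundary walls only (it cancels on interior walls): each
boundary wall contributes $P \cdot \text{length}/2$ to each endpoint along
its outward normal, which is exactly $P$ times the gradient of the enclosed
area. Equilibration integrates the overdamped dynamics with backward-Euler
steps; each step solves the linearised implicit system with
Jacobi-preconditioned conjugate gradients. Growth then extends rest lengths
from their stretch, $dL/dt = g\,(\lVert\mathbf{p}_n - \mathbf{p}_v\rVert -
L)/L$, once per iteration; compressed springs shrink, as the law reads.

### Chemistry

Each cell $i$ carries auxin $\mathrm{aux}_i$ and CUC1 $\mathrm{cuc}_i$; each
wall side carries a PIN1 allocation. Per chemical substep, concomitantly:

* PIN toward neighbour $j$ relaxes at speed $\alpha = 0.01$ toward the
  up-the-gradient target $\mathrm{aux}_j^{\,n} L_j / \sum_k
  \mathrm{aux}_k^{\,n} L_k$, where $n = 1$ if $\mathrm{cuc}_i <
  \mathrm{cuc_{thres}} = 2$ and $n = 2$ otherwise. Allocations start
  length-proportional (apolar), sum to 1 per cell, and never face the
  boundary (zero-flux).
* Auxin: $d\,\mathrm{aux}_i/dt = \mathrm{Prod_{aux}}\,\delta_i -
  \mathrm{Dec_{aux}}\,\mathrm{aux}_i + \mathrm{Tran_{aux}} \sum_j
  (\mathrm{aux}_j\,\mathrm{pin}_{j\to i} - \mathrm{aux}_i\,
  \mathrm{pin}_{i\to j})/\mathrm{Area}_i$ with
  $\mathrm{Prod_{aux}} = 1$, $\mathrm{Dec_{aux}} = 0.2$,
  $\mathrm{Tran_{aux}} = 400$.
* CUC1: $d\,\mathrm{cuc}_i/dt = \mathrm{Prod_{cuc}}/(1 +
  (\mathrm{aux}_i/K_{\mathrm{aux}})^{\mathrm{hill}}) -
  \mathrm{Dec_{cuc}}\,\mathrm{cuc}_i$ with $K_{\mathrm{aux}} = 5$,
  $\mathrm{hill} = 4$, $\mathrm{Dec_{cuc}} = 0.2$.

The noise multipliers $\delta_i \sim N(1, \mathrm{SD_{aux}})$ (negatives set
to 0) are redrawn each iteration in ascending cell order, or drawn once at
initialisation under the frozen-noise variant. Genotypes:
$\mathrm{SD_{aux}} = 0.1$ for WT and *cuc1*, $1$ for *drmy1* and *drmy1
cuc1*; $\mathrm{Prod_{cuc}} = 1$ for WT and *drmy1*, $0$ for the *cuc1*
backgrounds.

### Iteration protocol

Each iteration runs, in order: (1) relaxation to mechanical equilibrium;
(2) dilution of auxin and CUC1 by the relaxation-induced area changes
(amounts conserved); (3) noise redraw; (4) ten chemical substeps;
(5) a division pass over all cells above 50 µm²; (6) subdivision of walls
longer than 1 µm (rest lengths and PIN apportioned by length);
(7) rest-length growth; (8) reinitialisation of cached adjacency structures;
(9) data output. Snapshots are kept every 10 iterations by default.

### Division rule

A dividing cell is cut along one of 180 candidate planes (1° spacing)
through its centroid, choosing the shortest wall. Three noise terms perturb
the rule, all with default SD 2 µm: the centroid is displaced isotropically
(rejected if it leaves the cell), each candidate's length score is
perturbed before taking the minimum, and each junction is displaced along
its intersected wall (clamped inside it). These are this package's
operationalisation of "cell centre / cell division / wall junction" noise;
the original implementation's exact semantics are not published, so they are
documented as an interpretation rather than asserted as identical.
Candidate planes whose line crosses the cell boundary more than twice
(possible when a plane runs nearly parallel to a chain of collinear wall
segments) are rejected as geometrically degenerate, as are planes that would
cut off a daughter below 20% of the parent's area: such slivers do not occur
in real tissue and their near-zero areas would violate the stability bound
of the explicit transport integration (see below). If the jittered junctions
still realise a degenerate cut (below 5% of the parent), the division is
skipped and retried at the next iteration. Daughters inherit `aux`, `cuc` and `delta`
unchanged; severed walls apportion PIN proportionally to length; the new
wall starts with an infinitesimal PIN (10⁻⁶) on each side followed by
per-cell renormalisation, keeping every cell's total PIN at exactly 1.

## Parameters, units and defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k` | 1 | force/strain | spring stiffness (sets the force scale) |
| `P` | 1e-3 | force/µm | turgor pressure on boundary walls |
| `g` | 0.8 | µm/iteration per unit strain | wall extensibility (0.4 low, 1.2 high) |
| `division_area_thres` | 50 | µm² | division threshold |
| `max_wall_len` | 1 | µm | wall segment length cap |
| `alpha` | 0.01 | per substep | PIN repolarisation speed |
| `cuc_thres` | 2 | a.u. | CUC1 level switching the PIN exponent to 2 |
| `prod_aux`, `dec_aux`, `tran_aux` | 1, 0.2, 400 | a.u./time, 1/time, µm²/time | auxin kinetics |
| `prod_cuc`, `dec_cuc`, `k_aux`, `hill` | 1, 0.2, 5, 4 | — | CUC1 kinetics |
| `sd_aux` | 0.1 / 1 | — | production-noise SD (genotype preset) |
| `dt_chem`, `n_substeps` | 0.01, 10 | time, — | chemical substepping |

Auxin and CUC1 are in arbitrary units; no calibration to reporter intensity
is attempted.

## Numerical choices

* **Turgor calibration.** The force scale is nondimensionalised (`k = 1`);
  only geometry and growth matter for patterning. `P` was calibrated once on
  the packaged disk so that the equilibrium boundary strain is ≈ 1%,
  which with the growth law gives a roughly four-fold area expansion and
  one to two rounds of division over a reference 100-iteration run at
  g = 0.8 — the few-fold expansion a stage-2 bud undergoes. Strains of
  several percent would compound to unbounded exponential growth over 100
  iterations and were rejected on those grounds.
* **Relaxation.** Backward-Euler steps with a large implicit step
  (`euler_dt = 500`, damping 1) behave like damped Newton iterations near the
  quasi-static equilibrium; small steps (≲ 0.1) need hundreds of iterations
  to reach the same residual. The linear systems are solved by conjugate
  gradients with a 2×2 block-Jacobi preconditioner to a relative residual of
  10⁻⁵ (capped at 30 iterations per step); the transverse (rotational) curvature of compressed springs is
  clamped at zero so the implicit matrix stays positive definite. Steps are
  accepted only if the global force 2-norm does not increase (with
  backtracking), and convergence is declared when the maximum per-vertex
  force norm drops below `relax_tol` (default 10⁻⁴ k, a tenth of the typical
  boundary wall load P·len ≈ 10⁻³ k — loose enough for speed, tight enough
  that the quasi-static geometry drives dilution and growth consistently). The post-condition — equilibrium within
  tolerance — is the contract; the solver internals are not.
* **Chemistry stability.** Explicit Euler with `dt_chem = 0.01` keeps
  `dt · Tran_aux / (2 · Area)` well below 1 for all admissible cell areas
  (the division rule's 20% floor guarantees daughters ≳ 10 µm², bound
  0.05). Concentrations are clamped at 0 after each substep; explicit Euler
  can undershoot and negative concentrations would corrupt the PIN weights.
* **Ties and degeneracies.** `cuc = cuc_thres` takes the high branch
  (n = 2) so the rule is deterministic. If every neighbour of a cell has
  zero auxin, the PIN target falls back to the length-proportional (apolar)
  form, which keeps normalisation exact and reproduces the initial state.
  A cell too degenerate to bisect skips division with a warning record.
* **Reproducibility.** A run is fully determined by `(config, seed)`: one
  seeded generator drives noise draws (ascending cell order) and division
  noise (ascending cell order within the division pass).

## The packaged initial tissue

The simulation starts from a shipped disk of exactly 73 cells and 348 wall
segments (hence 276 vertices), radius 24 µm, mean cell area ≈ 25 µm², built
by `build_disk()`: a central cell surrounded by concentric rings of
annular-sector cells with seeded angular jitter, refined by splitting the
longest walls until the wall count is exact, and frozen as a fixture so the
counts are reproducible. Rest lengths equal current lengths; auxin and CUC1
are zero; PIN is apolar.

## What the in-silico experiments emulate

The ensemble runners reproduce, at reduced ensemble size, the model
experiments on developmental robustness: per-genotype ensembles at growth
rate 0.8 scored at iteration 100 by maxima count, mean per-maximum auxin and
angular CV; a growth-rate sweep for *drmy1* in which buds are compared at
similar size (iterations 210, 105 and 72 for g = 0.4, 0.8 and 1.2, each about
a four-fold area expansion), since at a fixed iteration faster-growing buds
are simply larger and carry more maxima; and the frozen-noise control in
which the production noise is drawn once and never redrawn, removing
temporal averaging. The acceptance tests use 80 runs per genotype (25 for
the frozen-noise control and 12 per growth rate) so the whole suite stays
within a desktop-scale budget; `run_ensemble()` takes any `n_runs` for
larger studies.

One caveat this package's own ensembles make explicit: with ten substeps of
`dt_chem = 0.01`, one iteration advances chemical time by only 2% of the
auxin decay timescale, so per-iteration noise redraws are strongly averaged
before they imprint on auxin. The production-noise contrast between
genotypes therefore shows up clearly in maxima intensity and in the
WT-versus-*drmy1* count dispersion, while the rescue of count dispersion by
CUC1 removal is weaker here than in vivo; the frozen-noise variant, which
removes the averaging entirely, markedly raises count dispersion, consistent
with this reading. Raising the substep size is not an option under the
explicit scheme: the transport stability bound at the smallest realised cell
areas (~3 µm²) is dt ≈ 0.015.

The simulated disk is flat, isotropic and unbounded by neighbouring organs.
Passing tests therefore show that the implemented circuit reproduces the
direction of the noise-amplification, CUC1-rescue and growth-rate effects in
this idealised geometry — not that the model quantitatively matches real
buds, which are curved, mechanically anisotropic, and measured through
reporter intensities with their own noise.

## Known limitations

* 2D only; no shell curvature, no wall-stiffness anisotropy, no
  viscoelasticity.
* Auxin moves only by PIN-directed transport (no diffusion term), as in the
  modelled circuit.
* CUC2/CUC3 and the miR164 pathway are not represented beyond the
  `prod_cuc` switch.
* The division-noise semantics are an interpretation (see above); the
  magnitudes match the stated SDs but not necessarily the original
  implementation's geometry.
* Concentrations are per-cell; no subcellular PIN localisation beyond the
  per-wall-side allocation.
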