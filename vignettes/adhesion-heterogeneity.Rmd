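---
title: "Modelling glioblastoma spheroid invasion with heterogeneous cell-to-cell adhesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glioblastoma spheroid invasion with heterogeneous cell-to-cell adhesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(gliomorph)
library(ggplot2)
```

## The model

`gliomorph` is a hybrid discrete-continuum, individual-cell-based simulator of
glioblastoma spheroid invasion. Tumour cells are discrete agents on a 2D
exclusion lattice (one cell per site) representing a planar slice through a
3D spheroid embedded in an ECM-like matrix; oxygen is a continuous field on
the same lattice. The central hypothesis the model encodes is that
*intratumoural heterogeneity in cell-to-cell adhesion preference alone* is
enough to produce the two qualitatively different invasion patterns seen in
3D spheroid assays: the non-cohesive "starburst" dispersal of U87MG cells and
the cohesive, sheet-like collective invasion of patient-derived primary
cells.

Each cell carries one integer trait, its **adhesion preference** $a \in
\{0,\dots,7\}$: the number of occupied Moore neighbours the cell requires at
a destination site before it will move there. Preference-0 cells seek empty
surroundings and disperse as single cells; preference-7 cells only accept the
densest neighbourhoods and stay aggregated. Preferences 0--1 are called *low*
adhesive, 2--5 *middle*, 6--7 *high* (`phenotype_category()`). All other cell
properties (division age, oxygen consumption, death threshold) are shared,
so every morphological difference between scenarios traces back to the
adhesion mixture.

Three processes run on an asynchronous clock with update interval
$t_r = 0.8$ h; within a macro-step, cells are visited in a fresh uniform
random permutation for the movement pass and again for the lifecycle pass, so
no cell has a persistent priority:

1. **Movement.** Cell motion derives from the diffusion equation
   $\partial c/\partial t = D_c \nabla^2 c$. The 5-point discretisation turns
   $D_c$ into a per-substep move probability $p = 4 D_c k / h^2$, with the
   substep $k$ chosen as the largest divisor of $t_r$ not exceeding
   $h^2/(4 D_c)$ so that $p \le 1$ (`move_kernel()`). Adhesion gates each
   attempt: a move is only taken onto an *empty* Moore neighbour whose
   occupied-neighbour count, excluding the mover, equals the cell's
   preference.
2. **Oxygen.** The field obeys
   $\partial o/\partial t = D_o \nabla^2 o - \gamma_o\, o\, c_{ij} -
   \alpha_o o$ with Dirichlet boundaries held at $o_{max}$ (the culture
   medium). Live cells consume; dead cells are empty space.
3. **Lifecycle.** A cell below its division age $T_p$ ages by $t_r$. At or
   past it, it searches the Moore neighbourhood of radius 2 (24 sites) for
   empty space: none means quiescence (with the age clock frozen; the cell
   re-checks every pass and divides immediately once space appears);
   otherwise a daughter is placed uniformly on an empty site and both cells
   restart at age 0. With probability $p_{mut}$ a division also resamples the
   phenotype uniformly from the allowed set and assigns it to *both*
   daughters. After the division pass, every cell sitting where
   $o < o_{deadly}$ dies and frees its site.

A run starts from a completely filled disc of cells at the domain centre and
ends at the time horizon (9 days) or as soon as any cell comes within 5 sites
of the lattice border.

## Scenarios and parameters

| parameter | default | units | meaning |
|---|---|---|---|
| $L$ | 5 | mm | domain side (250 sites) |
| $h$ | 20 | µm | site size = cell diameter |
| $t_r$ | 0.8 | h | asynchronous update interval |
| $T_p$ | 31 (U87MG), 25 (primary) | h | division age, from doubling-time assays |
| initial radius | 140 (U87MG), 200 (primary) | µm | seeded disc |
| $D_c$ two-phase | $1.5\times10^{-8}$ then $3\times10^{-9}$ (U87MG); $4\times10^{-10}$ then $4\times10^{-8}$ (primary) | cm²/s | motility before/after 24 h |
| phenotypes | \{0,1,6,7\} (U87MG), \{2..7\} (primary) | — | adhesion mixture |
| $p_{mut}$ | 0 (0.5 in switch studies) | — | mitotic switch probability |
| $D_o$ | $10^{-5}$ | cm²/s | oxygen diffusion |
| $\alpha_o$ | 0 | 1/s | background decay |
| $\gamma_o$ | 0.012 | 1/s | per-cell consumption (calibrated, below) |
| $o_{deadly}$ | 0.1 $o_{max}$ | — | hypoxic death threshold |

`config_u87mg()` and `config_primary()` bundle these. The U87MG mixture pairs
low-adhesive cells (the migrating halo) with high-adhesive ones (the immotile
maternal core); the primary mixture spans middle-to-high adhesion and
produces a connected mass with protrusions whose tips are enriched in the
least adhesive types present.

### Choices the problem left open

* **Initial mixture proportions.** Uniform over the scenario's phenotype
  set. Nothing in the doubling-time or imaging data pins the proportions; a
  uniform prior adds no structure beyond the hypothesis under test. It is a
  config field (`mixture`) for sensitivity analyses.
* **Initial ages.** Uniform on $[0, T_p)$ per cell, which avoids synchronised
  division waves that a common age would cause.
* **Daughter placement.** Uniform over *all* empty sites within radius 2
  (not just the outer ring) — the simplest unbiased reading.
* **Quiescent age.** Frozen while quiescent; both cells reset to 0 on
  division. Readiness to divide is a state, not an accumulating debt.

## The movement rule

Two readings of "a cell only moves to empty adjacent locations with
neighbours equal to its adhesion preference" are implemented
(`move_rule` in `sim_config()`):

* **proposal** (default): each attempt proposes one of the 8 Moore directions
  uniformly — per-direction rate $p/8$, which is the flux the diffusion
  discretisation assigns — and the move is vetoed if the proposed site is
  occupied or fails the preference test.
* **renormalised**: each attempt relocates with the full probability $p$
  uniformly onto whatever admissible destinations exist.

For a free cell the two laws are identical (every neighbour is admissible for
preference 0), and both satisfy the exact free-walker second moment
$\mathbb{E}[d^2] = n_{sub} \cdot 1.5\, p\, h^2$ per macro-step — the factor
1.5 is the diagonal inflation of uniform Moore steps, making the realised
diffusivity $1.5\,D_c$. They differ at constrained sites: renormalisation
concentrates the entire attempt probability onto however few admissible sites
remain, which inflates mobility at the spheroid rim far beyond the
diffusion-derived rate. In practice that extra rim flux ejects so many cells
that U87MG simulations reach the domain edge within two to five days; under
the proposal rule most reach the four-day mark and beyond, matching the
nine-day experimental design. The proposal rule is therefore the default;
conditioned on a move happening, both rules select uniformly among the
admissible destinations, so the schematic three-way choice of a
preference-0 cell next to a wall behaves identically under either.

## Oxygen numerics

`oxygen_advance()` integrates the field with the explicit 5-point scheme,
substep $\min(t_r,\ 0.9\,h^2/(4 D_o))$ (plus a positivity bound on the
reaction term), which guarantees the discrete maximum principle — the field
stays in $[0, o_{max}]$, and adding a consumer can only lower it. At
$D_o = 10^{-5}$ cm²/s and $h = 20$ µm this substep is ~0.09 s, i.e. tens of
thousands of 250×250 sweeps per macro-step — accurate but far too slow to
carry a replicate ensemble.

The engine therefore exploits a timescale separation: the field relaxes over
the tumour in $r^2/D_o \approx$ minutes, while occupancy changes on the
$t_r = 0.8$ h clock. Its default update (`oxygen_solver = "steady"`) relaxes
the field to the quasi-steady state $D_o \nabla^2 o = (\gamma_o c +
\alpha_o) o$ once per macro-step, warm-started from the previous field, using
a geometric multigrid V-cycle (red-black Gauss–Seidel smoothing,
cell-centred coarsening; plain SOR on small grids). The relaxation solver is
validated in the tests against a direct sparse solve of the discrete system
and against the 1D $\cosh(x/\ell)/\cosh(X/\ell)$ closed form with
$\ell = \sqrt{D_o/\alpha_o}$; the fully explicit transient solver remains
available (`oxygen_solver = "transient"`).

### Calibrating $\gamma_o$

With $o$ normalised ($o_{max} = 1$, $\alpha_o = 0$, $o_{deadly} = 0.1$), the
per-cell consumption rate is the one free oxygen parameter. It is pinned to a
single observable: in the primary scenario (single-phase
$D_c = 2\times10^{-8}$ cm²/s, $T_p = 25$ h), necrotic cells should first
appear near 150 h, when the growing mass becomes large and dense enough to
starve its centre. A coarse-to-fine scan of the ensemble-median first-death
time across replicate seeds gave ~161 h at $\gamma_o = 0.011$ /s, ~148 h at
0.012 and ~140 h at 0.013; the default is frozen at **0.012 /s**. The
first-death time is insensitive to the replicate seed (a few hours of spread)
because it is governed by the deterministic bulk growth of the core.

## Morphometrics

All metrics mirror image-analysis quantities and use the *initial-disc
centre* (not the evolving centroid) so asymmetric invasion cannot shift the
reference point:

* `invasive_radius()` — maximum centre distance over live cells: the radius
  enclosing all invasive cells.
* `core_radius()` — maximum centre distance within the 8-connected component
  containing the centre-most cell: the maternal spheroid. For the primary
  morphology core and invasive area cannot be separated (the phenotypes stay
  spatially mixed and connected), so the metric is reported as missing and
  analyses use the invasive radius only.
* `compactness()` — mean occupied Moore-neighbour fraction (count/8) over
  live cells, in $[0,1]$.
* `sparseness()` — mean nearest-other-cell distance in units of $h$
  ($1$ = perfectly packed).
* `expansion_speed()` — OLS slope of a radius metric against time on a
  window, fitted to the ensemble-mean series.

The exact compactness/sparseness formulas used alongside the original assay
are not public; these are deliberately simple local-density and
nearest-neighbour statistics whose *directions* under perturbations are the
quantity of interest, and the tests treat them that way. Phantom generators
(`phantom_disc()`, `phantom_starburst()`, `phantom_sprouted()`) construct
grids with known radii, connectivity and ground-truth metrics so the
morphometrics layer is validated independently of the simulator.

## What the simulator does and does not emulate

The synthetic tumours reproduce: the starburst-versus-cohesive dichotomy from
adhesion mixtures alone; phenotype sorting (low-adhesive cells in the halo,
high-adhesive in the core, tips of primary sprouts enriched in the least
adhesive types present); quiescence-limited growth; central necrosis on a
calibrated clock; and frequency flattening under mitotic switching.

They do not emulate: the third spatial dimension (a 2D slice both
underestimates available escape routes and overestimates crowding); ECM
degradation, remodelling or haptotaxis (the matrix is a passive homogeneous
scaffold); microenvironment-regulated (non-mitotic) phenotype switching; or
sub-cellular mechanics. One quantitative limitation is documented rather than
patched: with the stated motility coefficients, the *maximum-distance*
statistic over all escaped low-adhesion walkers grows faster in the first
24 h than the in vitro front-speed estimate, because every escapee performs an
independent $1.5\,D_{c1}$ random walk and the maximum over tens of walkers
outruns the root-mean-square displacement that the in vitro estimate tracks.
Passing morphology tests therefore support the *qualitative* invasion
patterns and directional trends, not a quantitative match of the early
dispersal speed.

## A small worked example

```{r example, eval = FALSE}
cfg <- config_u87mg(two_phase = TRUE)
run <- sim_run(cfg, seed = 1)
plot_spheroid(run$state)          # blue halo, red core
autoplot(run)                     # metric time courses

ens <- sim_replicates(cfg, n = 20, seed = 1)
expansion_speed(ens, window = c(24, 96))   # um/h, ensemble-mean OLS slope
```

Problem sizes used throughout the test-suite: unit tests run on 21--101-site
lattices with tens to hundreds of cells; the full-scale checks use the
complete 250-site domain with 20-replicate ensembles for the expansion
speeds and 10 for the necrosis onset, and paired 10-replicate ensembles for
the perturbation trends. `scripts/acceptance.R` re-runs the full-scale
studies from a single seed and writes the four headline numbers (three
expansion speeds and the necrosis onset median) as JSON.
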