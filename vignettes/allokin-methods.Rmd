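---
title: "Methods: rare-event detection, kinetic modelling and allosteric coordination in allokin"
author: "allokin maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-event detection, kinetic modelling and allosteric coordination in allokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

`allokin` packages three complementary ways of interrogating a protein
(plus ligand) molecular-dynamics trajectory: *when* does something rare
and interesting happen (rare-event detection on contact maps), *how*
does the system move between its metastable states (tICA, Markov state
models, transition path theory), and *which parts of the structure talk
to each other* while it happens (Gaussian configurational-entropy
measures of coordination). This vignette explains each model, its
assumptions, the tunable parameters, and the choices made where the
method definitions leave latitude. Every empirical statement below is
one the test suite or `scripts/acceptance.R` actually computes.

## 1. Contact time series and rare-event detection

### The model

Each trajectory frame is reduced to a binary residue–residue contact
vector: pair $(i,j)$ is in contact when any atom of residue $i$ is
within a cutoff (default 3.5 Å, heavy atoms only) of any atom of
residue $j$. Stacking frames gives the matrix $I$ (frames × pairs).
Pairs that never change state over the whole series carry no dynamic
information and are removed; the remainder is smoothed with a sliding
mean (default 25 frames) so that a brief flicker does not register as
a state change, and independent replicas are concatenated along the
time axis so that the decomposition is driven by features shared
across replicas rather than by single-replica noise.

The smoothed matrix is factorized by non-negative matrix factorization
into $I \approx W H$ with $W \ge 0$ (frames × $c$, "temporal"
weights) and $H \ge 0$ ($c$ × pairs, "spatial" components). Each
spatial row is a contact pattern — a conformational archetype — and
the corresponding temporal column says when that archetype dominates.
A rare event appears as a change of the dominant component.

### Normalization and SDCPs

NMF fixes $WH$ but not the scale split between $W$ and $H$. Two
conventions are applied. At fit time each component is rescaled so its
temporal weights peak at 1, making spatial values comparable to
contact occupancies. Then, *constitutive pairs* — pairs contributing
a similar, high weight to every component (coefficient of variation
across components below `cvMax = 0.15`, mean above `meanMin = 0.5`) —
define a per-component normalization factor (their mean spatial
value); the spatial row is divided by it and the temporal column
multiplied by it, so the reconstruction is untouched (verified to
1e-10) while constitutive pairs sit at exactly 1 in every component.
Normalized spatial values are *not* bounded by 1: a pair can
contribute more than the constitutive baseline.

Subtracting the spatial rows of two components cancels the
constitutive baseline; the pairs whose difference exceeds
`kSigma = 4` plain (non-robust) standard deviations of the difference
array are the *structure-differentiating contact pairs* (SDCPs),
labelled "formed" (positive) or "broken" (negative) for the
from→to transition. The plain standard deviation is used because the
threshold is defined in terms of it; note the consequence that a
4σ threshold is only meaningful when the difference array is
dominated by near-zero pairs — with a handful of retained pairs the
σ estimate is inflated by the switching pairs themselves, and a lower
threshold is appropriate (the unit tests on miniature fixtures use
0.5σ for exactly this reason; the study-scale fixture with ~190
dynamic pairs uses the 4σ default).

### Numerical choices

* NMF is minimized by hierarchical alternating least squares (HALS)
  from a deterministic non-negative double-SVD (NNDSVD, average
  variant) start; a seeded random start is available. HALS was chosen
  over multiplicative updates because it reaches the 1e-6 relative
  reconstruction error of exactly factorizable inputs in hundreds of
  sweeps rather than many thousands.
* Convergence: relative change of the Frobenius error below `tol`
  (default 1e-8); non-convergence is a warning with the final error,
  not a failure. A projected-ALS polish runs after the main loop and
  keeps the best iterate, so it can only improve the fit.
* When `c = 2` and the input is numerically rank 2 (third singular
  value below 1e-10 of the first), the factorization is constructed
  in closed form from the extreme rays of the two-dimensional column
  cone — a rank-2 non-negative matrix always has non-negative rank 2 —
  and reaches machine precision immediately. This matters because the
  tail convergence of first-order NMF solvers (HALS here, coordinate
  descent elsewhere) on dense exactly-factorizable inputs can be very
  slow; for ranks above 2 no closed form exists and the iterative
  path is used throughout.
* Component matching across runs (for reproducibility checks) is by
  greedy cosine similarity of spatial rows.
* Hydrogens are excluded from contacts by default ("any atom" is
  ambiguous; heavy-atom contacts are stabler), restorable with
  `heavyOnly = FALSE`. Sequence-adjacent pairs are retained —
  invariance trimming removes the permanently fused ones anyway.
* Smoothing truncates the window at series edges and at replica
  boundaries rather than padding, so replicas are never averaged
  together.
* Distances are computed by the exact double loop over atom pairs at
  every problem size. A neighbour-list scheme was considered for very
  large systems and deliberately not built: at the sizes this package
  targets (hundreds of atoms in validation work, a few thousand in a
  single-protein trajectory) the exact loop is already cheap, and one
  code path means one set of numbers.

## 2. Collective variables and binding modes

Distance CVs are mass-weighted center-of-mass distances between
selections. The *cavity coordinate* is a scalar ligand-position
coordinate: the complex is rotated so the gate helix's long axis (first
principal axis of the helix selection) lies along $x$, oriented from
the first to the last helix atom to fix the sign, with the protein
center of mass placed directly above the helix center of mass
(positive $z$, zero $y$); the origin is the serine-site center of mass
and the coordinate is the probe displacement projected on
$(\hat{x}+\hat{z})/\sqrt{2}$. "Directly above" is interpreted as: the
component of (protein COM − helix COM) perpendicular to the helix axis
defines $+\hat z$. All CVs are invariant under global rotation and
translation of the input (checked to 1e-8).

Binding modes are classified from two distance channels: `SER` when
the probe-to-Ser-site distance is below `dSite` (default 6 Å, wide
enough to absorb water-bridged variants of a mode) and smaller than
the probe-to-Trp-site distance, `TRP` symmetrically, `OTHER`
otherwise. Explicit water-bridge or hydrogen-bond geometry is out of
scope. Contact probability between two residues is simply the
percentage of (optionally mode-conditioned) frames with any atom pair
below the cutoff.

## 3. tICA

Mean-centered CV data give the instantaneous covariance $C(0)$ and the
lag-$\tau$ covariance $C(\tau)$ (default lag 25 frames), accumulated
per replica segment — lagged pairs never span a boundary — and pooled.
The generalized eigenproblem $C(\tau)v = \lambda C(0)v$ is solved
through a Cholesky transform of $C(0)$. Choices the method definition
leaves open:

* $C(\tau)$ is symmetrized as $(C+C^\top)/2$ before solving, which
  guarantees a real spectrum.
* $C(0)$ receives a ridge $\varepsilon = 10^{-10}\,\mathrm{tr}(C(0))/d$
  to guard near-singular CV sets.
* Eigenvector sign is fixed by making the largest-magnitude loading
  positive; eigenvectors are normalized to $V^\top C(0) V = I$.
* "Kinetic content" of the first $k$ components is defined here as
  $\sum_{i\le k}\max(\lambda_i,0)/\sum_i\max(\lambda_i,0)$ — the
  positive-eigenvalue fraction. Other normalizations exist in the
  literature; this one is documented and used consistently, and the
  package does not claim to reproduce any particular published
  percentage with it.
* Implied timescale of component $i$: $t_i = -\tau/\ln\lambda_i$.
  Note that measurement noise on a slow CV attenuates its lagged
  autocorrelation and biases $t$ low; the validation fixtures
  therefore keep emission noise on the slow channel small.

## 4. Markov state models

Projected frames are clustered by k-means (Lloyd) from a seeded
k-means++ start — the only stochastic step in the kinetic pipeline,
reproducible by seed. Transition counts at lag $\tau'$ use the
sliding window (every frame pair $t, t+\tau'$ within a segment),
which maximizes data use. The count matrix is trimmed to its largest
connected set (dropped states are warned about), symmetrized as
$(C+C^\top)/2$ to enforce detailed balance, and row-normalized; the
stationary distribution is proportional to the symmetrized row sums,
so $\pi_i T_{ij} = \pi_j T_{ji}$ holds exactly and the spectrum is
real in $[-1, 1]$.

* Implied timescales $t_i = -\tau'/\ln\lambda_i$ are reported per lag;
  flatness in the lag diagnoses Markovianity. Non-positive eigenvalues
  give NaN with a warning; eigenvalues at 1 give Inf (disconnection).
* GMRQ cross-validation: $R =
  \mathrm{Tr}[(V^\top S T V)(V^\top S V)^{-1}]$ with $V$ the first $n$
  right eigenvectors of the training TPM, $T$ the test TPM and $S$ the
  diagonal matrix of test-set stationary populations (the Perron
  eigenvector, normalized to sum 1). With train = test the score equals
  the sum of the top-$n$ eigenvalues to machine precision.
* PCCA+ macrostates come from the inner-simplex construction on the
  first $m$ right eigenvectors: the most distant microstate rows are
  taken as simplex vertices, memberships are the barycentric
  coordinates, tiny negative memberships (weakly metastable states)
  are clipped and rows renormalized. Rows sum to 1 exactly; the crisp
  map is the argmax. The macro-level transition matrix is the
  $\pi$-weighted coarse-graining over the crisp partition.

## 5. Transition path theory

For disjoint source and target sets, the forward committor solves the
harmonic system $q_i = \sum_j T_{ij} q_j$ on intermediates with
$q=0$ (source) and $q=1$ (target), by direct linear solve. The
reactive flux is
$J_{ij} = \pi_i (1-q_i)\, T_{ij}\, q_j$ — the backward factor
$(1-q_i)$ is the committor toward the source for reversible $T$, an
identity the tests verify independently. The net flux is
$J^+ = \max(0, J - J^\top)$ and the total flux is the net flux out of
the source set, which equals the net flux into the target set
(conservation, checked to 1e-12).

Pathways are extracted from the *net* flux (a gross-flux mode is
available behind a flag) by iterated widest-path search: a
Dijkstra-type sweep maximizing the minimum edge weight finds the
highest-bottleneck path; the path is recorded with its bottleneck
flux, that flux is subtracted along the path, and the loop repeats to
a coverage fraction (default 0.95) or a path-count cap. Ties between
equal-bottleneck paths break toward the lowest state index, making
the decomposition deterministic and invariant (up to relabeling)
under state permutations. The reported table mirrors the standard
presentation: path, normalized flux, cumulative normalized flux.

## 6. Coordination analysis (configurational-entropy measures)

After least-squares superposition of every frame onto a reference
structure (closed-form SVD rotation, reflections forbidden; alignment
selection configurable — typically Cα atoms of the rigid core), each
motif yields a *displacement ensemble*: per atom, either the scalar
distance to its reference position (default, one variable per atom)
or the $(\Delta x, \Delta y, \Delta z)$ deviations (three per atom).
Scalar mode follows the narrower reading of the displacement
definition; vector mode is provided because the measures are
covariance-based either way, and results are always labelled with the
mode used.

All measures reduce to Gaussian differential entropies
$H = \tfrac12\ln\big((2\pi e)^N |C|\big)$ of sample covariances:

* Total correlation: $TC(X_1,\dots,X_N) = \sum_i H(X_i) -
  H(X_1,\dots,X_N)$ — zero iff the motifs are independent.
* Conditional TC given $X_m$: $\sum_i [H(X_i,X_m) - H(X_m)] -
  [H(X_1,\dots,X_N,X_m) - H(X_m)]$.
* Coordination information of transmitter $X_m$ on a receiver set:
  $CI = TC - TC(\cdot|X_m)$, normalized as $NCI = 100\,CI/TC$ (percent
  of the receiver's internal coordination explained by the
  transmitter). A receiver given as one motif is split into
  per-residue blocks, since TC needs at least two blocks — a
  documented convention.
* Mutual coordination information through a channel $X_n$:
  $MCI = CI(R,X_m) + CI(R,X_n) - CI(R, X_m \cup X_n)$, normalized by
  $CI(R,X_m)$. Residues on the transmission path score near 100%,
  bypass topologies near 0%.
* The coordination matrix reports TC (nats) on the diagonal and NCI
  (%) off-diagonal, rows = receiver, columns = transmitter; it is
  deliberately asymmetric because the receiver normalization differs.
* Per-residue transmitter contributions use leave-one-residue-out CI
  drops. This is one reasonable operationalization of "contribution";
  note that residues carrying *redundant* copies of the signal all
  score near zero individually — the tests document this behaviour.

Units are nats throughout (natural logarithm); outputs carry the unit
in their documentation because entropy-derived tables are meaningless
without it. Covariance eigenvalues are floored at the absolute value
1e-8 Å² before the log-determinant. An absolute floor (rather than one
relative to the mean eigenvalue of each covariance) is essential: the
measures are differences of entropies evaluated on marginal and joint
covariances, and only a context-independent floor makes rigid
(zero-variance) degrees of freedom cancel exactly instead of leaving
floor-mismatch artifacts.

## 7. The synthetic generators: what they emulate, what they do not

The study conditions are not shipped as data; they are *generated*,
with ground truth attached, by three generators that are first-class,
tested package code.

**Planted-event bead trajectories** (`genPlantedTrajectory`) emulate
a multi-state protein with time-localized contact-pattern changes and
a ligand bead that switches binding site at the same event. Residue
cores sit on random base positions at least 16 Å apart; every
designated contact pair owns two satellite atoms that meet 3.0 Å
apart (cutoff − 0.5) at a pair-specific meeting point when the
contact is active and park 0.5 Å from their own core otherwise. A
static safety check guarantees every *other* atom-pair combination
stays beyond cutoff + 1.0 Å, so isotropic positional noise (default
σ = 0.2 Å, a typical heavy-atom RMSF scale; margins tolerate up to
~0.3 Å) cannot flip unintended pairs. Flicker pairs (independent
per-frame Bernoulli contacts, default rate 0.1) emulate incidental
dynamic contacts, and constitutive pairs (always on, rare dropouts at
rate 0.02) emulate the maintained fold — they both survive invariance
trimming, exactly the population structure the normalization step
needs. The study-scale fixture (20 residues → 190 candidate pairs, 8
planted switching pairs, 1000 frames, event mid-series) is the
recovery benchmark.

**Gaussian displacement networks** (`genGaussianNetwork`) produce
samples with an exactly known covariance, either from shared latent
factors or from a latent chain (transmitter → channel → receiver),
giving closed-form targets for every entropy measure via the same
sub-determinant arithmetic an independent oracle uses.

**Markov-chain CV emitters** (`genMarkovCV`) sample a known
transition matrix and emit Gaussian CVs per state, providing ground
truth for tICA, MSM estimation, implied timescales, GMRQ, PCCA+ and
TPT.

What passing these tests shows: the estimators implement their
definitions correctly and recover planted structure under realistic
noise at desk scale. What it does not show: behaviour on real
all-atom trajectories — force-field physics, solvent, correlated
noise, slow convergence of sampling, and the ambiguity of choosing
collective variables and motifs are all outside what bead models and
Gaussian ensembles exercise.

## 8. Problem sizes

The validation suite uses: 1e5 samples for the closed-form entropy
battery (2% tolerance) and 48 variables for the exact
sub-determinant cross-check (1e-9); 20 seeds of the 1000-frame,
190-pair planted fixture for event recovery (precision/recall ≥ 0.9
at 4σ); 1e6-step chains for TPM recovery (max error 0.01), implied
timescale flatness (10%), the tICA telegraph limit (slow-mode cosine
> 0.99, timescale within 10%); 198 microstates / 9 blocks for PCCA+
(adjusted Rand > 0.95); and ~3×10^5 Monte-Carlo walks per start state
for committor validation (0.01). These sizes were chosen so each
quantity's sampling error sits comfortably below its tolerance.

## 9. Known limitations

* Contact computation is exact but quadratic in atoms per residue
  pair; very large systems would want a neighbour list.
* PCCA+ uses the inner-simplex construction with clipping, not the
  constrained optimization refinement; for strongly overlapping
  macrostates the refined variant can differ.
* The Gaussian entropy model ignores anharmonicity and multimodality;
  a motif hopping between sub-states inflates its apparent entropy.
* Binding-mode classification is purely distance-based; water-mediated
  sub-modes are absorbed into their parent mode by the 6 Å site
  radius rather than detected explicitly.
* DCD trajectories are read (via bio3d) but not written; the
  package's writers emit multi-model PDB and CSV, which are
  text-stable and round-trip at 1e-3 Å.
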