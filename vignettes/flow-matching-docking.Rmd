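---
title: "Flow-matching transport of apo protein-ligand complexes: models, priors, and samplers"
author: "cfmdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-matching transport of apo protein-ligand complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmdock)
```

## The problem

Blind flexible docking asks for the bound (holo) structure of a
protein-ligand complex given only the unbound ingredients: an apo
protein structure and the ligand's bond graph. Generative flow matching
recasts this as transport between probability distributions. A prior
distribution $\rho_0$ over complex coordinates is built from things we
can obtain cheaply (a predicted or experimental apo structure, and a
bond-graph-constrained Gaussian over ligand coordinates), the data
distribution $\rho_1$ is the distribution of crystal complexes, and a
learned vector field moves samples from one to the other along a
continuous time $t \in [0, 1]$. After transport, scalar heads score
each generated sample (a structural confidence and a binding affinity
in pK units) so samples can be rank-ordered.

`cfmdock` implements this machinery at desk scale, with a synthetic
bead-chain generator standing in for curated structural data, so every
component — priors, path construction, coupling filters, solver, field,
heads — is exercised end to end on one CPU in minutes.

## Prior distributions

**Harmonic ligand prior.** Let $L = D - A$ be the graph Laplacian of
the ligand's heavy-atom bond graph. The prior density over ligand
coordinates $x \in \mathbb{R}^{N_L \times 3}$ is
$\rho_0^L(x) \propto \exp(-\tfrac12 x^\top L x)$ applied independently
per Cartesian axis, so bonded atoms are strongly correlated and sampled
close together. $L$ is positive-semidefinite with one zero eigenvalue
per connected fragment (rigid fragment translations), which makes the
density improper along those modes. `sample_harmonic()` resolves this
by sampling only the positive modes — an eigenmode with eigenvalue
$\lambda$ receives an independent $N(0, 1/\lambda)$ coefficient per
axis — and pinning each fragment's centroid exactly to a supplied
center (the origin for standalone draws; the apo ligand centroid when a
complex provides one). For the single-bond two-atom graph the
difference mode has eigenvalue 2, giving the closed form
$E\|x_a - x_b\|^2 = 3$ that the test suite checks by Monte Carlo.

**Noised apo protein prior.** The protein side of $\rho_0$ is a
user-supplied apo structure plus i.i.d. Gaussian noise of scale
$\sigma = 10^{-4}$ Å per coordinate (`sample_protein_prior()`). During
training the same $\sigma$ is applied to the holo protein and ligand
coordinates as well, which regularizes against coordinate-level noise
without pretending to be a conformational ensemble. At inference
protein noising is off by default.

## CondOT paths and the endpoint loss

The conditional path between a prior draw $x_0$ and a data sample
$x_1$ is the straight line $x_t = (1-t)\,x_0 + t\,x_1$ with
$t \sim U(0,1)$ (`condot_interpolate()`,
`sample_training_batch()`). Under this path the tractable regression
target is the endpoint itself, so the field $v_\theta(x_t, t)$ is an
*endpoint predictor* — we use that name throughout to avoid confusion
with velocity parametrizations — and the training loss is

$$\mathcal{L} = E\,\|v_\theta(x_t, t) - x_1\|^2,$$

reduced as the mean over atoms of the squared Euclidean deviation, so
a uniform 1 Å error on every atom gives a loss of exactly 1
regardless of system size. The loss is deliberately frame-dependent:
rigid motion applied to both arguments leaves it unchanged, applied to
one it does not, and the test suite pins down both facts.

## Unbalanced coupling of apo-holo pairs

Naively pairing independent prior and data samples includes pairs whose
apo and holo proteins differ too much to define a learnable
correspondence. The coupling is therefore *unbalanced*: a pair enters
training only if, after a ligand-proximity-weighted superposition of
the apo onto the holo protein, its TM-score is at least
$c_{TM} = 0.7$ and its C$\alpha$ RMSD is strictly below
$c_{RMSD} = 5$ Å (a pair with RMSD exactly 5 Å is rejected — the
inequality semantics are asserted at the literal thresholds in the
tests), plus configurable residue- and ligand-size bounds
(defaults $10 \le S_P \le 2000$, $1 \le N_L \le 200$).

The superposition weights follow $w_i \propto \exp(-d_i / 4\,\text{Å})$
where $d_i$ is the minimum distance from residue $i$'s C$\alpha$ to any
holo ligand heavy atom. The functional form of the weighting is a
package choice: exponential decay concentrates the fit on the binding
pocket, which is the stated purpose of weighting the alignment, and the
scale is configurable. Alignment is computed on C$\alpha$
correspondences; heavy atoms inherit the rigid transform. TM-score uses
$d_0(L) = 1.24 (L - 15)^{1/3} - 1.8$ Å floored at 0.5 Å and is
normalized by the holo chain length; whether the score is taken after
the ligand-weighted alignment (default) or after an iterative
TM-favouring refinement is a flag on `apo_holo_filter()`, since either
reading is defensible.

## The variance-diminishing ODE sampler

Generation integrates the endpoint predictor over `n_steps` $= i = 40$
uniform steps. With $t = n/i$ and $s = (n+1)/i$, one step of the
variance-diminishing update is

$$x_{n+1} = \mathrm{clamp}\!\Big(\tfrac{1-s}{1-t}\,\eta\Big)\, x_n +
  \mathrm{clamp}\!\Big(\big(1 - \tfrac{1-s}{1-t}\big)\,\eta\Big)\,
  v_\theta(x_n, t),$$

with $\eta = 1$ and each *scalar coefficient* clamped into
$[10^{-6},\, 1 - 10^{-6}]$ — the clamp acts on the blending
coefficients, not on coordinates, which is the reading under which both
sides of the update stay bounded. For $\eta = 1$ the unclamped
coefficients are exactly those of the Euler discretization of the
linear-path ODE with induced velocity $(v_\theta - x_t)/(1-t)$ (the
`euler_integrate()` baseline), and they sum to 1 at every step; the two
solvers differ where the clamp binds, i.e. at the terminal step, where
Euler jumps fully onto the (possibly noisy) prediction while the VD
update retains a $10^{-6}$ mixture of the current state. Late steps
therefore interpolate sharply toward the prediction while early-step
predictions enter with weight only $1/(i-n)$, damping their variance.
The test suite operationalizes the variance comparison with a noisy
endpoint oracle (1 Å Gaussian noise per call) under common random
numbers — both solvers consume the identical noise stream — and checks
that the final-state variance under the VD update is strictly below the
Euler baseline at equal step count. The $t = 1$ singularity of
$(1-s)/(1-t)$ is never evaluated because the last step uses
$t = (i-1)/i$.

## The toy endpoint field

The trainable field is intentionally the smallest architecture that
honours the contracts the samplers and training loop need: SE(3)
equivariance, joint protein-and-ligand coordinate updates (flexible
receptor — the protein is not frozen), time conditioning, and exact
gradients. Each atom $i$ carries geometric basis vectors built from the
current coordinates:

* contraction toward its own entity's centroid (protein centroid, or
  ligand fragment centroid);
* for ligand atoms, soft-nearest-protein vectors at 2 Å and 6 Å
  softmin scales, pointing toward the closest protein surface with
  magnitude tracking the gap — the feature that lets the field carry a
  stray ligand back into the pocket;
* distance-gated neighbor means over `n_layers` aggregation rounds with
  `hidden_width` Gaussian radial gates on a `neighbor_cutoff` = 10 Å
  radius graph (the message-passing part);
* the bonded-neighbor mean (Laplacian smoothing direction along the
  bond graph).

The prediction is $x_i$ plus a learned linear combination of these
vectors, with separate coefficients per atom type (protein/ligand) and
a time embedding of powers $(1-t)^1, \dots, (1-t)^K$. The embedding
deliberately has **no constant term**: the CondOT endpoint target
$x_1 - x_t = (1-t)(x_1 - x_0)$ vanishes at $t = 1$, so the field is
built to be the identity there. (An earlier design with a constant term
let the trained field keep deforming the ligand in the late, almost
fully-trusted steps of the solver, degrading transport; constraining
the boundary behaviour fixed this.) Because the model is linear in its
coefficients the loss is quadratic; `train_field()` runs Adam on exact
gradients with a $1/(1 + 2\,\mathrm{step}/\mathrm{steps})$ learning-rate
decay and returns the Polyak average of the final quarter of iterates,
which stabilizes small-batch stochastic optimization.

## Confidence and affinity heads

Both heads are linear models on rigid-motion-invariant descriptors
(`complex_features()`): total and per-atom protein-ligand contacts
(4.5 Å), clashes (2.2 Å), mean nearest-protein distance, an 8 Å
burial count, the RMS bond-length deviation from the 1.5 Å bead rest
length, and the ligand radius of gyration.

The *affinity head* regresses the synthetic pK affinity on the holo
descriptors by ordinary least squares; affinities are in pK units
($-\log_{10}$ of a molar binding constant), the convention of binding
databases, with a mean-square loss.

The *confidence head* is trained on decoy poses labelled by their
ligand RMSD to the reference pose, with one twist: features and targets
are demeaned **within each system** before fitting (the fixed-effects
estimator, `groups` argument of `train_ranking_head()`). A confidence
score is used to rank alternative poses of one complex, so only
within-complex contrasts carry signal; without demeaning, between-system
offsets in contact counts dominate the fit and the learned slopes are
much noisier. Evaluation follows the use case: mean per-system Spearman
correlation between scores and pose quality on held-out systems.
`rank_samples()` sorts descending by the chosen key with a stable
tie-break on sample index.

## The synthetic generator, and what it does not emulate

`generate_system()` builds a bound complex first — a self-avoiding
bead chain (3.8 Å C$\alpha$ steps, plus one pseudo side-chain bead per
residue so the heavy-atom/C$\alpha$ distinction is real), with a
random connected ligand bond graph packed into a surface pocket 4.2 Å
off a mid-chain residue (deliberately not equal to the 4.5 Å contact
cutoff, so no atom pair sits exactly on the contact boundary) — and
then derives the apo state:

* `rigid_ligand_shift`: the ligand is translated by exactly
  `deformation_scale` along the jittered outward pocket normal, i.e. an
  undocking displacement. Outward is the physically meaningful
  direction — an unbound ligand sits off the protein surface, and a
  uniform random direction would regularly bury the apo ligand inside
  the protein core.
* `pocket_hinge`: a chain segment is rotated about a hinge residue, the
  angle solved by bisection so the RMS C$\alpha$ displacement equals
  the requested scale.
* `global_deform`: a smooth low-frequency sinusoidal backbone
  perturbation normalized to the requested RMS amplitude; sweeping the
  scale upward drives the measured TM-score down monotonically, which
  is how pairs straddling the coupling thresholds are made.

The synthetic affinity is
$\alpha \cdot \mathrm{contacts} + N(0, \sigma_{\mathrm{aff}})$ with
$\alpha = 0.1$ pK per contact and $\sigma_{\mathrm{aff}} = 0.5$ pK,
the order of experimental affinity uncertainty.
`deform_to_similarity()` additionally constructs apo partners whose
*measured* (TM, RMSD) land on requested values, using equal-and-opposite
deviations on weight-matched residue pairs (no net force or torque, so
the weighted superposition stays at the identity) with a short
fixed-point calibration against the measuring pipeline itself.

What the generator does **not** emulate: real folds and secondary
structure, sequence-structure relationships (the field cannot learn
where a pocket is from sequence, only from geometry), chemically valid
ligand geometry, symmetry-equivalent ligand atoms, and crystal
artefacts. Passing tests therefore demonstrate that the machinery —
priors, filters, losses, solvers, heads — behaves as specified, not
that this small field would dock real complexes.

## Numerical choices and problem sizes

* All randomness descends from one run-level seed through named
  substreams (`prior`, `batch`, `train`, `system`, ...), so every stage
  is bit-reproducible; the suite asserts bit-identity of a full rerun.
* Degenerate alignment inputs (collinear or coincident points) warn and
  return a best-effort transform; the proper-rotation determinant
  correction is always applied.
* The harmonic sampler treats eigenvalues below $10^{-10}$ as zero
  modes; the PSD check tolerates $-10^{-8}$ of eigenvalue noise.
* Default study sizes, chosen to keep a full run on one CPU in
  minutes: benchmark suites of 50 systems (70/30 train/held-out split
  with disjoint seed blocks), 40-80 residues and 8-16 ligand atoms per
  system, deformation scales 2-6 Å, field training for 1500 steps at
  batch size 4, and 100 000 draws for prior statistics.
* Ties in ranking are broken by sample index; filter decisions at
  threshold equality follow the strict/non-strict semantics stated
  above.

## Known limitations

The field is linear in its features, so it can transport ligands into
pockets and relax conformations only as far as those features span;
it does not attempt contact-map decoding, attention over sequence, or
any learned representation of chemistry. The coupling filter assumes
residue-matched apo/holo pairs (no sequence alignment), and ligand RMSD
is computed without symmetry correction. Affinity and confidence heads
are linear probes, adequate for the synthetic contact-based ground
truth but not calibrated scores. Stochastic (SDE) samplers and
higher-order ODE solvers are out of scope.
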