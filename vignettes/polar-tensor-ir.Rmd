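---
title: "Atomic polar tensors, equivariant regression, and IR spectra: methods"
author: "aptIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomic polar tensors, equivariant regression, and IR spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aptIR)
```

## The quantity and why it is worth learning

The atomic polar tensor (APT) of atom $i$ is the $3\times3$ matrix

$$ P_i \;=\; \frac{\partial \mathbf{M}}{\partial \mathbf{r}_i}, \qquad
   (P_i)_{\xi\zeta} = \frac{\partial M_\xi}{\partial r_{i\zeta}}, $$

the derivative of the simulation box's total dipole moment with respect to
that atom's Cartesian position, in units of the elementary charge $e$. It is
a genuine physical observable (no charge partitioning, no molecular reference
frames), it remains well defined when bonds break, and it is precisely the IR
selection rule expressed per atom: by the chain rule the dipole velocity is

$$ \dot{\mathbf{M}}(t) = \sum_i P_i(t)\, \mathbf{v}_i(t), $$

so any atomic-velocity spectrum can be promoted to a proper IR spectrum by
APT weighting. The absorption spectrum follows from the Fourier-transformed
autocorrelation of $\dot{\mathbf M}$,

$$ n(\omega)\,\alpha(\omega) \;=\; \frac{\beta}{3 \varepsilon_0 V c}
   \int_0^\infty \langle \dot{\mathbf M}(0)\cdot\dot{\mathbf M}(t)\rangle
   \cos(\omega t)\, dt , $$

with $\beta = 1/k_BT$ and $V$ the box volume. The harmonic quantum
correction factor is already absorbed in this dipole-velocity form; the
package applies no further frequency-dependent factor, and it reports the
product $n(\omega)\alpha(\omega)$ jointly without attempting to separate the
refractive index.

Obtaining $P_i$ from first principles is expensive: a central
(two-sided) finite difference needs 6 single-point dipole evaluations per
atom, i.e. 2304 for one 384-atom configuration. The package therefore
(i) labels a small number of snapshots by finite differences of a pluggable
dipole backend, (ii) fits an E(3)-equivariant regressor that predicts every
atom's APT from its local environment, and (iii) pushes the predicted APTs
through the dipole-velocity route to the spectrum. Training on a handful of
configurations suffices because one 384-atom snapshot already contributes
384 tensor labels.

## Finite-difference labelling

* Scheme: central differences, column $\zeta$ of $P_i$ equal to
  $[\mathbf M(r_{i\zeta}{+}h) - \mathbf M(r_{i\zeta}{-}h)]/2h$. Exactly 6
  displaced evaluations per atom; the unperturbed geometry is never needed.
* Displacement: $h = 0.01$ Å by default. $h$ is a convergence parameter and
  is exposed as a setting (`fdSettings()`); `displacementCheck()` audits the
  difference between two displacements (e.g. 0.01 vs 0.04 Å), which is zero
  for dipoles linear in positions and scales as $h^2$ otherwise.
* Displacements are applied to the raw Cartesian coordinate without
  re-wrapping into the cell. Wrapping would hop between branches of the
  multivalued periodic dipole and corrupt the quotient; backends must be
  branch-consistent under sub-displacement perturbations.
* `richardsonAPT()` combines central differences at $h$ and $h/2$ to cancel
  the $O(h^2)$ term; at $h = 0.01$ Å it agrees with closed-form tensors of
  the toy models to better than $10^{-8}\,e$ and serves as the independent
  numerical oracle throughout the tests. Plain central differences at
  $h = 0.01$ Å carry a truncation error of order $10^{-5}\,e$ on the
  fluctuating-charge surface; tests assert the measured convergence order
  ($2 \pm 0.2$) rather than pretending the plain quotient is exact.
* A backend may advertise analytic derivatives (`aptFun`); the analytic path
  then bypasses finite differences, while the FD path remains the reference.

## The equivariant regressor

The APT is translation invariant, permutation equivariant, parity even, and
rotates as $P \mapsto R P R^{\mathsf T}$. The regressor enforces all four
properties *by construction* rather than by data augmentation.

Architecture (a two-hop symmetry-adapted message-passing model):

1. **Neighbor graph.** Edges between atoms closer than the cutoff
   $r_c$ (default 6 Å) under the minimum-image convention; $r_c$ must stay
   below half the smallest cell height, and an explicit-image path
   (`buildGraph(..., method = "images")`) covers smaller cells and serves as
   the brute-force oracle. Edges are sorted so floating-point summation
   order is reproducible.
2. **Hop 1 — density projections.** Per atom, species- and radially-resolved
   sums of spherical tensors of the unit bond vectors: scalars ($\ell=0$,
   even), polar vectors ($\ell=1$, odd), symmetric-traceless tensors
   ($\ell=2$, even). The radial basis is 8 Gaussians under a smooth cosine
   envelope that vanishes at $r_c$.
3. **Hop 2 — message passing.** The hop-1 features of the neighbors,
   compressed through fixed seeded orthonormal projections, are aggregated
   again with their own radial weights (4 channels), extending the receptive
   field to $n_\text{layers} \times r_c$ and making the prediction genuinely
   many-body. With `nLayers = 1` the second hop is disabled.
4. **Tensor products.** Couplings of the pooled features produce exactly the
   three channels the APT decomposes into, with even parity throughout:
   scalars (dots of two odd vectors, traces of products of two even
   tensors), axial vectors (crosses of two odd vectors, commutators of two
   even tensors), and symmetric-traceless tensors (symmetrised outer
   products plus the direct $\ell=2$ features).
5. **Readout.** Per species, one linear map per irreducible channel;
   the prediction is recomposed as $P = s\,I + [\mathbf a]_\times + S$.

Because every feature entering the readout transforms exactly in the
representation of its channel (including the $\det R$ factor of axial
vectors under improper rotations), equivariance holds to machine precision;
the test suite checks proper and improper rotations, translations and
permutations at $10^{-5}$ relative or better.

**Training.** Adam (initial learning rate 0.01) on the mean squared error
over the 9 tensor components in units of $e$, one configuration per batch,
100 epochs by default, with the learning rate reduced by a factor 0.1 when
the validation MSE has not improved over the last 10 epochs. Splitting is by
configuration, never by atom (atom-level splits would leak near-identical
environments). Weights start at zero and all stochastic choices (feature
projections, batch order) derive from recorded seeds, so training is
bitwise reproducible.

**Normalisation.** Targets are centred by the species-mean *isotropic*
tensor ($\operatorname{tr}/3 \cdot I$) and scaled by a single scalar
standard deviation per species; scalar features are centred and scaled,
vector/tensor feature channels are RMS-scaled only. Anything finer-grained
(per-component statistics, shifts of equivariant channels) would break
rotation equivariance, which is why the package deliberately restricts
normalisation to isotropic operations.

**Design note.** The literature implements this class of model as a deep
equivariant graph network with irreducible-representation features (e.g.
multiplicity-20 features of ranks 0, 1, 2 in both parities and two message
passing layers). This package keeps the two-hop message-passing structure
and the irrep bookkeeping but makes the trainable part a per-channel linear
readout over a rich fixed symmetry-adapted basis. That choice keeps
training convex, fast and exactly reproducible in pure R while preserving
every symmetry contract; its capacity limit shows up as the approximation
floor discussed under the learning curve below.

## Spectrum estimation

* **Autocorrelation:** biased (divide by $N$) estimator, FFT-based with a
  brute-force $O(N^2)$ oracle path; both agree to $10^{-10}$ relative.
* **Transform:** windowed cosine transform of the ACF onto an explicit
  wavenumber grid (default spacing 2 cm$^{-1}$ up to 4500 cm$^{-1}$), with a
  Hann taper over the lag range (default: half the series) to suppress
  leakage on short trajectories. With no window and the full lag range the
  integral of the returned density equals the time-domain mean square
  (Parseval, tested at 1%).
* **Units:** absolute $n(\omega)\alpha(\omega)$ in cm$^{-1}$ when
  temperature and volume are supplied, otherwise unit-maximum normalised.
* **Nyquist guard:** a requested maximum wavenumber above $1/(2 c\,\Delta t)$
  raises an error; `nyquistInterval(3500)` ≈ 4.77 fs reproduces the familiar
  rule of thumb that O–H stretching demands data roughly every 4.5–5 fs.
* **Decomposition:** group dipole velocities
  $\dot{\mathbf M}_g = \sum_{i\in g} P_i \mathbf v_i$ (optionally after
  per-atom $3\times3$ velocity projectors that must resolve the identity),
  with symmetrised cross-correlations so all spectra are real. The estimator
  is bilinear, so group autos plus twice the crosses reconstruct the total
  pointwise to rounding error.
* **Averaging:** multiple trajectories are combined by averaging their ACFs
  before the transform.
* **Velocities:** stored integrator velocities when available;
  `velocitiesFromPositions()` reconstructs them by central differences on
  minimum-image-unwrapped coordinates (for velocity-Verlet trajectories the
  two coincide identically, a property the tests exploit).

## The synthetic water generator

The generator emulates the *shape* of a condensed-phase reference system —
periodic boxes of 128 water molecules (384 atoms) at 0.997 g/cm³, sampled by
NVE dynamics at 1 fs-scale timesteps — with an analytic dipole surface whose
APTs have closed forms, so the whole labelling–training–spectrum loop can be
validated without electronic-structure code.

* **Geometry/dynamics:** rigid-geometry placement (O–H 0.9572 Å, H–O–H
  104.52°) on a jittered checkerboard lattice with a guaranteed 2.5 Å O–O
  floor; harmonic bonds ($k_b = 0.44$ amu/fs², stretches near 3600 cm$^{-1}$)
  and angles ($k_\theta = 0.039$ amu Å²/fs², bend near 1600 cm$^{-1}$); a
  purely repulsive O–O core (WCA form, $\sigma = 3.166$ Å) keeps molecules
  apart. These constants are documented package constants chosen to exercise
  sampling-theorem logic at realistic wavenumbers — not claims about real
  water. Velocity-Verlet integration at default $\Delta t = 0.25$ fs keeps
  the relative energy drift below $10^{-4}$ over multi-picosecond runs; at
  the 1 fs timestep used for spectrum-scale trajectories the integrator is
  still stable but its bounded energy oscillation grows as $\Delta t^2$, so
  the drift bound is asserted at the default timestep only. Normal modes
  come from central differences of the analytic forces (step $10^{-4}$ Å),
  mass-weighted and diagonalised.
* **Toy dipoles** ($\mathbf M = \sum_i q_i \mathbf r_i$, per-molecule
  neutral, hence translation invariant and single-valued — the generator
  deliberately sidesteps the branch bookkeeping of periodic first-principles
  dipoles):
  * *fixed*: SPC-like charges ($q_H = 0.41\,e$); every APT is exactly
    $q_i I$, the species-constant oracle.
  * *fluctuating*: bond stretches shift charge between H and its O
    (0.40 $e$/Å), and each O acquires a smooth environmental term from
    neighboring O atoms (compactly supported kernel, 5.5 Å reach, amplitude
    0.03 $e$), compensated by its own H atoms. The environmental term
    emulates condensed-phase polarisation — an atom's APT then depends on
    molecules beyond its own, as for first-principles dipoles — and it is
    what makes the regression problem genuinely many-body rather than a
    lookup of bond lengths. The kernel support is additionally capped just
    below half the cell height, because beyond that the minimum-image
    distance is not differentiable and the backend smoothness contract
    would fail in small boxes.
  * Closed-form APTs include all charge-gradient terms (bond charge flow
    and the intermolecular lever-arm terms) and are validated against the
    Richardson oracle at $10^{-8}\,e$.
* **What passing tests do *not* show:** the toy surface is smooth,
  single-valued and much tamer than a DFT dipole (no charge transfer across
  molecules, no genuine polarisation response to H positions, no
  anharmonicity beyond geometric nonlinearity). Accuracy numbers on
  synthetic data therefore validate the machinery — bookkeeping, symmetry,
  convergence orders, route equivalence — not chemical accuracy on real
  water, which requires electronic-structure labels that are out of scope
  here.

## Problem sizes and reference results

The packaged checks run at desk scale, chosen so the full suite completes
in minutes on one CPU:

* bookkeeping at the reference scale: 10 × 384-atom configurations (3840
  APTs), 90/10 splits (3456/384), 27 training configurations (10368 APTs);
* learning curve: 4/9/18/27 training configurations of 128 molecules,
  100 epochs each, evaluated on a fixed 3840-APT test set — the held-out
  MSE decreases monotonically with training size and flattens toward the
  approximation floor of the linear readout (the fixed-basis analogue of
  the log–log-linear learning curves reported for deep equivariant models);
* route equivalence: a 32-molecule, 8 ps, 1 fs trajectory; the spectrum
  from model-predicted APTs agrees with the direct-dipole spectrum to a few
  percent relative $L_2$ over 0–4500 cm$^{-1}$. The model uses
  $r_c = 4.5$ Å here because the 32-molecule cell (≈9.9 Å) bounds the
  minimum-image cutoff; the 6 Å default applies to 128-molecule cells.
  Both routes use the exact integrator velocities, and the reference
  dipole velocity is the exact chain-rule $\sum_i P_i^{\text{analytic}}
  \mathbf v_i$, so the comparison isolates model error rather than
  time-differencing artefacts (time-finite-difference consistency of
  $d\mathbf M/dt$ is tested separately at its own $O(\Delta t^2)$
  tolerance).

`scripts/acceptance.R` recomputes all of these from scratch for a given
seed; the numbers it prints are produced at run time, never stored.

## Known limitations

* The regressor's accuracy saturates at the approximation floor of its
  fixed symmetry-adapted basis; a deep equivariant network can go below it
  at the cost of non-convex training.
* No uncertainty quantification or committee models; no active learning.
* Spectra assume classical nuclei (the harmonic quantum correction implicit
  in the dipole-velocity form only); no path-integral centroids.
* Raman/SFG require polarisability tensors, which share the machinery but
  are not implemented.
* The CLI toy backends cover the synthetic models only; production
  labelling hooks in through `dipoleBackend()` with a user-supplied dipole
  function.
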