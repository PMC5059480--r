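---
title: "Models and methods behind thiodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thiodyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

thiodyn models the photophysics of sulfur-substituted pyrimidine nucleobases
(thiobases), using 2-thiocytosine as the worked system. Thionation red-shifts
the absorption into the UV-A/UV-B and converts the near-perfect photostability
of the canonical bases into near-unity intersystem crossing (ISC) to reactive
triplet states. The package implements the three computational pillars of
that analysis — global/target fitting of femtosecond transient-absorption
(TAS) maps, simulation of excited-state absorption spectra, and spin–orbit
trajectory surface hopping on a calibrated vibronic model — together with a
synthetic-data layer that generates every input with known ground truth.
This vignette records the models, the tunable parameters and their defaults,
and the numerical and design choices, so that a reader can judge exactly what
the tests demonstrate.

## 1. Global target analysis of transient absorption

A broadband TAS experiment yields a map $\Delta A(\lambda, t)$ (mOD) over
probe wavelengths 320–710 nm and pump–probe delays up to a few picoseconds.
The kinetic model is a two-step sequential scheme $A \to B \to C$ with
lifetimes $\tau_1$, $\tau_2$, convolved with a Gaussian instrument response
function (IRF). The population of the initial species is the exponentially
modified Gaussian (EMG)

$$c_A(t) = \tfrac12\, e^{-k(t-t_0) + k^2\sigma^2/2}\,
 \operatorname{erfc}\!\left(\frac{t_0 - t + k\sigma^2}{\sigma\sqrt2}\right),
 \qquad k = 1/\tau_1,\; \sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2}),$$

the intermediate follows as $c_B = \frac{k_1}{k_1-k_2}(c(k_2) - c(k_1))$ and
the long-lived offset $C$ as the IRF-convolved step minus $c_A + c_B$, so
the three profiles sum exactly to the step at every delay. The EMG is
evaluated on the log scale (`pnorm(..., log.p = TRUE)`), which keeps it
finite for stiff rate–width combinations. The degenerate case
$\tau_1 = \tau_2$ (rates within $10^{-12}$ fs$^{-1}$) switches to the
analytic limit $-k\,\partial c/\partial k$, a $t$-weighted EMG, to avoid
catastrophic cancellation.

`global_fit()` minimizes the summed squared residual over the nonlinear
parameters $(\tau_1, \tau_2, t_0)$ only; for any trial profile matrix the
decay-associated spectra (DAS) are the conditionally linear part and are
solved row by row on the unmasked points (variable projection). The
nonlinear part uses bounded Levenberg–Marquardt (minpack.lm) with three
starts log-spaced around the initialization (factors 0.5, 1, 2), ties broken
by lowest residual then lowest $\tau_1$. The IRF width is fixed at its
protocol value — 200 fs by default — matching the practice of determining it
independently from a solvent coherence signal; `fix_irf = FALSE` frees it.
The two-lifetime bilinear model has an exchange symmetry (swapping
$\tau_1, \tau_2$ spans the same profile space), so the fast lifetime is
reported first by convention. A fit in which the intermediate or the
lifetimes collapse to the bounds is flagged non-identifiable rather than
silently returned.

Chirp (group-velocity dispersion of the white-light probe) is handled before
fitting: each wavelength's trace is resampled at $t + t_0(\lambda)$ with a
polynomial $t_0(\lambda)$, points leaving the recorded window becoming
masked. After this correction a single global $t_0$ remains in the fit.
Masked points — the pump-overtone window, chirp edges, NaN cells — are
excluded from every residual.

Lifetime uncertainties follow the replicate convention: the five synthetic
experiments of the analysis workflow are fitted independently and the spread
is reported as twice the standard deviation across fits.

## 2. Excited-state absorption spectra

Calculated stick spectra (transition energy, oscillator strength) are turned
into bands as sums of Gaussians *in the energy domain* with a constant
0.7 eV full width at half maximum, amplitudes proportional to the oscillator
strengths, sampled on the wavelength grid. No $dE/d\lambda$ Jacobian is
applied by default — the band is a Gaussian in energy plotted against
wavelength — because that is the simplest reading of a constant-eV-width
convolution displayed on a nm axis; `broaden(..., jacobian = TRUE)` applies
the reweighting for users who prefer strict area preservation per nm.

Transient spectra are decomposed into non-negative linear combinations of
the component bands (`fit_combination()`, active-set NNLS via
`pracma::lsqnonneg`); non-negativity is physical — the components are
additive populations of absorbers — and the weights are reported as
percentages of their sum. The packaged fixture sticks place the bright
singlet $\pi_s\pi^*$ band at 363 nm, the triplet $\pi_s\pi^*$ pair at
441/546 nm and the $n_s\pi^*$ pairs at 333/576 and 333/574 nm, with the
$n\pi^*$ oscillator strengths one tenth of the $\pi\pi^*$ ones; the
strengths themselves are declared fixtures, not computed values, so only
band positions and that 10:1 ratio should be read as meaningful.

## 3. The calibrated vibronic model

The excited-state landscape is represented by a linear vibronic coupling
(LVC) Hamiltonian over dimensionless normal coordinates $q$:

$$H_{\alpha\alpha}(q) = E_\alpha + \sum_i \kappa_{\alpha i} q_i +
  \sum_i \tfrac{\omega_i}{2} q_i^2, \qquad
  H_{\alpha\beta}(q) = \sum_i \lambda_{\alpha\beta i}\, q_i,$$

with five spin-free states — S0 and the $^1n_s\pi^*$, $^1\pi_s\pi^*$,
$^3n_s\pi^*$, $^3\pi_s\pi^*$ pairs — and interstate couplings only between
states of equal multiplicity. Triplets carry three sublevels, degenerate in
the spin-free part, giving a 9-dimensional spin Hamiltonian
($3 + 3 \times 2$). Spin–orbit couplings are coordinate-independent
(Condon) complex blocks between singlets and triplet sublevels; each block's
Frobenius norm equals the configured magnitude (stored in cm$^{-1}$,
converted at build time), distributed over sublevels by a unit-norm pattern
(default: equally over $m_s = \pm 1$). Because the contract is on the
Frobenius norm, rate-level observables are insensitive to the pattern.

The SOC magnitudes follow the El-Sayed propensity: 160 cm$^{-1}$ between
opposite-character pairs ($^1n_s\pi^*$–$^3\pi_s\pi^*$ and
$^1\pi_s\pi^*$–$^3n_s\pi^*$) and 50 cm$^{-1}$ between same-character pairs.
These are the reported trajectory-average magnitudes; the packaged SOC
reference table keeps all three printed values (170 near the crossing
points, 160 and 50 as averages) under distinct labels because they refer to
different geometries.

**Mode structure.** Two tuning modes (0.030 and 0.025 eV, i.e. roughly
240 and 200 cm$^{-1}$ skeletal deformations) carry the landscape: every
stationary point and crossing of interest lives in this plane. One coupling
mode (0.020 eV) hosts the $\lambda q_3$ interstate couplings
($\lambda = 0.04$ eV for the singlet pair, 0.03 eV for the triplet pair),
creating genuine conical intersections at $q_3 = 0$. Five further bath
modes (0.028–0.011 eV) carry small state-dependent gradients
(reorganization energy $\approx$ 15 meV per state). The bath is a deliberate
extension beyond the minimal three-mode design: a three-mode model has no
vibrational energy sink, so ensembles equilibrate between the singlet and
triplet manifolds instead of funnelling — triplet population plateaued near
50% with strong back-transfer. The weakly displaced bath restores the
irreversibility that the 33-mode molecule has (energy deposited in spectator
modes on every surface change is unlikely to reassemble in the reactive
coordinate), and with it the triplet population rises to a clear majority within 1 ps
(the mechanism suite asserts the ordering and its monotone dependence on
the spin-orbit magnitudes). The model's coordinates remain abstract
effective modes: nothing about them should be read as real nuclear
geometries.

**Calibration.** The packaged critical-point table holds the ten printed
MS-CASPT2 energies (eV above the S0 minimum): the bright-state FC point at
3.65; singlet minima at 3.02/2.95 with their CoIn at 3.02; triplet minima at
3.02/2.85 with their CoIn at 3.03; singlet–triplet MECPs at 3.05 and 3.08;
and a $\geq 0.8$ eV bound on the ground-state-recovery barrier.
`calibrate_model()` least-squares adjusts the four excited-state vertical
energies and their tuning-mode gradients (11 parameters, 9 equality targets
plus the barrier hinge) so that `locate_critical_points()` reproduces every
entry; the shipped resource `model_2tc.yaml` reproduces all targets to
better than $10^{-6}$ eV, far inside the 0.05 eV contract. The start point
was constructed analytically: with equal curvatures on all states the
crossing seam between two paraboloids is a hyperplane, so target crossing
energies pin the pairwise distances between minima in the metric
$\sum_i \tfrac{\omega_i}{2}\Delta q_i^2$, and the minima layout can be
solved by hand before any optimization.

**Numerical choices in the searches.** Minima are located by
derivative-based descent on the character-tracked adiabatic surface (the
eigenstate with the largest weight on the target diabatic state), started
from the diabatic minimum. Because the interstate couplings are odd in
$q_3$, the $q_3 = 0$ plane is gradient-stationary and the descent stays in
it, which keeps the search deterministic even near intersections. Crossing
seams are found by minimizing the mean energy of the two tracked surfaces
under a squared-gap penalty whose weight is ramped tenfold per cycle until
the gap falls below $10^{-4}$ eV; non-converged searches are flagged in the
report, never dropped. The barrier entry reports the lowest crossing energy
between S0 and any excited singlet surface minus the $^1n_s\pi^*$ minimum
energy. All energies are reported relative to the S0 minimum.

## 4. Surface hopping in the spin-mixed basis

Dynamics runs on the *diagonal* states — eigenstates of the total
electronic + spin–orbit Hamiltonian — as in spin-adiabatic surface-hopping
schemes. Per nominal nuclear step (0.5 fs):

1. velocity-Verlet motion on the active diagonal surface, with the gradient
   taken as the diagonal element of the transformed spin-free gradient
   (Hellmann–Feynman; no response terms);
2. diagonalization at the new geometry and construction of the
   Löwdin-orthonormalized overlap $\tilde T = U(t)^\dagger U(t+\Delta t)$
   (exact in a fixed diabatic basis; the orthonormalization is kept for
   generality and the overlap's smallest singular value is monitored);
3. local-diabatization propagation of the electronic coefficients: the
   end-of-step Hamiltonian is rotated into the frozen basis,
   linearly interpolated over 25 electronic substeps of 0.02 fs, and each
   substep applies the exact unitary $e^{-iH\,\delta t/\hbar}$ via
   eigendecomposition, so the norm is conserved to machine precision;
4. an energy-based decoherence correction with
   $\tau_k = \frac{\hbar}{|E_k - E_a|}\left(1 + \frac{C}{E_\mathrm{kin}}\right)$,
   $C = 0.1$ hartree by default (the community value; it is not printed in
   the source analysis), vanishing gaps giving no damping;
5. a fewest-switches hop decision with probabilities taken from the
   population flux: the fractional loss of active-state population over the
   step, distributed over the states that gained population. This is the
   standard flux construction for overlap-based propagation, where no
   nonadiabatic coupling vector is available, and it reduces exactly to the
   two-state fewest-switches expression for monotone transfer.

Accepted hops conserve total energy by uniform rescaling of the full
momentum vector — the conventional choice under local diabatization, where
no coupling-vector direction exists; energetically frustrated hops are
rejected with momenta unchanged (no reflection) and counted. Initial
conditions are drawn from the harmonic ground-state Wigner distribution
(variance $\tfrac12$ in each dimensionless $q$ and $p$); the initial
electronic state is selected by filtering vertical excitation energies
through a window (default 3.4–3.9 eV, centred on the bright state) with
acceptance proportional to an oscillator-strength surrogate weight, and the
trajectory starts on the diagonal state of maximum overlap with the chosen
spin-free state.

**Adaptive step refinement.** An LVC model has genuine conical
intersections, and a fixed 0.5 fs step can jump across their cusps: the
resulting total-energy errors reached $10^{-2}$ eV in early tests, far above
the package's conservation contract of $10^{-4}$ eV between hops. The
propagator therefore subdivides nuclear steps adaptively. For every surface
within 0.1 eV of the active one it estimates the local sweep rate as
$\sqrt{s_\mathrm{adia}^2 + 4|\langle u_k|\dot q \cdot \nabla H|u_a\rangle|^2}$
— the adiabatic slope difference plus twice the off-diagonal element of
$dH/dt$, which dominates at spin–orbit-avoided crossings where the
adiabatic slopes momentarily coincide — and shrinks the step so the gap is
swept in at least ~50 slices (subdivision capped at 256). Sublevel
partners, which share a spatial surface and sweep at zero rate, never
trigger refinement. A baseline factor of 2 keeps the bounded
velocity-Verlet energy oscillation itself below the contract. With these
choices the between-hop drift across a 64-trajectory, 1 ps ensemble stays
comfortably below the 10$^{-4}$ eV contract (the conservation suite asserts
it on every trajectory). Electronic substeps shrink proportionally so the
0.02 fs electronic resolution is preserved. Trajectories whose drift ever
exceeds 0.1 eV are flagged invalid, and an ensemble aborts if more than 20%
flag.

## 5. Population analysis and the Markov surrogate

Populations are *active-state counts*: per trajectory and time step the
active diagonal state is assigned to the spin-free adiabatic class — S0,
S1, S2 within the singlet block, T1, T2 within the triplet block, labelled
by energetic ordering at that geometry — carrying the largest squared
weight, with triplet sublevels pooled and exact ties broken toward the
lower index. Class fractions averaged over trajectories are simplex-valued
by construction. Lifetimes come from least-squares fits of
$p(t) = A\,e^{-\max(t - t_d, 0)/\tau}$ (or its complement for rises); both
the onset $t_d$ and the amplitude can be freed or pinned, since the
convention used in the original analysis is not stated. Confidence
intervals are bootstrap percentiles over trajectories (default 200
resamples, seeded).

The three-step relaxation scheme is also available as a continuous-time
Markov chain S2 → S1 → {T2, T1}, T2 → T1 with exact (event-driven)
stochastic simulation and the matrix-exponential master-equation solution.
The packaged rates anchor to the simulated time constants: S2 depopulation
at $1/160$ fs$^{-1}$, total S1 ISC at $1/250$ fs$^{-1}$ split 70/30 toward
T2 (so T2 is populated faster than T1), and T2 → T1 internal conversion at
$1/480$ fs$^{-1}$, the slower experimental component being attributed to
that step. The 70/30 split is a declared choice consistent with the
reported SOC asymmetry, not a printed number.

## 6. Synthetic data: what it does and does not emulate

`generate_tas()` composes the bilinear map from three fixture DAS shapes —
sums of Gaussians in wavelength: a broad featureless initial component, a
UV band peaked at 355 nm with a visible shoulder, and an offset component
peaked at 525 nm — with the sequential profiles (defaults
$\tau_1 = 210$ fs, $\tau_2 = 480$ fs, IRF 200 fs), imprints a polynomial
chirp (default spanning roughly ±120 fs across the probe window), adds iid
Gaussian noise (default 0.05 mOD — a declared fixture value; the
experimental noise level is not reported), and masks 600–632 nm, where the
second harmonic of a 308 nm pump would fall. The delay grid mixes 20 fs
linear spacing to 1 ps with logarithmic spacing to 5 ps, emulating typical
acquisition. Not emulated: coherent-artifact lineshapes around time zero,
solvent signals, wavelength-dependent noise, and scan-to-scan drift.
Passing recovery tests on these maps therefore demonstrates correctness of
the estimator under the model's own assumptions (plus chirp and masking),
not robustness to every artefact of real data. The DAS shapes are
fixtures: only the lifetimes, IRF and band positions carry over from the
measured system.

## 7. Problem sizes and limitations

The test suite uses desk-scale sizes chosen to exercise every claim: five
synthetic experiments for lifetime recovery; 137 stochastic realizations
(the size of the reference trajectory ensemble) for the kinetic-scheme
lifetime; a 64-trajectory, 1 ps surface-hopping ensemble for conservation
and mechanism checks; 10$^4$ trajectories per velocity for the
Landau–Zener comparison; 10$^4$ realizations for the master-equation
convergence check.

Known limitations: the vibronic model's coordinates are abstract, so no
structural statement (ring puckering, bond inversion) can be made; SOC is
coordinate-independent, so the growth of couplings near crossing seams is
averaged into the constant magnitudes; the exact triplet-yield split among
T1/T2 depends on the underlying ab initio surfaces and is deliberately not
asserted — only the qualitative ordering (triplet majority at 1 ps,
monotone growth with SOC) is claimed; and the flux-based hopping formula,
while exact in the two-state limit, distributes multi-state flux
proportionally to population gains, which is an approximation away from
that limit.
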