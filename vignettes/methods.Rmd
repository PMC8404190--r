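---
title: "Probing a conical intersection with attosecond pulse trains: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing a conical intersection with attosecond pulse trains: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement this package simulates

When a photoexcited molecule passes through a conical intersection (CI),
the nuclear wave packet branches between two electronic surfaces and the
two components form a phase-locked electronic superposition.  The phase
of that superposition advances at the local energy gap, so any observable
sensitive to the cross term between the two components beats in time at
the gap frequency — for a 1 eV gap, with a period of about 4.1 fs.

Time-resolved photoelectron spectroscopy (TRPES) with a single probe
pulse faces a rigid trade-off.  A sub-femtosecond pulse has several eV of
bandwidth: the photoelectron peaks of the two states merge into one broad
band, whose intensity oscillates at the gap frequency (the coherence is
visible, the states are not).  A few-femtosecond pulse resolves the two
peaks, but their photoelectron distributions no longer overlap and the
interference disappears (the states are visible, the coherence is not).

A harmonic comb — an attosecond pulse train (APT) — evades the
trade-off.  Sign-alternating sub-fs bursts spaced by half the IR driving
period `t' = pi / omega_I` produce a comb of narrow teeth spaced
`2 omega_I`.  Each tooth is narrow enough to resolve the states; but when
the electronic gap matches the tooth spacing, the photoelectrons that
harmonic *n* ejects from the upper state land at the same kinetic energy
as those that harmonic *n + 1* ejects from the lower state.  The two
quantum paths end in the same final state and interfere; the overlapped
sideband then oscillates with pump–probe delay at the gap frequency.
Energy resolution and time-domain coherence are obtained simultaneously.
The mechanism is RABBITT-like, but the harmonics themselves interfere —
no IR streaking field is involved, and the (filtered) IR fundamental
never touches the molecule.

## The vibronic model

The package propagates a two-state, two-mode diabatic vibronic model on a
regular grid (mass-weighted coordinates, atomic units internally; eV, fs
and bohr at every interface):

* `V0`: bound Morse potential along the reaction coordinate `R1`
  (depth `D0`, width `a0`) plus a harmonic coupling mode `R2`
  (`omega2`, 0.1 eV);
* `V1`: dissociative exponential along `R1`
  (`B1 exp(-beta1 R1) + C1`) plus the same harmonic mode;
* `W = lambda (R2 - R2w) exp(-(R1 - Rc)^2 / 2 s_c^2)`: linear diabatic
  coupling in `R2`, gated around the diabatic crossing `Rc`;
* `I1`: the ionized surface, chosen exactly parallel to `V1` along `R1`
  and offset so that a 32.9 eV photon ejects 3–9 eV photoelectrons.

The adiabatic transformation of `(V0, V1, W)` closes the gap at
`(R1 = Rc, R2 = R2w)`: a conical intersection.  All dynamics run in the
diabatic basis (smooth potentials, no geometric-phase bookkeeping);
adiabatic populations and the interstate coherence are obtained by
rotating stored snapshots into the local eigenbasis.

**Why the seam offset `R2w` is not optional.**  With `W` proportional to
`R2` and the initial packet centered at `R2 = 0`, every transferred
amplitude carries odd `R2` parity while the parent packet is even, and
the electronic coherence `<psi_lower | psi_upper>` vanishes *identically*
for all time — the symmetric linear-coupling model predicts no
interference signal at all.  Real molecules are not parity-locked to
their CI seam; we displace the seam by `R2w = -0.5` bohr (about 1.3
ground-state widths), which is the generic situation and restores a
finite coherence.

**Calibration.**  The published model's analytical surface parameters
live in supporting information that is not part of the available text,
so the package ships a re-parameterized model calibrated to the printed
observables: diabatic population transfer starting near 5 fs, an
asymptotic adiabatic gap of 1 eV, band branching resolved between 10 and
15 fs, and sideband interference appearing only after 15 fs.
`calibrate_paper_model()` performs the documented deterministic grid
search over the excited-state slope, the coupling center and strength,
and the asymptotic diabatic offset; the search landscape is nearly
degenerate at the sub-fs / sub-0.1 eV level, and the committed
`paper_model` parameter set was fixed once from that family (the
remaining freedom was resolved by the interference-onset behaviour,
which is too expensive for the inner search loop).  The frozen numbers
are committed in `paper_model_params()` so every run is fast and
bit-reproducible.

Two deliberate shape choices matter for the phenomenology:

* the Morse width `a0 = 0.45` makes the gap at the moving packet settle
  slowly (0.6 eV at 12 fs, 0.8 at 15 fs, 0.95 at 25 fs), reproducing the
  published "separation constant at ~1 eV only after 20 fs" and delaying
  the tooth-overlap resonance until after 15 fs;
* `I1` exactly parallel to `V1` pins the excited-state photoelectron
  comb at fixed energies for all delays; the ground-state comb drifts
  down by the gap and re-enters tooth resonance when the gap reaches the
  comb spacing — which is precisely the moment interference switches on.

**Grid.**  256x32 points over `R1 in [-4, 26]`, `R2 in [-2, 2]` bohr,
both masses 1836 a.u.  This is the same point count as a 128x64 grid but
re-shaped: the dissociative `R1` coordinate needs ~30 bohr of range *and*
momentum headroom (the packet reaches ~19 a.u. of momentum, two thirds of
the 26.8 a.u. Nyquist limit), while the bound harmonic `R2` mode is fully
converged with 32 points (sigma/dx ~ 3, checked by grid doubling).

**Known limitation: coherence lifetime.**  A constant ~1 eV asymptotic
gap forces the branched components to differ by ~1 eV of kinetic energy,
so they drift apart in phase space and the coherence decays from ~0.3 at
branching to a ~1.5% plateau.  The published model was explicitly
constructed for long-lived coherence (its surfaces evidently remain
near-degenerate along the packet's path for longer); with the functional
forms used here the decay is unavoidable.  Consequences: the beats in
the overlapped sidebands have depths of a few percent rather than tens
of percent.  They are perfectly measurable in a deterministic
simulation, and every onset/ordering observable survives, but a noisy
experiment would need the larger depths.

## Numerical methods

**Propagation** is a Strang-split Fourier method: half kinetic step in
momentum space, full 2x2 coupled potential step in position space
(closed-form Pauli-decomposition exponential, exact for the pointwise
2x2 matrix), half kinetic step.  The default `dt` of 0.1 atomic time
units (~2.4 as) over-resolves every phase in the problem by two orders
of magnitude; the suite verifies unitarity (norm drift < 1e-9 without
absorber over 30 fs), energy conservation (< 1e-6 hartree), second-order
convergence in `dt` (error ratios 4.0 under halving), and agreement with
a dense matrix-exponential propagator (overlap deficit < 1e-8 after 50
steps on a 16x16 grid).

**Absorbing boundary**: cubic complex absorbing potential on the outer
15% of the `R1` range, 3 eV at the last grid point.  On the calibrated
model less than 1.5% of the norm is absorbed within 45 fs, and
`P0 + P1 + absorbed = 1` holds to 1e-8 throughout.

**Ground state** by imaginary-time propagation with per-step
renormalization, converged when the energy change per step falls below
1e-10 hartree (checked against the exact 2D harmonic zero point to 1e-6
hartree).

**The ionization signal** is first-order time-dependent perturbation
theory, evaluated without further approximation by source-term
propagation on the ionized surface: in the frame rotating at the carrier
`omega_X`,

```
i d/dt psi_I = (T + I1 + omega_p - omega_X) psi_I
              + mu * Ebar(t - T) * (psi_0(t) + psi_1(t))
```

and `S(T, omega_p) = ||psi_I||^2` after the probe has passed.  Both
valence components feed the *same* ion surface coherently — that sum is
the interference mechanism.  The transition dipole `mu` is constant
(the published treatment does the same; Dyson-orbital refinements are
out of scope).  The photoelectron energy enters only as the constant
shift `omega_p - omega_X`.

**Gram-band factorization.**  Evaluating the driven equation separately
for every delay and energy would cost `N_T x N_E` propagations.  Instead
note that the final amplitude is a weighted sum of ion-propagated source
snapshots, so the signal is a quadratic form

```
S(T, omega_p) = dt^2 * sum_{j,k} conj(w_j) w_k G(j,k),
w_j = Ebar(t_j - T) exp(i (omega_p - ref) t_j),
G(j,k) = <U^(k-j) g_j | g_k>
```

in a two-time Gram matrix `G` that depends only on the trajectory and
the model — not on the probe, the delay, or the energy.  `G` is banded:
envelope pairs at lag `tau` carry weight at most `exp(-tau^2/4 sigma_t^2)`,
so lags beyond 6 envelope sigmas (weight < e^-9) are truncated.
`ion_gram()` computes the band with one split-operator step and one
inner-product sweep per source sample; every spectrogram afterwards is
seconds of dense algebra, and one band serves all five bundled probes.
The truncation floors relative signal structure at the ~1e-3 level,
far below the percent-scale beats of interest (the mechanism test in
the suite, which probes sub-percent depths, widens the band).  The
direct driven route is retained as `ionization_amplitude()`; the suite
checks Gram-vs-direct agreement and both against a dense
matrix-exponential oracle.

**Sampling.**  Sources are stored every 1.5 a.u. (0.036 fs; 16 samples
per 0.59 fs burst fwhm).  Delays every 0.5 fs resolve the 4.1 fs beat
eight times per period; energies every 0.05-0.1 eV resolve the 0.44 eV
teeth.

## Probe fields

`gaussian_pulse(fwhm, omega_X)` uses the amplitude-envelope convention
`sigma = fwhm / (2 sqrt(2 ln 2))` — the convention the published pulse
pairs (2.55 fs <-> 6 fs, 0.25 fs <-> 0.59 fs) obey.  `apt_spec()` builds
the train as Gaussian bursts at `k t'` weighted by a Gaussian train
envelope evaluated at the burst centers, with a pi carrier-phase step
between consecutive bursts; that phase alternation is what places the
comb at odd harmonics with spacing `2 omega_I` (a train without it would
sit at even harmonics and the sideband bookkeeping of the measurement
would change).  By default the carrier is the 47th harmonic
(`omega_X = 47 omega_I`); the bundled `fig4_*` presets pin it to 32.9 eV
instead so that all three IR fundamentals (0.5, 0.6, 0.7 eV) ionize into
the same 3-9 eV window of the same model — with `47 omega_I` the 0.5 and
0.6 eV trains would eject electrons at negative nominal energies.  For
`omega_I = 0.7` eV the two conventions coincide (47 x 0.7 = 32.9).

## Operational definitions of the extracted observables

The published onsets ("around 5 fs", "after 15 fs") are visual readings
of figures; the package fixes operational definitions:

* **Population onset** (`onset_time`): first crossing of 5% of the trace
  maximum (1% of total norm for the transfer-time acceptance check),
  linearly interpolated.
* **Band peaks** (`band_peaks`, `top_bands`): local maxima above a
  relative threshold with parabolic sub-bin interpolation; bands ranked
  by time-integrated intensity ("three most intense peaks" = top 3).
* **Modulation analysis** (`modulation_analysis`): band-integrated
  signal, moving-average detrended (default window 8.27 fs, two beat
  periods of a 1 eV gap).  The beat frequency is the dominant DFT
  component over the settled second half of the delay range.  The
  *onset* is the first zero crossing of the detrended trace followed by
  at least four consecutive half-periods within 40% of the dominant
  half-period.  A plain amplitude threshold (the natural first choice)
  is *not* usable here: in a noise-free simulation the population
  -transfer transient — a single slow swing of half-period ~5 fs —
  always exceeds any small threshold ~10 fs before sustained beating
  starts, so it would measure the transfer, not the interference.  The
  zero-crossing rule keys on what actually distinguishes the beat:
  sustained periodicity at the gap frequency.  *Depth* is the
  post-onset peak-to-peak detrended amplitude over twice the mean band
  intensity; the raw `(max-min)/(max+min)` alternative is contaminated
  by residual band drift (on this model it even inverts the
  depth-vs-omega_I ordering).

On the calibrated model these instruments give: transfer onset 5.59 fs;
late-delay band separation 0.94 eV (5.29 fs probe, delays 25-35 fs);
APT(0.5 eV) central-band modulation onset 17.7 fs at beat frequency
0.92 eV with depth 0.052; depths 0.052 / 0.043 / 0.018 for IR
fundamentals 0.5 / 0.6 / 0.7 eV — each number computed by the test
suite and the acceptance script, never hard-coded.

## What the synthetic model does and does not establish

The generator *is* the stated world: no external data enters.  A green
suite establishes that the propagation machinery is numerically exact to
its stated tolerances (against closed forms and dense oracles), and that
the calibrated model reproduces the *mechanism*: population transfer at
5 fs creating a coherence; single-pulse time/energy-resolution
trade-off; comb-resonance-gated interference appearing only once the
gap reaches the tooth spacing; its frequency reading off the gap; its
depth falling as the comb detunes.  It does not establish figure-exact
agreement with the published spectrograms (their surface parameters are
unavailable), absolute photoelectron energies (the ionization potential
is a modeling choice), realistic modulation depths under decoherence
(see the coherence-lifetime limitation), or anything about angular
distributions, multiple ion states, or non-impulsive pumping, which are
out of scope.
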