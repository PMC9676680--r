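---
title: "Modeling venous pulsatile tinnitus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling venous pulsatile tinnitus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Venous pulsatile tinnitus (PT) is a pulse-synchronous somatosound that, in
many patients, originates in the transverse–sigmoid sinus: blood accelerating
through the elbow-like transverse–sigmoid junction (TSJ) and jugular bulb
(JB) generates sound directly (a *hydroacoustic* source, the Lighthill
quadrupole mechanism of unsteady flow), and the fluctuating wall pressure
drives vibration of the vessel wall and of the tissue layers above it (a
*vibroacoustic* source). Clinically the relevant anatomy is a layered wall:
the vascular wall, the dura mater over it, and the thin bony sigmoid plate —
with PT frequently associated with a *dehiscence*, a focal absence of the
plate.

`venacoustics` implements both source mechanisms as a one-way coupled
pipeline on a fully synthetic, two-dimensional stand-in for that anatomy, so
every stage is testable without patient data. The pipeline is:

1. geometry and mesh (`build_geometry()`, `generate_mesh()`,
   `assign_wall_composition()`),
2. pulsatile inlet (`synthesize_waveform()`),
3. transient incompressible laminar flow (`solve_transient()`),
4. hydroacoustics (`lighthill_tensor()`, `assemble_sources()`,
   `solve_acoustic()`, `sample_microphones()`),
5. vibroacoustics (`build_oscillator()`, `forced_response()`,
   `vibro_field()`),
6. band metrics and audio (`band_stats()`, `a_weight_offset()`, `sonify()`),
7. transcanal recording analysis (`stft()`, `band_delta()`,
   `synth_somatosound()`).

`run_pt_pipeline()` executes stages 1–6 under one configuration.

## What the synthetic generators emulate — and what they do not

**Geometry.** The domain is a planar curved conduit of constant 7 mm width
and 120 mm centerline, with two opposite 90° elbows (bend radius 12 mm)
standing in for the TSJ and the JB, and five landmarks (TS, TSJ, SSLO, JB,
IJV) at the segment midpoints. A 7 mm dehiscence patch sits on the lateral
(temporal-bone side) wall just distal to the first elbow. These dimensions
are of the order of a real sinus but are *not* patient values — none are
published for the case the study conditions mimic. Two dimensions retain the
elbow/vortex physics and keep transient solves in minutes; nothing
three-dimensional (secondary Dean flow, out-of-plane curvature, a real
jugular bulb expansion) is represented. The conduit radius is constant; the
mesh generator refuses varying radius profiles rather than silently
mis-solving them.

**Inlet.** One period of a venous, Doppler-like velocity waveform: a
raised-cosine systolic pulse truncated to 8 Fourier harmonics and rescaled
so the time average and maximum match the targets exactly (defaults 0.198
and 0.745 m/s at 70 bpm — field-average values typical of symptomatic
sinovenous flow, used here as waveform calibration targets). A small seeded
per-harmonic jitter (2 %) varies the shape between seeds without moving the
two calibrated targets. Real venous spectra have beat-to-beat variability
and respiratory modulation; the generator is strictly periodic.

**Somatosounds.** `synth_somatosound()` builds a stationary broadband
background (the NO_PT clip, standing in for the recording made during
jugular compression) and adds a pulse-train-modulated narrow-band hum at
225.5 Hz whose in-band spectral excess equals the requested amount. The
excess is *defined* against the same Welch estimator `band_delta()` uses —
the generator calibrates the injected amplitude until the measured peak
excess equals the request, so parameter recovery is exact by construction
and the tests verify the analysis chain, not chance. Levels are relative
(uncalibrated microphone convention); the generator never claims absolute
SPL.

Passing tests on these generators therefore show that the *methods* are
implemented correctly and behave as the physics dictates on clean synthetic
input; they do not show that a patient's geometry or recording would
reproduce any particular number.

## Flow solver

The incompressible Navier–Stokes equations (blood as a Newtonian fluid,
density 1050 kg/m³, dynamic viscosity 3.45 mPa·s) are solved with the
transient laminar method — no turbulence model; peak Reynolds numbers here
are a few hundred. Discretization is a staggered (MAC) grid in
centerline-fitted coordinates $(s, n)$ with metric $h = 1 - \kappa(s)\,n$:

* continuity, advection and the pressure gradient carry the exact metric
  terms, including the centrifugal ($\kappa u^2/h$) and Coriolis-type
  ($\kappa u v/h$) contributions;
* the viscous term uses the scalar Laplacian of each velocity component in
  the metric. The dropped curvature couplings of the full vector Laplacian
  are $O(\kappa \delta)$ corrections to an already small term; the operator
  is exact on straight channels, which is where every quantitative oracle
  (Poiseuille profile, pressure gradient, wall shear) lives.
* time stepping is explicit first-order upwind advection plus explicit
  central diffusion, then an exact discrete projection (sparse Cholesky of
  the metric-aware Poisson operator, factored once). Implicit diffusion is
  unnecessary at these parameters: the explicit diffusion bound (~1 ms) is
  far looser than the advective CFL bound (~0.3 ms), which is checked and
  reported when violated.

Boundary conditions: prescribed inlet velocity (the default profile is the
exact oscillatory plane-channel — Womersley — solution per waveform
harmonic, so the inlet introduces no artificial development region; flat and
parabolic profiles are options), zero outlet pressure, and no-slip rigid
walls (the walls do not feed back on the flow — one-way coupling
throughout). The wall no-slip ghost for diffusion is quadratic, making the
discrete steady Poiseuille solution exact at the wall and the extracted
wall shear accurate to a fraction of a percent.

Defaults: dt = 0.25 ms (snapped to divide the period exactly), three
pulsatory cycles, fields stored at 2 kHz over the second cycle (Nyquist for
the 0–1 kHz observation band) and 200 Hz elsewhere. The first cycle carries
the start-up transient; with the Womersley inlet the cycle-to-cycle L2
velocity difference is already below 10⁻⁴ by cycle 2, comfortably under the
2 % quasi-periodicity criterion.

Mesh defaults: 0.35 mm cells (343 × 20 ≈ 7k cells) for flow, 0.7 mm for
acoustics. A transient solve at these sizes takes roughly one minute on one
CPU; the element-size ladder of the grid-independence protocol is exercised
in the test suite on a smaller channel.

## Hydroacoustics

For an incompressible low-Mach flow the Lighthill stress reduces to
$T_{ij} = \rho u_i u_j$; the entropy term vanishes and the viscous
quadrupole is negligible at these Reynolds numbers (its omission is recorded
in the output metadata). Sources are assembled on the (coarser) acoustic
mesh: velocities are projected, the tensor formed, its divergence taken in
Cartesian components via the chain rule, and the *outer* divergence
evaluated in conservative flux form with boundary fluxes dropped — on rigid
walls the surface term of the variational formulation vanishes, and the
inlet/outlet faces are non-physical truncation boundaries. The conservative
form matters: a naive per-cell double divergence leaves a spurious net
monopole which, in a domain that is acoustically compact below 1 kHz,
dominates the whole low-frequency response. With the flux form the
quadrupole source integrates to zero to machine precision, and a spatially
uniform flow produces exactly no source.

The time-to-frequency map is a Hann-windowed DFT of the selected cycle; bin
spacing is the inverse cycle duration (≈1.17 Hz at 70 bpm), bins cover up to
1 kHz. Each bin gets a Helmholtz solve $\nabla^2 \hat p + k^2 \hat p =
-\hat q$ with $c_0 = 1540$ m/s and $\rho_0 = 1050$ kg/m³ ($c_0$ is an
assumption — soft-tissue/blood sound speed; nothing in the study conditions
fixes it). Rigid walls impose a vanishing normal derivative; the inlet and
outlet carry a first-order impedance-matched (non-reflecting) closure
$\partial p/\partial n = -ikp$, chosen so the truncated conduit does not
ring with spurious duct resonances. Complex systems are solved as real
2N × 2N sparse block systems. Virtual microphones at the five landmark
centerline points interpolate the per-bin complex pressure; SPL is re
20 µPa.

## Vibroacoustics

The wall composition maps the lateral wall to RIGID (vessel leaning against
temporal bone) except a compliant window around the dehiscence:
plate+dura+vessel stacks (PLATE_DURA_VESSEL) flanking a dura+vessel stack
(DURA_VESSEL, the plate absent) over the dehiscence itself; the medial
(brain-side) wall is VESSEL_ONLY in eight equal patches. Layer properties
(thickness mm / density kg·m⁻³ / Poisson / modulus MPa) are 0.1/1868/0.30/
12000 for the plate, 0.7/1174/0.45/70 for the dura, 0.3/1050/0.30/1.26 for
the vascular wall.

Each compliant patch is a locally reacting per-area oscillator
$m\ddot x + c\dot x + kx = p(t)$ driven by the patch-averaged wall pressure
from the flow stage. The areal mass is $\sum \rho_i h_i$ (1.3236 kg/m² for
the full stack). The stiffness combines:

* the fundamental bending mode of the laminated strip over the patch span,
  $k_b = D(\beta/a)^4$ with $D$ from classical lamination about the
  composite neutral axis. Soft patches get simply supported edges
  ($\beta = \pi$); the bone-backed plate stack gets clamped edges
  ($\beta = 4.730$) because the plate is fused to the surrounding mastoid —
  pinned edges are not physical there. This was a genuinely open design
  point; the clamped choice follows the anatomy, and it also keeps an
  order-of-magnitude compliance contrast between the dehiscence and the
  plate-backed stack.
* a hoop-membrane term $\sum E_i' h_i / R^2$ with $R$ the conduit
  half-width. For a thin curved conduit wall, membrane action — not
  flat-plate bending — is the leading restoring force; without it a 15 mm
  span of 1.26 MPa tissue would displace by ~0.25 m under kPa-scale
  pulsatile pressures, which is meaningless in a one-way model. With it,
  displacements land at the tens-of-microns scale for the free medial wall,
  sub-micron at the dehiscence, and nanometers for the plate stack, and the
  class hierarchy (VESSEL_ONLY ≫ DURA_VESSEL > PLATE_DURA_VESSEL) holds
  with ≥10× gaps regardless of the forcing details.

Damping ratio defaults to 0.05 (soft-tissue structural damping; configurable
and recorded in output). The steady-periodic response is computed in the
frequency domain through the closed-form receptance, so the static limit
$p/k$ and the resonance limit $p/(2\zeta k)$ are exact. "Median (low/high)"
displacement statistics are reported as the median with signed cycle
extrema — an interpretation, since the parenthetical convention is never
defined in the source material.

The radiated field solves the same per-bin Helmholtz problem with
vibrating-wall boundary data $\partial p/\partial n = \rho_0 \omega^2
\hat\xi$ per patch (piston motion). One caveat is documented deliberately:
below 1 kHz a 0.12 m conduit is acoustically compact ($kL < 0.5$), so the
radiated vibro field is nearly uniform along the duct. The strong
proximal-to-distal decline lives in the wall forcing and displacement
(strictly monotone from inlet to outlet, driven by the zero-pressure outlet
datum), while the mic-level RMS ordering TS ≥ IJV is preserved only
marginally (~0.05 dB). Mic-level gradients of tens of dB, as described for
3-D patient-specific models in the clinical literature, cannot arise in
this 2-D compact duct; asserting the ordering, not the magnitude, is the
honest desk-scale check.

## Metrics

SPL is $20\log_{10}(p_\mathrm{rms}/20\,\mu\mathrm{Pa})$; A-weighting is the
IEC 61672 closed form, normalized to exactly 0 dB at 1 kHz (no standard is
named in the source material; this is the standard choice). Note that
A-weighting at 20 Hz is about −50 dB: dB→dBA pairs that drop by only ~33 dB
at a 20 Hz peak are inconsistent with the standard curve; the package
follows the standard and the discrepancy in the vibro reference rows is
noted rather than imitated.

Band statistics over 20–1000 Hz report the peak bin, its frequency, and an
RMS. The default RMS convention is the root-mean-square of the per-bin SPL
*values in dB* — with many quiet bins this lands far below the peak, which
is the only convention consistent with peak/RMS pairs like 119.3/82.0 dB
(an energy RMS would be pinned near a single dominant peak). The energy
convention is implemented as an option (`rms_convention = "energy"`), and
`band_delta()` uses energy RMS, where relative uncalibrated levels make the
dB-value convention meaningless.

`sonify()` renders one computed cycle as repeated audio (nine cycles by
default, the duration used for subjective rating of simulated somatosounds),
band-limited FFT resampling, peak-normalized to −1 dBFS, written as 16-bit
PCM WAV.

## Numerical choices and degenerate inputs

* Time step snapped to divide the period; refused with the limiting value
  when it violates the advective CFL or explicit-diffusion bound.
* Projection is a direct sparse Cholesky solve; the post-projection
  divergence is checked at every stored step against 10⁻⁸ (relative).
* Zero-length dehiscence: no DURA_VESSEL patch anywhere downstream.
* Zero inlet: identically zero fields. Zero sources: identically zero
  acoustic fields. Rigid oscillators: identically zero displacement.
* Bins are matched between displacement spectra and acoustic problems with
  a 10⁻⁶ relative tolerance; mismatches are an error, not a silent
  interpolation.
* A singular Helmholtz bin (impossible with the impedance closure, possible
  under all-rigid boundary sets) is skipped with a warning rather than
  aborting the sweep.

## Problem sizes used by the tests

The default study configuration (343 × 20 flow cells, three cycles at
dt = 0.25 ms, 857 acoustic bins on a 171 × 10 mesh) runs in roughly one to
two minutes and is computed once and shared across the test suite. Oracle
tests use smaller straight channels (≈600–2500 cells) where the analytic
solutions are exact, and a 200 × 100 absorbing box for the Green's-function
check. These sizes were chosen so the full suite exercises every stage at
meaningful resolution while staying fast enough to run routinely.

## Known limitations

* Two-dimensional planar geometry; no secondary (Dean) flow, no true bulb.
* Newtonian rheology; venous blood is mildly shear-thinning, which matters
  for wall shear stress more than for flow rate or pressure.
* One-way coupling: wall motion does not act back on the flow.
* Locally reacting single-mode wall patches; no shell FEM, no modal
  coupling between patches, no tissue radiation damping.
* First-order non-reflecting closures; a perfectly matched layer would
  absorb oblique incidence better (the Green's-function check bounds the
  effect at ~4 % over mid radii).
* Far-field transmission through the mastoid to the ear canal is out of
  scope; computed SPLs are intravascular, not ear-canal levels, and the
  transcanal module deliberately works in relative dB only.
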