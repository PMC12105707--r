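---
title: "Stability analysis of cyclic peptide-polymer nanotubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability analysis of cyclic peptide-polymer nanotubes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpnano)
```

## The system and the statistics

Cyclic peptides of alternating D- and L-residues adopt flat rings whose
backbone amides point perpendicular to the ring plane. Rings therefore
stack into nanotubes held together by inter-ring N--H···O=C hydrogen
bonds, in a beta-sheet-like registry. For an 8-residue ring each
ring--ring interface supports up to 8 such bonds, so a stack of `N`
unimers (an octamer: `N = 8`, 7 interfaces) carries at most `8(N-1) = 56`
backbone bonds. The two terminal rings -- the *capping unimers* -- bond
through a single interface each and are the labile component of the
assembly: the 16 bonds of the two cap interfaces break more readily than
the 40 core bonds, and cap dynamics regulate tube growth and shrinkage.

`cpnano` quantifies this picture with:

* **BHB/ns** -- broken hydrogen bonds per nanosecond: the rate of
  present-to-absent transitions of backbone bonds across a trajectory,
  decomposed into cap and core contributions (`broken_bonds_per_ns()`).
* **Mean inter-unimer distance** -- the time-averaged centroid-to-centroid
  spacing of adjacent rings (`mean_interunimer_distance()`), near 4.85 Å
  for a beta-sheet-like stack.
* **Dissociation events** -- sustained drops of the per-frame bond count,
  the signature of a cap leaving the stack
  (`detect_dissociation_events()`); a full cap removes ~8 bonds.
* **Length statistics** -- per-tube length summaries and the conversion
  of a tube length to a stacked-unimer count at the 4.85 Å repeat
  (`summarize_lengths()`, `length_to_unimer_count()`).
* **Core-shell cylinder SANS model** -- the orientation-averaged
  small-angle-scattering intensity of a peptide cylinder wrapped in a
  polymer corona, with synthesis and bounded least-squares fitting
  (`sans_intensity()`, `fit_sans_cylinder()`).

Everything operates on *synthetic* inputs with known ground truth, so
every estimator is validated by parameter recovery rather than by
comparison with (unavailable) atomistic trajectories.

## The idealized geometry

`build_ring()` places `n_residues` amide units on a circle of radius
`radius` (default 4 Å) in a plane. The amide face alternates around the
ring -- the geometric consequence of alternating D/L chirality -- so each
face exposes `n_residues/2` donors (N--H pointing out of the plane, N
offset by `amide_offset`, H one 1.0 Å bond further) and `n_residues/2`
acceptors (C=O pointing out on the opposite parity, O at 1.23 Å from C).
An odd residue count cannot alternate and is rejected.

`stack_rings()` translates copies along +z at `spacing` (default 4.85 Å)
and, in the antiparallel arrangement, flips every second ring by 180°
about an in-plane axis. Flipping swaps the donor/acceptor roles of the
two residue parity classes, which displaces the donor columns by half the
angular residue spacing twice -- a full `360/n_residues`. The default
registry rotation is therefore `360/n_residues` (45° for octapeptide
rings), which restores *head-on* donor-over-acceptor alignment: every
inter-ring N--H···O is exactly linear with an N···O distance of
`spacing - 2*amide_offset - 1.23` Å (2.62 Å at the defaults). A
half-registry rotation of `360/(2*n_residues)` -- an apparently natural
alternative -- leaves each donor 22.5° away from its acceptor column,
bending every bond ~47° off line; such a lattice loses most of its bonds
under modest thermal jitter and was rejected on that ground.

`amide_offset` defaults to 0.5 Å. The choice was made with a Monte Carlo
robustness scan *before* the test suite was frozen: under 0.2 Å Gaussian
jitter per atom coordinate, the per-bond detection probability at the
default criteria peaks near offset 0.5 (≈ 0.97, i.e. a mean of ~54 of 56
bonds detected) and falls off both for larger offsets (the N···O distance
shrinks toward the cutoff's noise floor -- distance is not the limit, the
angle is) and smaller ones (N···O grows toward the 3.5 Å cutoff). These
are constructions, not reproductions: no registry angle or ring radius is
claimed for the real assemblies.

## Hydrogen-bond detection

A bond is counted between a donor (N--H) and an acceptor O on an
*adjacent* ring when the N···O distance is ≤ `d_max` (default 3.5 Å) and
the N--H···O angle at H is ≥ `theta_min` (default 120°) -- the standard
geometric criterion of MD analysis suites; reported counts and break
rates are criteria-dependent, and both cutoffs are explicit parameters.
Each donor H bonds at most once: the closest passing acceptor wins, exact
ties break to the lowest acceptor residue (then ring) index, so detection
is deterministic. Intramolecular pairs never count (at the ideal geometry
the nearest same-ring O fails the angle cutoff by ~26°, and the statistic
of interest is the inter-ring network). The adjacency restriction is an
optimization, not an assumption: the test suite compares the detector
bond-for-bond against a brute-force scan over all ring pairs on hundreds
of jittered frames.

## Synthetic trajectories and their limits

`jitter_trajectory()` displaces every atom coordinate independently with
zero-mean Gaussian noise of s.d. `sigma` (default 0.2 Å) around the ideal
model; frame 1 is unperturbed. Frames are mutually independent -- there
is no temporal correlation, no collective motion, no force field. This
emulates *occupancy statistics* of a thermally fluctuating but stable
stack, and it deliberately does not emulate bond kinetics: because
successive frames are independent, per-frame detection flicker inflates
the raw BHB/ns of a jittered trajectory far above what correlated
dynamics would show. Kinetic questions are asked of the Markov generator
instead, which controls time correlation explicitly.

`script_cap_unbinding()` translates the terminal ring along +z (default
10 Å, far beyond any cutoff) and tilts it from a chosen frame onward --
the minimal representation of the cap-dissociation mechanism (in the real
system, water attacking the terminal interface). It leaves the other
interfaces untouched, giving a clean 56 → 48 step for the event detector
to find. The mean inter-unimer distance of such a trajectory includes the
displaced interface; interpret spacing on stable segments.

`simulate_bond_states()` evolves each bond as an independent two-state
(formed/broken) Markov chain sampled every `frame_dt` ns, with exact
exponential discretization `p = 1 - exp(-k dt)` so rate parameters keep
their meaning at coarse sampling. Cap and core bonds (16 and 40 in the
octamer) may break at different rates; all bonds start formed. Real
hydrogen-bond dynamics are correlated (a broken neighbour destabilizes a
bond) -- independence is a modelling choice that makes ground truth exact.

## The BHB estimator and its validation regime

A break event at window 0 is any present→absent transition; the rate is
events divided by `(n_frames - 1) * frame_dt`, reported per class, per
bond, and in total (cap + core = total exactly). A positive
`flicker_window` requires the absence to persist that many frames,
discarding transient flicker; increasing the window can only decrease the
estimate. Whether re-formation events should be re-counted is a
convention, not a fact -- window 0 counts them, large windows do not, and
both are exposed.

Validation compares the estimate against the stationary continuous-time
expectation `n_bonds * k_break * k_reform / (k_break + k_reform)`. That
oracle holds in the fine-sampling regime: the observed per-frame
transition rate is biased low by O(`k_reform * dt`) because flips that
revert within one interval are invisible. The recovery studies therefore
sample at `dt = 0.005` ns (`k_reform * dt = 0.025`, bias ≲ 0.1 counting
s.e.) over 15 000 frames, spanning `k_break` from 0.005 to 0.5 /ns, and
require agreement within 3 counting standard errors
(`sqrt(events)/time`). The analysis default `frame_dt = 0.1` ns is a
plausible trajectory-saving interval for production use, where the few
per-cent discretization bias is immaterial.

## Event detection

`detect_dissociation_events()` smooths the total count with an 11-frame
running median, then scans for a level at least `drop_threshold` (default
6) bonds below the median of the preceding segment, sustained for
`persistence` (default 50) frames; the magnitude is the drop of medians.
The defaults are set so that a full cap unbinding (8 bonds) triggers
while Markov/jitter flicker of a few bonds does not; the median filter
makes single-frame dips invisible by construction. Multiple events are
found sequentially, each re-basing the baseline on the segment after the
previous event.

## The SANS model

The orientation-averaged core-shell cylinder intensity is

$$I(q) = \frac{10^{-4}\,\mathrm{scale}}{V_\mathrm{total}}
\int_0^{\pi/2} F^2(q,\alpha)\,\sin\alpha\,d\alpha + \mathrm{bkg},$$

$$F = (\rho_c-\rho_s)V_c\, j_0\!\big(qL\cos\alpha/2\big)\,
\Lambda\!\big(qR_c\sin\alpha\big) +
(\rho_s-\rho_\mathrm{solv})V_t\, j_0\!\big(q(L/2+t)\cos\alpha\big)\,
\Lambda\!\big(q(R_c+t)\sin\alpha\big),$$

with $j_0(x)=\sin x/x$, $\Lambda(x)=2J_1(x)/x$, $V_c=\pi R_c^2 L$,
$V_t=\pi(R_c+t)^2(L+2t)$; lengths in Å, SLDs in $10^{-6}$ Å$^{-2}$, the
$10^{-4}$ factor yields cm$^{-1}$. The orientation integral uses
Gauss-Legendre quadrature whose node count scales with the fastest phase,
`max(76, ceiling(0.8 * max(q) * (L/2 + t)))`; a fixed 76-node rule --
adequate for short cylinders -- misses the axial oscillations of an
800 Å cylinder by ~1%, while the scaled rule changes by < 0.01% on
doubling. Instrument resolution smearing and size polydispersity are not
modelled.

Synthesis defaults (`R_core` 30 Å, `t_shell` 20 Å, `L` 800 Å, SLDs
1.8/5.5/6.36, scale 0.003, background 0.05 cm$^{-1}$) describe a peptide
cylinder in a strongly hydrated polymer corona in D$_2$O and were chosen
once so that the recovery study is well conditioned: the two contrast
terms contribute comparable amplitude, so both radii shape the curve. A
corona of dry-polymer SLD would leave the core below 1% of the amplitude
and its radius unidentifiable at realistic noise -- a genuine feature of
near-contrast-matched systems worth knowing when interpreting real fits.
Curves are synthesized on 100 log-spaced points over
$q \in [3\times10^{-3}, 0.5]$ Å$^{-1}$ with multiplicative Gaussian noise
(`dI = rel_noise * I`). Fitting is bounded weighted least squares
(Levenberg-Marquardt) on `(I_obs - I_model)/dI` with SLDs fixed by
default. Noiseless curves refit their generating dimensions to machine
precision; at 5% noise the median recovery over seeds is a few per cent
for `R_core` and `t_shell`. `L` is recoverable here because
$q_\mathrm{min} L \approx 2.4 \lesssim \pi$; for much longer cylinders
only $q_\mathrm{min}^{-1}$-scale lower bounds survive. Individual noisy
fits can land in secondary minima (observed: ~1 seed in 10 at 1.5×
perturbed starts), which is why recovery is summarized by medians.

## Study sizes and determinism

The shipped analyses use an octamer (256 backbone sites), trajectories of
1000 frames at 0.1 ns, Markov simulations of 15 000 frames, 200-tube
length samples, and 10-seed fit-recovery studies -- sizes at which every
statistic is stable to well under its acceptance tolerance and the whole
workflow runs in minutes on one core. Every stochastic operation takes an
explicit integer seed and touches no global RNG state; identical seeds
give byte-identical outputs, and `run_pipeline()` stamps each JSON output
with an MD5 hash of its full configuration.

## Known limitations

* Geometry is a construction: no claim is made about the real registry
  angle, ring radius, or amide offset of the assemblies.
* Jitter frames are time-uncorrelated; jittered-trajectory BHB values
  measure detection flicker, not kinetics.
* Markov bonds are mutually independent; cooperative breaking is not
  modelled.
* The water-attack mechanism is represented only as a scripted
  geometric event.
* Reported bond counts and break rates depend on the geometric criteria
  (`d_max`, `theta_min`); there is no energetic bond definition.
* SANS fits are unsmeared and monodisperse; polymer-chain scattering
  beyond the uniform-shell approximation is absent.
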