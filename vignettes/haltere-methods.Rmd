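---
title: "Haltere dynamics and spike-timing prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haltere dynamics and spike-timing prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halteredyn)
```

## The problem

Flies sense body rotations with their halteres: club-shaped organs,
evolved from hindwings, that are flapped antiphase to the wings. When the
body rotates while the haltere flaps, Coriolis-type inertial forces bend
and twist the stalk by tiny amounts, and fields of campaniform sensilla
(cuticular strain sensors) at the haltere base transduce the resulting
strains into spikes. `halteredyn` implements a reduced-order model of this
whole chain: prescribed flapping and body rotation, rotating-frame
inertial loads on a distributed-mass haltere, linear structural dynamics
of the stalk, strain recovery at the base, and a two-stage
linear–nonlinear model of spike generation. The package is aimed at
readers who want to reproduce and probe the mechanics of timing-based
rotation encoding rather than at fitting data from a particular animal.

## Structural model

### Geometry and cross-sections

The reference haltere is a hollow circular stalk (outer radius 150 μm,
inner radius 50 μm) carrying a rigid bulb whose centre of mass sits
$x_d = 5\,\mathrm{mm}$ from the clamped base. The material is linear
elastic cuticle: $E = 1.5\,\mathrm{GPa}$, $\rho = 1200$ kg m⁻³,
$\nu = 0.33$. Two stalk cross-sections are built in:

* **CS** — the circular annulus, with $I_y = I_z = \pi(r_o^4-r_i^4)/4$
  and torsion constant $J = 2I$ (closed section, torsionally stiff);
* **PS** — a plus-shaped (cruciform) open section of two orthogonal
  rectangles (height 481 μm, thickness 40.8 μm, aspect ratio ~12),
  dimensioned to match the annulus' bending moment $I$ while its
  Saint-Venant constant, from the thin-open-section membrane-analogy
  result $J = 2\,k(h/t)\,h t^3$ with
  $k(a) = \tfrac13(1 - 0.63/a + 0.052/a^5)$, is ~38× smaller.

```{r sections}
cs <- annulus_section(150, 50)
ps <- plus_section(481, 40.8)
c(I_ratio = cs$I_y / ps$I_y, J_ratio = cs$J / ps$J)
```

The cruciform $J$ deliberately ignores warping restraint and the junction
correction at the cross centre; a Prandtl stress-function finite-difference
oracle in the test suite shows the formula sits ~4–5% below the exact
Saint-Venant value, which is the usual accuracy of the thin-strip
approximation and irrelevant next to the 38× contrast being studied.
`match_second_moment()` exposes the inverse design problem (find $h, t$ at
a given aspect ratio matching a target $I$); solving it for the annulus'
$I$ gives $h \approx 487$ μm, slightly above the 481 μm used by the
standard geometry, so the package keeps the printed 481 × 40.8 dimensions
for all scenarios and leaves the matcher as a separate tool.

Bulb variants are a 500 μm sphere and equal-volume prolate ellipsoids
(semi-major axis 1000 μm — the only reading that conserves the sphere's
volume, giving semi-minor axes $\sqrt{500^3/1000} \approx 353.6$ μm),
oriented vertically (long axis in the stroke plane) or horizontally
(lateral), and optionally mounted asymmetrically with the centre of mass
offset 150 μm along the long axis. The bulb is rigid: its mass, principal
inertia and offset enter the distal node exactly through a rigid-link
(master–slave) 6×6 mass block with translation–rotation coupling, not
through penalty springs, so no artificial stiffness parameter exists. The
stalk is meshed over the full base-to-COM distance with the bulb lumped at
the distal node; compared with a geometry in which the stalk stops at the
bulb surface this overestimates stalk mass by ~10% of a contribution that
is itself a quarter of the response, and it keeps the deformation-angle
definitions exact.

### Kinematics and loads

The base plate flaps the haltere as
$\phi(t) = A_f \sin(2\pi f_\phi t)$ with $A_f = \pi/2$ and
$f_\phi = 40$ Hz, while the body yaws at $\dot\theta = \Omega$ (0 or
10 rad s⁻¹) about the global Z axis. Both motions are ramped from rest by
a C²-continuous quintic smoothstep over two flapping periods; runs last
ten periods and all quantities are measured over the final five (the
post-transient window). The ramp length and window are package choices —
the transient decays within a period or two at these damping levels — and
every simulation uses $dt = 10^{-5}$ s (250 steps per flapping period) so
that millisecond-scale spike-timing shifts are resolved with margin;
sub-sample spike times come from quadratic peak interpolation.

In the haltere-fixed frame the angular velocity is
$\omega = (-\dot\theta\sin\phi,\ \dot\phi,\ \dot\theta\cos\phi)$, and a
point fixed at $r$ experiences
$a = \dot\omega \times r + \omega \times (\omega \times r)$: the Euler
term drives the large in-plane bending at $f_\phi$, the centrifugal term
tensions the stalk at $2f_\phi$ (plus a constant offset), and the
$\dot\phi\,\dot\theta$ cross terms — the Coriolis-type loading — push the
stalk out of plane at $2f_\phi$ with a sign that follows the rotation
direction. Loads are evaluated on the undeformed configuration and the
Coriolis coupling of *elastic* velocities with the frame rotation is
neglected: deflections stay below 0.01 rad, making those terms second
order. This linearisation is one known (small) source of discrepancy with
a fully nonlinear 3D solution.

### Finite elements and time integration

The stalk is discretised into 31 (by default) two-node 3D Euler–Bernoulli
beam elements — axial, Saint-Venant torsion, and two cubic-Hermite bending
planes, 12 DOF per element, consistent mass including the cross-section's
polar rotary inertia. Slenderness justifies the kinematic hypothesis
(L/d ≈ 17; a Timoshenko shear correction would move results by <1%).
Damping is stiffness-proportional Rayleigh, $C = \alpha_k K$ with
$\alpha_k = 10^{-5}$ s, so mode $i$ decays with
$\zeta_i = \alpha_k \omega_i/2$; the base node is fully clamped. Dynamics
use average-acceleration Newmark ($\gamma = 1/2$, $\beta = 1/4$):
unconditionally stable, no algorithmic dissipation, one Cholesky
factorisation reused every step. The first bending mode sits near 700 Hz,
far above both drive lines (40/80 Hz), so the response is quasi-static and
mesh convergence is rapid (31 → 62 elements moves the in-plane
peak-to-peak by well under 2%).

Deformations are summarised as the bulb angles
$\Delta\phi = \arctan(\delta_z/x_d)$ (in-plane),
$\Delta\theta = \arctan(\delta_y/x_d)$ (out-of-plane) and the twist
$\Delta\gamma$, computed from the z′ deflection difference of two
rigid-body points at the bulb's ±y′ semi-axis divided by their
separation — which reduces to $\arctan$ of the distal torsion DOF. The
arctangent rather than a literal tangent of the deflection ratio is the
only dimensionally sensible reading, and at $10^{-2}$ rad the two are
identical to $10^{-6}$. Surface strain at span position
$x_s = 300\ \mu\mathrm{m}$ (inside element 2 of 31) and circumferential
angle $\alpha$ (0 = dorsal, $\pi/2$ = lateral) is recovered from the
element shape functions as
$\epsilon_{xx} = u_x' - c\cos\alpha\,\kappa_z - c\sin\alpha\,\kappa_y$,
the Euler–Bernoulli bending-strain relation $\epsilon = -z\,w''$ applied
in both planes plus the axial stretch; 16 equally spaced $\alpha$
positions are sampled by default.

## What the simulations show

```{r headline, eval = FALSE}
rf <- run_scenario("cs_flap")   # flapping only
rr <- run_scenario("cs_rot")    # + 10 rad/s yaw
rf$summary$p2p_dphi             # ~0.0104 rad in-plane, at 40 Hz
rr$summary$p2p_dtheta           # ~5.4e-4 rad out-of-plane, at 80 Hz
rr$summary$p2p_dgamma           # ~5.8e-6 rad twist, at 40 Hz
```

Flapping alone bends the stalk in plane by ~0.01 rad peak-to-peak and
produces *exactly* no out-of-plane bending or twist for symmetric bulbs —
in the linear model the lateral load rows are identically zero, so the
package's "silent modes" are machine-precision zeros rather than small
numbers. Adding the 10 rad s⁻¹ yaw produces out-of-plane bending at twice
the flapping frequency, linear in $\Omega$ and sign-reversing with it,
and a twist whose amplitude is set by the torsion constant: the cruciform
stalk twists ~38× more than the annulus under identical excitation.
Asymmetric bulbs add centrifugally driven modes that exist *without* any
body rotation: a lateral COM offset bends the stalk out of plane at
$2f_\phi$ (with a constant lateral torque offset), and a vertical offset
perturbs the in-plane bending by ~$10^{-4}$ rad.

One headline ratio deserves a caveat. The in-plane to out-of-plane
peak-to-peak ratio under these conditions is essentially kinematic for
any linear, quasi-static, distributed-mass beam model: both loads scale
linearly with spanwise position, so the ratio collapses to
$A_f\omega^2 / (2\Omega \max_t|\dot\phi\sin\phi|) \approx 19.4$
($\omega = 2\pi f_\phi$), and the simulation returns 19.2. Reported
values for the equivalent 3D solid-element computation are nearer 25;
within this model class no parameter consistent with the stated
kinematics reaches that value, and the package reports its own number
rather than adjusting toward it.

## Neural encoding model

Each circumferential position is read out by the same two-stage cascade.

**Linear stage.** The strain history is correlated with a unit-norm
spike-triggered average (STA). The measured STA of cranefly haltere
campaniforms is published only as a normalised curve, so the package
generates a Gabor-like stand-in
$g(\tau) \propto e^{-(\tau-\tau_0)^2/2\sigma^2}
\sin 2\pi f_{STA}(\tau-\tau_0)$ — defaults: 20 ms window,
$\tau_0 = 8$ ms, $\sigma = 3.5$ ms, $f_{STA} = 45$ Hz. These defaults are
deliberate: the projection
$\xi(t) = \langle w_t, g\rangle / \lVert w_t \rVert$ is a windowed cosine
similarity, and for the lateral sensilla to respond to the $2f_\phi$
Coriolis signature at all, the filter must keep a substantial normalised
response at both 40 and 80 Hz. Long, narrowband windows cannot do this
(over a window long enough to make the two frequencies orthogonal,
$c_{40}^2 + c_{80}^2 \le 1$, so both responses cannot clear the spike
threshold of 0.676 below), which is why the window is one flapping period
and the wavelet broadband, slightly above $f_\phi$. With these defaults
$c_{40} \approx 0.78$ and $c_{80} \approx 0.74$.

**Amplitude sensitivity.** A pure cosine is scale-free, but spike
*presence* in the real system is not: the flapping-only lateral strain is
a clean $2f_\phi$ sinusoid (centrifugal tension $\propto \dot\phi^2$) of
~3 μstrain amplitude — the same *shape* as the rotation-driven lateral
signal, only ~6× smaller — so no purely scale-invariant readout can be
silent without rotation yet fire with it. The package therefore
multiplies $\xi$ by a series-level saturating sensitivity gate
$g(r) = r^4/(r^4 + \epsilon_0^4)$ on the RMS strain $r$, with the
detection floor $\epsilon_0 = 5$ μstrain sitting between the
axial-tension background (~2.4 μstrain RMS) and the Coriolis-driven
lateral signal (~16 μstrain RMS); campaniform mechanical thresholds are
of this microstrain order. Because the gate is a single number per
series it rescales $\xi(t)$ uniformly: spike *times* remain exactly
invariant under any positive rescaling of the strain (multiplying a
series by a constant never moves a spike), while spike *existence*
encodes absolute amplitude. This is the one deliberate departure from a
fully scale-free readout, and the tests exercise both halves of the
contract.

**Nonlinear stage.** Firing probability follows the sigmoidal decision
function $P = P_{max}/(1+e^{-(\xi-\xi_0)/k})$ with $\xi_0 = 0.5$,
$k = 0.08$, $P_{max} = 1$; a spike is placed at each strict local maximum
of $P$ that exceeds 0.9 (so $\xi$ must exceed ~0.676), refined by
quadratic interpolation, with plateaus collapsing to their midpoint.
The NLD parameters were chosen once so that a strain cycle well matched
to the STA crosses threshold exactly once per cycle; they are exposed in
the configuration together with every filter parameter.

With this cascade the simulated strains reproduce the circumferential
firing pattern: dorsal and ventral positions fire once per cycle in
antiphase and do not move their spike times under rotation; intermediate
positions acquire timing shifts that grow toward the lateral margin
(~0.06, 0.12, 0.23 ms at $\alpha = \pi/8, \pi/4, 3\pi/8$ with mirrored
signs on the other side, inside the 0.2–1 ms range reported for this
system); and the lateral margin itself is silent without rotation but
fires at twice the flapping frequency with it.

```{r encoding, eval = FALSE}
spikes <- encode_runs(rf, rr, neural_filter())
spikes[, c("alpha", "n_flap", "spikes_per_cycle_rot", "mean_shift_ms")]
```

## Synthetic data

`make_strain()` generates series with the structure the simulations
produce — dominant $f_\phi$ line, small $2f_\phi$ quadrature component
(default relative amplitude 1/25, mirroring the in-plane/out-of-plane
ratio), constant tensile offset, optional seeded white noise — so the
encoding stage is testable without running the solver, including a
brute-force reference implementation of the whole projection chain and a
byte-reproducible fixture bundle (`reference_pipeline_fixture()`). What
the synthetic signals do *not* emulate: broadband structural noise,
cycle-to-cycle variability of real flapping, electrophysiological jitter,
or the white-noise stimulus statistics under which real STAs are
estimated. Passing tests therefore demonstrate the mechanics of the
pipeline, not fidelity to any particular recording.

## Numerical choices and degenerate inputs

* Time step $10^{-5}$ s, 31 elements, 10 periods, 5-period analysis
  window: a full scenario is ~200 DOF × 25 001 steps and runs in seconds;
  the whole scenario matrix stays well inside a desk-machine budget.
* The Newmark effective stiffness is factorised once per run; divergence
  (any non-finite state) aborts with the offending step index.
* Degenerate geometry (zero wall thickness, $h \le t$, zero bulb y′
  semi-axis for the twist angle, strain positions outside the stalk,
  series shorter than the STA window) raises immediate errors rather than
  propagating nonsense.
* All configuration lengths are micrometres (the natural unit of the
  geometry); everything is converted to SI at model assembly so the
  assembled operators are well conditioned.
* The solver is fully deterministic; randomness exists only in the
  synthetic-strain noise and is always routed through an explicit seed
  that leaves the session RNG untouched.

## Known limitations

Beyond the linearisations already noted: no aerodynamics or gravity, no
stress stiffening under the centrifugal tension, no warping restraint of
the open section, a single haltere without wing coupling, yaw-only body
rotation, and a stand-in STA/NLD whose absolute timing numbers should be
read as order-of-magnitude predictions — the range check against the
published 0.2–1 ms band, not the exact per-position values, is the
meaningful comparison.
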