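---
title: "Models and methods: inhibitory control of evoked traveling waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: inhibitory control of evoked traveling waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eiwaves)
```

## The scientific problem

A localized stimulus to cortical tissue can evoke a wave of activity that
travels over distances far larger than any single axonal arbor.  In healthy
tissue these waves are *sparse* — only a small fraction of excitatory
neurons fire as the wave passes — and tightly controlled by recurrent
inhibition and by spike-frequency adaptation.  When inhibition is reduced,
participation rises toward 100% and the dynamics resemble seizure
propagation; when negative feedback is too strong, propagation fails
altogether.  `eiwaves` implements a ladder of four model descriptions of
this phenomenon so that the same mechanism can be studied at the level of
spikes, rates, fields, and closed-form wave analysis:

1. a **spiking network** of 400 excitatory (E) and 80 inhibitory (I) theta
   neurons on the unit interval with distance-dependent random synapses;
2. its **space-clamped mean-field reduction** — three variables
   $(s_e, s_i, z)$ for the population-averaged synaptic gates and
   adaptation;
3. the **1-D neural field**, the same kinetics coupled in space through
   normalized convolution kernels;
4. the **step-function (Heaviside) model**, a piecewise-constant caricature
   of the field whose traveling pulses and their stability are computable
   in closed form through an Evans function.

## The spiking network

Each neuron is a quadratic integrate-and-fire cell written in its phase
(theta) form, $V = \bar V + \tfrac{E_T - E_L}{2}\tan(\theta/2)$ with
$\bar V = (E_L + E_T)/2$, so that the spike (the passage of $V$ through
$+\infty$ and reset at $-\infty$) becomes the smooth crossing of
$\theta = \pi$:
$$C_m \dot\theta = -g_L\cos\theta + (1 + \cos\theta)\, G_{\rm tot}(t),
\qquad G_{\rm tot} = \frac{2 I_{\rm tot}}{E_T - E_L}.$$
Synapses are *current-based* with driving forces frozen at $\bar V$ — the
choice that later makes the mean-field reduction exact in form.  The total
current onto a cell of population $\beta$ is
$$I_{\rm tot} = g_{\beta e}\gamma_e^{\rm raw} (W s_e)
 - g_{\beta i}\gamma_i^{\rm raw} (W s_i)
 - g_{ad}\gamma_z^{\rm raw} z \,[\beta = e]
 + I_{\rm stim}(t) + \zeta_\beta \Xi(t),$$
with $\gamma^{\rm raw} = (57.5, 17.5, 27.5)$ mV the absolute driving
forces.  Each spike increments the cell's outgoing gate (and its
adaptation, for E cells) by one; gates decay exponentially with
$\tau_e = 3$, $\tau_i = 4$, $\tau_z = 50$ ms.  Integration is
Euler–Maruyama at `dt = 0.05` ms with the noise scaled by $\sqrt{dt}$.

Connectivity is Bernoulli with distance-dependent probabilities
($0.35\,e^{-10|x-y|}$ for E$\to$E, $e^{-10|x-y|}$ for E$\to$I,
$e^{-20|x-y|}$ for both inhibitory projections), drawn once per seed with
one independent draw per ordered pair, self-connections allowed.  A cell in
the interior then receives on average about 27 E and 8 I inputs if
excitatory, and about 80 E and 8 I inputs if inhibitory; cells near the
domain ends receive about half that, which is why waves thin out near the
edges.

Two printed-parameter ambiguities are resolved as follows and exposed as
arguments: the recurrent excitation is quoted both as 0.2 (parameter table)
and 0.15 (text); `spiking_params()` defaults to 0.15 and the wave
experiments of the acceptance analyses use 0.2, with which the evoked wave
at high inhibition ($g_{ei} = 2$) crosses the domain in a few tens of
milliseconds with roughly 10% excitatory participation.  The inhibitory
noise amplitude is printed ambiguously ("0.50.05"); the default is
$\zeta_i = 0.5$ (both readings give indistinguishable wave statistics —
the wave is driven by synaptic input, not noise, at these amplitudes).

**Stimuli.**  The standard wave-evoking stimulus is a square current pulse
to the first 20 E cells at $t = 5$ ms.  Its amplitude is a free choice; we
use 20 (current units) for 3 ms, strong enough to make the stimulated cells
fire within 1–2 ms.  The *priming probe* is 10 cells wide, 5 ms long, and
its amplitude (0.3) is deliberately below the saddle-node current
$I^* = g_L(E_T - E_L)/4 = 0.375$, so that in the absence of a wave it can
depolarize but never fire a resting cell.  The probe is intended as a
readout of the wave's spatiotemporal excitability trace: a cell recently
depolarized by a passing wave should be easier to push over threshold.  In
practice this facilitation is weak in the default calibration — the cells
that a sparse wave depolarizes without firing are precisely the ones being
clamped by strong recurrent inhibition (tens of conductance units against
a probe of order one), and the phase-model gain $(1+\cos\theta)$ throttles
any current injected near the top of the depolarization — so
`priming_probe()` exposes amplitude, width and timing as free parameters
and the shipped tests assert only the guaranteed half of the
discrimination (the probe alone never fires a resting cell).

**Wave metrics.**  `participation_fraction()` counts E cells with at least
one spike within 100 ms of stimulus onset.  `transit_time()` takes the
median first-spike time of E cells in a band around each landmark; because
participation at high inhibition is ~10%, a 10-cell band is frequently
silent, so the wave-level analyses use 40-cell bands (about 4 spiking
cells).  `raster_front_speed()` provides an independent least-squares
estimate from all first spikes.

## The mean-field reduction

The rate function of a noisy QIF population is
$$F(G, \zeta) = \frac{1}{\pi}\Big[\tfrac12\big(\mu +
\sqrt{\mu^2 + \zeta^2}\big)\Big]^{1/2}, \qquad
\mu(G) = \frac{g_L}{2 C_m^2}\Big(G - \frac{g_L}{2}\Big),$$
with all inputs in *input-conductance units* $G = 2I/(E_T - E_L)$.  At
$\zeta = 0$ this is exactly the deterministic firing rate (verified in the
test suite against direct quadrature of the passage time); for $\zeta > 0$
it is positive and smooth everywhere, which both models noise-induced
firing and provides the differentiability that the wave continuation needs.

The **single most consequential unit convention** in the package is that
the driving-force factors of the mean field are measured in units of
$(E_T - E_L)/2 = 7.5$ mV: $\gamma_e = 57.5/7.5$, $\gamma_i = 17.5/7.5$,
$\gamma_z = 27.5/7.5$.  This is forced by the composite gains of the
normalized step-function model, $\kappa_\beta = a_1\tau_\beta\gamma_\beta =
(0.92,\ 0.37333,\ 7.333333)$, together with $a_2 = 0.12$ being on the same
scale as $G$.

The space-clamped kinetics are
$$\dot s_e = -s_e/\tau_e + F(g_{ee}\gamma_e s_e - g_{ei}\gamma_i s_i -
g_{ad}\gamma_z z, d_e),$$
and similarly for $s_i$ (no adaptation) and $z$ (same input as $s_e$;
a printed variant with $\gamma_i$ multiplying $s_e$ in the adaptation
input is available behind `local_params(z_input = "literal")` but is not
the default, since the adaptation is stated to be driven by the excitatory
input).  Mean-field couplings keep the spiking values except
$g_{ee} = 1$ and $g_{ad} = 0.25$.

**The noise-smoothing parameters $d_e, d_i$** of the rate function are not
fixed by any printed constant, and the model is genuinely sensitive to
them: the slow adaptation multiplies any background rate by $\tau_z = 50$,
so too large a $d$ buries the rest state under tonic adaptation and
inhibition and the medium cannot propagate at all, while the deterministic
limit $d = 0$ breaks differentiability.  We fixed $d_e = d_i = 10^{-4}$
(units of $\mu$, ms$^{-2}$) once, on three model-validity grounds, and did
not revisit it: (i) the rest state is quiescent (≈0.3 Hz background, rest
$s_e \approx 10^{-3}$); (ii) the standard initial block evokes a traveling
pulse across the default parameter regimes; (iii) the pulse speed of the
boundary-value continuation matches the direct field simulation to well
under 1% at the default point (0.6495 vs 0.65 space units/ms).

`find_equilibria()` locates and classifies the equilibria by multi-start
damped Newton over a box.  Note that the adaptation coordinate of the
elevated (seizure-like) equilibrium is $O(\tau_z F) \approx 5$, so the
search box extends much further in $z$ than in the gates.  The structure
reproduced at the defaults: excitable kinetics at $(g_{ei}, g_{ad}) =
(2, 0.25)$; three equilibria with a saddle near $(0, 0.005)$ for
adaptation removed; a unique stable rest for inhibition removed; and
bistability (a stable state with $s_e > 0.1$) at low values of both.

## The neural field

Space enters through unit-mass kernels, exponential $e^{-|x|}/2$ or
Gaussian $e^{-x^2}/\sqrt{\pi}$, scaled by footprints $\sigma$; the
excitatory footprint $\sigma_e = 1$ sets the space unit (≈1/10 of the
spiking domain).  The default domain is $[0, 80]$ with $dx = 0.2$.  The
convolution is **truncated at the boundaries** (no periodic wrap, no
renormalization): waves genuinely interact with the domain ends, which is
what produces the boundary-reflected zigzag regime at low adaptation.  The
integrator is classical RK4 at `dt = 0.05` ms; the dense kernel matrix is
applied by BLAS.  Halving $dx$ moves the measured speed by well under 1%
(tested).

`classify_outcome()` tracks the crest (spatial maximum of $s_e$ above 3×
the rest level) and distinguishes steady pulses (crest amplitude constant),
modulated pulses (peak-to-peak crest variation above 5% of its mean over
the post-transient window), propagation failure, fronts (the medium stays
active behind the crest), zigzag waves (crest direction reversals) and
stationary stripes (time-stationary multi-peaked end state).  Speeds come
from a least-squares fit of crest position over the domain interior.

At the defaults the field reproduces the expected phenomenology: a sparse
steady pulse at $(g_{ei}, g_{ad}, \sigma_i) = (2, 0.25, 0.5)$; faster
exponential-kernel than Gaussian-kernel waves; slowing with widening
inhibition; fronts at low $(g_{ei}, g_{ad})$; stripes at $g_{ad} = 0$ and
large $\sigma_i$.

## Traveling pulses as homoclinic orbits

For the exponential kernel the convolution can be inverted
($\sigma^2 S'' = S - s$), turning the wave equation in the comoving
coordinate $\xi = x + ct$ into a seven-dimensional ODE whose rest point has
a 2-dimensional unstable and 5-dimensional stable manifold (1 and 4 when
$\sigma_i = 0$).  A pulse is a homoclinic orbit.  The package computes it
in three stages (`lift_and_refine()`):

1. **Reduced-system shooting** (`shoot_5d`): with $\sigma_i = 0$ the
   unstable manifold is one-dimensional, and the pulse speed is bracketed
   by the *qualitative departure direction* of the shot orbit — below the
   pulse speed the orbit relaunches a second excursion (the convolution
   deviation escapes upward), above it the orbit departs downward.
   Bisection on this boundary is robust to $10^{-8}$ in $c$ and also
   exposes the slow (unstable) pulse as the window's other edge.  A
   quantitative Newton iteration on unstable-eigenvector projections at a
   return point was tried first and abandoned: with a rate function this
   close to a kink, nonlinear mixing along the return contaminates the
   projections at any usable return distance.

2. **Collocation boundary-value refinement** (`tw_bvp_refine`): midpoint
   collocation on $\xi \in [0, L_\xi]$ ($L_\xi = 50$, $N = 700$ by
   default), with the left end anchored on a circle of radius
   $\delta = 10^{-4}$ in the unstable eigenplane (angle $\phi$ unknown)
   and unstable left-eigenvector projection conditions at the right end.
   Unknowns are $(c, \phi)$ plus the mesh profile; the sparse Newton system
   is solved exactly.  Converged residuals are $10^{-10}$ or better, and
   doubling $L_\xi$ moves $c$ by under $10^{-4}$.  Eigenvector
   orientations are canonicalized (largest-magnitude component positive) —
   without this, arbitrary sign flips in the LAPACK eigenvectors break the
   continuity of $\phi$ along branches.

3. **Pseudo-arclength continuation** (`continue_branch`) in any of
   $g_{ei}$, $g_{ad}$, $\sigma_i$ jointly with $c$, which rounds folds
   (detected by the reversal of the parameter progression and refined by a
   local quadratic fit) and flags pulse-to-front transitions when the
   orbit's excursion plateau exceeds a threshold length.

At the default point the branch continued in $g_{ei}$ folds at
$g_{ei} \approx 4.76$, where the fast (simulation-stable) and slow branches
meet; beyond it no pulse exists.  With adaptation removed the pulse gives
way to a front as $g_{ei}$ decreases; because the collocation mesh cannot
resolve the $\sim 0.01$-unit internal layer that forms along the wake at
$g_{ad} = 0$ (the wake re-crosses the rate function's near-kink at
threshold), the transition point is located instead by bisection on the
simulated outcome (`front_transition_sim`), which lands near
$g_{ei} \approx 2.7$, consistent with the local kinetics being bistable
there.

## The step-function model and its Evans function

Replacing $F$ by $a_1 H(G - a_2)$ with the calibrated plateau
$a_1 = 0.04$ spikes/ms and threshold $a_2 = 0.12$, and rescaling
$s_\beta = a_1 \tau_\beta \hat s_\beta$, gives the normalized model whose
gates lie in $[0, 1]$ and whose couplings collapse into
$\kappa_\beta = a_1\tau_\beta\gamma_\beta$.  A traveling pulse is fully
described by the quadruple $(c, a, b, d)$: the excitatory threshold input
$I_e$ is positive on $(0, a)$ and the inhibitory one on $(b, d)$.  The gate
profiles are piecewise exponentials, their kernel convolutions are sums of
elementary closed forms (`conv_step`, `conv_expstep`, verified against
adaptive quadrature to $10^{-8}$), and the four conditions
$I_e(0) = I_e(a) = I_i(b) = I_i(d) = 0$ are solved by damped Newton with
transversality and interior-sign checks.  At the default gains the
solution is $(c, a, b, d) \approx (0.941, 6.21, 3.46, 6.20)$, whose speed
matches the step-function field simulation to 0.5%.

Linearizing about the pulse turns each perturbation mode into a pair of
decaying exponentials with complex constants
$\zeta_\beta = c\tau_\beta/(\lambda\tau_\beta + 1)$ launched at the
threshold crossings; self-consistency of the four jump amplitudes yields a
$4\times4$ matrix $M(\lambda)$ and the Evans function
$E(\lambda) = \det(M(\lambda) - I)$, whose roots are the eigenvalues of
the wave.  The adaptation drive is convolved with a narrow kernel
($\sigma_z = 10^{-3}$) so the jump coefficients stay continuous at the
crossings.  Two structural identities validate the assembly: $E(0) = 0$ to
$10^{-14}$ at every computed pulse (the translation mode exercises every
entry of $M$, including the relative $\tau_e/\tau_z$ scaling of the
adaptation jumps), and $E(\bar\lambda) = \overline{E(\lambda)}$.
`find_eigenvalues()` grids a rectangle, intersects the zero contours of
the real and imaginary parts cell-wise, and polishes candidates by complex
Newton with central-difference derivatives; the rectangle is clipped to
the region where every mode convolution converges,
$\mathrm{Re}\,\lambda > -1/\tau_\beta - c/\sigma_\beta$.

`track_eigenvalue()` follows the leading oscillatory pair along a
parameter with warm-started pulse solves and step halving;
`hopf_crossing()` bisects a sign change of its real part, and
`hopf_curve()` maps the crossing in a two-parameter plane.

### A stability finding, and a limitation

At the default gains $(g_{ei}, g_{ad}) = (2, 0.25)$ the leading
oscillatory eigenvalue pair approaches the imaginary axis as the
inhibitory footprint $\sigma_i$ grows — its imaginary part is ≈0.45–0.5
rad/ms around $\sigma_i \approx 1.5$–1.8, a ~14 ms modulation period — but
in this implementation its real part saturates near $-0.06$ (around
$\sigma_i \approx 5$) and never crosses zero; the same holds at
$g_{ad} = 0.1$.  Consistently, direct simulations of both the
step-function and the smooth field model show steady pulses far beyond
$\sigma_i = 2$, and the smooth-model pulse at $(2, 0.1)$ still crosses the
domain at $\sigma_i = 12$.  So in this realization the
oscillatory-destabilization route to propagation failure is *latent*
rather than realized at the default gains: the closed-form analysis, the
eigenvalue tracker and the simulators all agree with one another
(stability verdicts against simulation are part of the test suite), but a
Hopf destabilization of the pulse is not reached along $\sigma_i$ with
these constants.  Users exploring that instability should treat the
default gains as a starting point and expect its location — if any — to be
quite sensitive to the coupling and normalization constants.

## What the synthetic inputs do and do not emulate

All inputs are generated in code: Bernoulli connectivity, Gaussian current
noise, square stimulus pulses, and rest-state initial conditions.  These
capture distance-dependent coupling statistics and trial-to-trial
variability of a slice-like 1-D preparation, but not: conductance-based
synaptic saturation, axonal delays, neuronal heterogeneity beyond noise,
layered (2-D) architecture, or slow extracellular modulations.  Passing
tests therefore demonstrate internal consistency of the model ladder and
faithfulness to its defining equations — not quantitative agreement with
any particular biological recording.

## Problem sizes and reproducibility

The test suite runs the full 480-cell network for ~100 ms episodes, field
simulations on the standard $[0, 80]$ grid for 150–260 ms, one
boundary-value continuation to the default point plus a short branch, and
Evans evaluations on 101–151 point grids; these sizes were chosen so the
whole suite completes in a few minutes while still exercising the
full-size models.  Every stochastic component takes an explicit integer
seed (`split_seed()` derives per-component streams), and identical seeds
reproduce trajectories bit for bit.  The script `scripts/acceptance.R`
recomputes the package's headline quantities end to end; see the README.
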