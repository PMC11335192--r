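---
title: "Models and methods: charge movement, transport kinetics and efflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: charge movement, transport kinetics and efflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatkit)
```

`gatkit` analyses the three current components of an electrogenic
transporter under voltage clamp — pre-steady-state (PSS) charge movement,
steady transport current, and linear membrane components — together with
superfusion efflux assays. This vignette is the package's own account of
the underlying models, the numerical choices, and what the validation
suite does and does not establish.

## The two-state charge-movement model

The simulator and the closed-form ground truths rest on the simplest model
whose steady state is a Boltzmann sigmoid and whose relaxation is
mono-exponential: a charge of effective valence $z$ hopping between an
outer and an inner position across a symmetric energy barrier. With
$u = (V - V_{0.5})/\sigma$ and $\sigma = RT/(zF)$ (in mV),

$$\alpha(V) = k_0 e^{+u/2}, \qquad \beta(V) = k_0 e^{-u/2},$$

the outward and inward rates; the occupancy of the inner position relaxes
mono-exponentially with $\tau = 1/(\alpha+\beta)$ towards
$f_\infty(V) = 1/(1+e^{u})$, and the charge displaced by a step from the
holding potential $V_h$ to $V$ is
$\Delta Q(V) = Q_{max}\,[f_\infty(V) - f_\infty(V_h)]$. Because the
barrier is symmetric, the observed relaxation rate splits exactly as

$$\text{inrate} = \frac{1}{\tau}\frac{Q_{in}}{Q_{max}} = \beta, \qquad
  \text{outrate} = \frac{1}{\tau}\Bigl(1-\frac{Q_{in}}{Q_{max}}\Bigr) = \alpha,$$

which is the identity the analysis pipeline uses to derive unidirectional
rate constants from the fitted Q–V and τ–V relationships, and what makes
every stage of the pipeline testable against the generator's closed
forms. The names `inrate`/`outrate` are used throughout; α/β are display
aliases only, since their assignment varies across the literature.

Assumptions worth stating: a single mobile charge species, no
multi-exponential relaxations (multi-state vestibules are out of scope),
and ON transients only — the OFF relaxation at the return to $V_h$ is
simulated for realism but not analysed, because published protocols do not
always state which transient was integrated.

### Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| $Q_{max}$ | 12 | nC | typical total displaceable charge of a well-expressing oocyte |
| $V_{0.5}$ | −32.87 | mV | reported midpoint for the substrate-free sodium-buffer condition in rGAT1 oocyte work |
| $z_{eff}$ | 1 | — | gives $\sigma = RT/F \approx 25.1$ mV at 291.15 K, in the usual 25–40 mV range |
| $k_0$ | 10 | s⁻¹ | τ = 50 ms at the midpoint, 12–30 ms at the range limits; realistic, and keeps 1 kHz sampling adequate for trapezoid-level charge accuracy (error $\approx (\Delta t/\tau)^2/12 < 0.1\%$ everywhere) |
| T | 291.15 | K | 18 °C, the oocyte incubation temperature; fixes the $\sigma \leftrightarrow z$ conversion |

The per-condition midpoints (−27.16 mV for 0.1 mM betaine, −43.19 mV for
10 µM GABA) are carried by `study_defaults()` as condition-specific ground
truths.

Cell parameters ($C_m$ = 220 nF, $\tau_c$ = 1 ms, $g_{leak}$ = 2 nA/mV,
$E_{leak}$ = −20 mV) are generator plumbing: they make sweeps look
realistic but are not estimates of any particular cell; such values are
rarely reported alongside transporter kinetics. The capacitive transient decays below 1% of
its peak 5 ms after the step, which motivates the default fit window.

## The sweep simulator and its scope

A simulated sweep is the sum of capacitive transient, ohmic leak, PSS
relaxation, steady transport current (during the step) and additive white
Gaussian noise. Noise is interpreted as *post-filtering* noise: the rig's
0.1 kHz low-pass is not simulated, because the deterministic components
are band-limited by construction and filter design is irrelevant to the
fits being validated. A seed is mandatory whenever noise is requested, and
per-sweep seeds are derived deterministically from the base seed, so any
simulated dataset is bit-reproducible.

Substrates modulate the simulated charge movement through the fractional
occupancy $occ = G/K_G + B/K_B$: $Q_{max}$ is scaled by $1/(1+occ)$ and
$k_0$ by $(1 + c_G\,G/K_G + c_B\,B/K_B)$. The acceleration constants are
deliberately per-substrate (defaults $c_G = 3.5$, $c_B = 0.35$; a single
scalar is accepted): a saturating concentration of the high-affinity
substrate must render the transient undetectable within the 5 ms analysis
window — the experimental signature of a fast, saturated cycle — while
tens of millimolar of the low-affinity substrate only moderately shortens
τ, as observed. One symmetric constant cannot do both.

What the generator does **not** emulate: solution-exchange artifacts,
series-resistance and clamp-speed errors, correlated (filtered) noise,
electrode drift, and cell-to-cell parameter spread. Passing recovery tests
therefore demonstrates the correctness and statistical efficiency of the
estimators under the stated model, not robustness to every artifact of
real recordings.

## The analysis pipeline: numerical choices

**Blocker subtraction** is an exact pointwise difference; protocol
mismatches are errors naming the offending field. Subtraction removes
everything common to the two conditions — including the capacitive
transient — so the pipeline is invariant to any common additive component
(a tested property).

**Relaxation fitting** uses Levenberg–Marquardt least squares of
$A e^{-(t-t_w)/\tau} + b$ on a window from 5 ms after the step onset
(configurable) to the step end, half-open at the step end so the first
OFF-relaxation sample is never included. Initialization: $A_0$ = first
minus last window sample, $\tau_0$ = window/5, $b_0$ = mean of the final
tenth; $\tau$ is bounded in [2 samples, 2 × window]. Failures and
amplitudes indistinguishable from zero (|A| < 2 SE, or below the numerical
floor of the data) yield `converged = FALSE` rather than an exception; a
flat trace reports the constant as its baseline.

**Charge integration** uses the analytic integral of the fitted component,
extrapolated to the step onset: $Q = A\tau\,e^{\delta/\tau}$, where
$\delta$ is the window offset. Without the extrapolation a 5 ms window
would underestimate $\Delta Q$ by $e^{-\delta/\tau}$ (up to ~30% at the
fastest τ), so the extrapolated form is what makes the fitted charge agree
with the numeric trapezoid of the isolated transient to better than 0.1%.
Fitting rather than integrating the raw trace keeps the charge immune to
leak and baseline contamination; the raw trapezoid remains available as a
diagnostic. Because the plug-in product $\hat A\hat\tau$ is biased by the
$\hat A$–$\hat\tau$ estimation correlation
($E[\hat A\hat\tau] = A\tau + \mathrm{cov}(\hat A,\hat\tau) + \dots$), the
second-order delta-method correction $\tfrac12\mathrm{tr}(H\,\Sigma)$ is
subtracted using the fit covariance; at the default noise levels this
removes a measurable ~0.1 nC downward bias at mid potentials and vanishes
on noise-free data.

**The Q–V table and its reference.** Integrated charge is defined relative
to the holding potential, so the step to $V_h$ itself displaces zero
charge *by construction*. The pipeline therefore does not attempt a
relaxation fit at $V = V_h$ (there is nothing to fit) and instead enters
$(V_h, 0)$ into the Q–V table as an exact reference point. This both
removes a degenerate fit and anchors the sigmoid mid-range, which
materially improves midpoint recovery at realistic noise.

**Boltzmann fitting** includes a free offset (the reference convention
above fixes only one point, not the asymptote), leaves the slope sign
unconstrained, and afterwards normalizes to $\sigma > 0$ with the
orientation recorded as a flag — the usual case for ON transients of
Na⁺-coupled transporters is charge saturating on hyperpolarization
(`decreasing = TRUE`). When per-point charge SEs are available the fit is
weighted by their inverse squares. Standard errors come from the local
covariance, transformed consistently when the orientation is normalized.

**Analysis range** defaults to −120…+20 mV even though the protocol spans
−140…+40 mV, excluding the extremes where relaxations are fastest and
single-exponential fits least reliable. **Steady currents** are means over
the final 100 ms of the step minus the pre-step holding baseline.

### A noise-convention note

The stochastic validation places noise so that the *analyzed*
(blocker-subtracted) trace carries a standard deviation of 5% of the
isolated-PSS peak amplitude; since subtracting two independent sweeps
scales noise by $\sqrt2$, each recorded sweep carries $5\%/\sqrt2$. This
is the convention under which the pipeline's recovery property is stated
and tested: an information analysis (Cramér–Rao bound of the relaxation
stage propagated through the Q–V fit) shows the per-point charge
estimates already sit at the bound, so the recovery precision reported by
the test suite is the attainable one, not an implementation ceiling.

## Dose–response and competition

The "logistic fit" is the Hill form through the origin with free exponent
initialized at 1 (a nonzero floor is excluded because currents are
baseline-subtracted); the exponent is reported so it can be fixed at 1 for
comparison — with a free exponent, $K_{0.5}$ and $p$ are strongly
correlated and $K_{0.5}$ scatter roughly triples. Weights are $1/SEM^2$
when every SEM is available and positive, otherwise the fit is unweighted
with a notice. Degenerate inputs (all-zero currents) return a flagged
non-converged fit, never a division error. Transport efficiency
$I_{max}/K_{0.5}$ carries a first-order (delta-method) SE validated
against Monte-Carlo propagation in the test suite.

The competition grid is the full crossing of the non-zero substrate levels
plus the substrate-only margins and the buffer-only reference — for the
canonical 6 × 11 design, 84 conditions. The **dual-effect** analysis
splits each row at the betaine level minimizing the current magnitude
(ties toward the lower concentration, matching the convention that the
boundary between the fitted "lower" and "higher" ranges is not published).
A row is biphasic when the minimum is interior and each limb — split level
included, since it anchors both — holds at least three levels. The
descending limb is fitted with an IC50-style logistic on the magnitude;
the ascending limb with the Hill model on the increments above the
minimum, fitted only when at least three levels lie strictly above the
split (anchoring that fit at the zero increment makes it degenerate, so it
is omitted and the limb reported as unavailable).

The generative two-substrate current is
$$I = f(V)\,\frac{I_G\,g\,S + I_B\,b}{1+g+b},\qquad
  g = G/K_G,\; b = B/K_B,$$
with an optional modulatory suppression $S = (1+g)/(1+g+B/K_{inh})$ on the
$G$-borne current ($S \equiv 1$ when $K_{inh} = \infty$, the default, which
is the plain single-site competitive scheme). The modulatory site is a
deliberate generative choice: in the plain competitive scheme the current
is *provably monotone* in $B$ at fixed $G$ (the derivative's sign is
independent of $B$), so no single-site parameterization can produce an
interior minimum. A high-potency, GABA-outcompeted modulatory action —
betaine slowing the transport cycle at sub-millimolar concentrations while
being transported only with ~12 mM affinity — is the minimal extension
that reproduces the observed biphasic rows at low GABA and their
disappearance at saturating GABA. It is a phenomenological emulation, not
a mechanistic claim.

## Efflux quantification

Percent release is computed against the conserved total (all supernatant
fractions plus the remaining cell content = 100%), and depletion is
applied to the content remaining at each fraction start, matching
superfusion physics. The plateau of the drug phase is the first fraction
whose percent differs from the next by less than 10% of the drug-phase
range (configurable); a flat phase plateaus at its first fraction; a
monotone rise yields the final fraction with a `no_plateau` flag. Induced
efflux is reported both uncorrected and basal-subtracted because published
values do not always state the convention. SEMs are reported at both the
well and experiment level where the design provides them.

Defaults: basal release 0.12 % min⁻¹ in 2-min fractions, maximal induced
release 1 % min⁻¹ above basal with a 2-fraction rise, half-maximal dose
6.73 mM (betaine) or 36.28 µM (GABA), monensin scaling 1.5 — the betaine
and GABA half-maximal doses and the basal rate are the published central
estimates; the ceiling, rise and monensin scale are only shown graphically
in the source material, so realistic values were fixed once.

## Validation design and problem sizes

The test suite validates every operation against an independent oracle:
explicit Euler integration of the two-state master equation (1 µs steps)
for the generator's closed forms; trapezoid quadrature for charge; a
τ-grid search with exact linear least squares for the exponential fits;
direct formula evaluation for Hill curves; brute-force row scans for the
dual-effect split; and Monte-Carlo propagation for delta-method SEs.
Stochastic recovery uses 50 seeded replicates for the charge-movement and
dose-response designs and 100 for the efflux design — sizes chosen to
estimate medians and success rates stably while keeping the default suite
fast; the acceptance script uses 12 replicate cells per voltage-step
condition for the same reason.

## Known limitations

* Mono-exponential relaxations only; transporters with multi-state charge
  movements need a different model.
* ON transients only; OFF-transient integration and P/4-style leak
  protocols are out of scope.
* The dual-effect generator is phenomenological; the grid analysis cannot
  discriminate competitive from modulatory mechanisms.
* Averaging across cells operates on derived quantities (Q, τ per
  potential), not raw traces; order-of-operations differences with other
  software are possible at high noise.
* The efflux model ignores scintillation-counter corrections (quench,
  background) and models monensin only as a scaling label.
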