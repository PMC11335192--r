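# gatkit

Kinetic analysis of voltage-clamp recordings from electrogenic
neurotransmitter transporters — written for electrophysiologists studying
solute-carrier (SLC6-family) transporters such as the neuronal GABA
transporter GAT1 in *Xenopus* oocytes or transfected mammalian cells.

Electrogenic cotransporters produce three experimentally separable current
components: transient **pre-steady-state (PSS) currents** from charge (e.g.
Na⁺) relaxing within the membrane electric field after a voltage step,
**steady transport currents** carried by the substrate-coupled cycle, and
linear capacitive/leak components. `gatkit` implements the full analysis
chain for all three, plus the release-assay quantification used to study
transporter-mediated efflux, and a forward simulator with known ground
truth so every stage can be validated by parameter recovery.

## The models

**Charge movement.** After isolating the transporter currents by
subtraction of the traces recorded under a saturating blocker, the ON
relaxation at each test potential V is fitted with a single exponential
`I(t) = A·exp(−t/τ) + baseline`; the displaced charge is the analytic
integral `Q = A·τ` (referenced to the step onset). The Q–V relationship is
fitted with the Boltzmann sigmoid

    Q(V) = Q_offset + Q_max / (1 + exp[−(V − V_0.5)/σ])

giving the maximal displaceable charge `Q_max`, the midpoint `V_0.5` and
the slope factor `σ = RT/(z_eff F)`. The relaxation rate is split into
unidirectional rate constants using the Boltzmann fraction:

    inrate (β) = (1/τ)·(Q_in/Q_max),   outrate (α) = (1/τ)·(1 − Q_in/Q_max)

so that `inrate + outrate = 1/τ` holds exactly at every potential.

**Steady-state kinetics.** Dose–response currents follow the
logistic/Hill model through the origin, `I(S) = I_max·Sᵖ/(Sᵖ + K_0.5ᵖ)`,
with the transport efficiency `I_max/K_0.5` and delta-method standard
errors. Two-substrate competition grids (e.g. GABA × betaine) are
summarized as mean ± SEM matrices and analyzed per row for the biphasic
"dual effect": inhibition of the primary-substrate current at low
concentrations of the second substrate and added transport at high
concentrations.

**Efflux.** Superfusion release assays are quantified as per-fraction
percent of total tracer (conserving 100% exactly), giving the basal rate
(% min⁻¹), the plateau-based drug-induced efflux, and its logistic
concentration–response.

## Worked example

Simulate a voltage-step experiment (holding −60 mV, 0.8 s steps from −140
to +40 mV at 1 kHz, with a blocker condition) and recover the charge
movement end-to-end:

```r
library(gatkit)
sd0 <- study_defaults()
sets <- simulate_condition_set(
  sd0$protocol, sd0$charge_movement$nd98, sd0$cell, sd0$transport,
  list(list(label = "SKF89976a_30uM", blocker = TRUE),
       list(label = "ND98")),
  noise = noise_spec(5, seed = 42))
pss <- run_pss_pipeline(sets$ND98, sets$SKF89976a_30uM)
pss
#> Pre-steady-state analysis
#>   analyzed potentials: 8; excluded: 0
#> Boltzmann Q-V fit (decreasing with V):
#>   Qmax = 12.37 nC, V_half = -30.91 mV, sigma = 26.74 mV, offset = 3.096 nC
#>   SE: Qmax 0.167, V_half 0.691, sigma 0.572
head(pss$rates, 3)
#>   V_mV      tau_s inrate_per_s outrate_per_s
#> 1 -120 0.01692856     57.03361      2.038158
#> 2 -100 0.02308782     40.27258      3.040304
#> 3  -80 0.03233616     26.67154      4.253596
```

The generator's ground truth was `Qmax = 12 nC`, `V_half = −32.87 mV`,
`σ = 25.09 mV`: at ~2% trace noise the pipeline recovers the midpoint
within ~2 mV and the charge within ~3%, with per-parameter standard errors
from the fit covariance. The `rates` table splits `1/τ` into the inward
(`inrate`, β) and outward (`outrate`, α) rate constants; their sum equals
`1/τ` to machine precision.

Dose–response kinetics with the published design (7 betaine concentrations,
0.1–50 mM, 8 cells each):

```r
tab <- simulate_dose_response(-76.15, 11.57, 1, c(0.1, 0.3, 1, 3, 10, 30, 50),
                              n_replicates = 8, noise = noise_spec(2, seed = 8))
fit_dose_response(tab)
#> Hill/logistic fit: Imax = -74.02 nA, K_half = 10.79 mM, p = 1.03
#>   transport efficiency Imax/K_half = -6.86 nA/mM (SE 0.268)
```

A command-line interface wraps the same pipelines
(`inst/cli/gatkit simulate|pss|dose|compete|efflux`); see `?run_cli`.

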