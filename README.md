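# dyefront

Reaction–diffusion modelling and image-moment analysis of DNA-binding dye
uptake in cell nuclei.

## The problem

DNA-binding drugs such as Hoechst 33342 and doxorubicin bind their nuclear
targets *in vitro* with relaxation rates of order 10 s⁻¹ at micromolar
concentrations (`k_off` ≈ 0.1 s⁻¹, `K_d` ≈ 0.01 µM, so
β = k_off(1 + u₀/K_d) ≈ 10 s⁻¹). In intact nuclei the same binding is
observed to relax a thousand-fold slower, of order 10⁻³ s⁻¹, with an
inward-moving reaction front, effectively irreversible binding under a
dye-free chase, and strong cell-to-cell variability. `dyefront` implements
a quantitative account of this discrepancy — non-specific, high-capacity,
low-affinity binding acts as an intracellular buffer and trap — together
with the single-cell image analysis needed to measure it, and a
synthetic-movie generator so the entire pipeline can be validated against
known ground truth. It is intended for quantitative cell biologists and
modellers working on intracellular pharmacokinetics and time-lapse
fluorescence analysis.

## Models

* **Well-mixed kinetics** (`well_mixed_solution`, `relaxation_rate`):
  v(t) = v_st + (c − v_st)e^(−βt), β = k_on u₀ + k_off.
* **Bath depletion** (`solve_depletion`, `depletion_closed_form`): the
  available-site concentration obeys
  dρ/dt = −k_on(u₀ + ρ − ρ_tot)ρ + k_off(ρ_tot − ρ), solved exactly along
  the hyperbolic-tangent family ρ(t) = ρ₁ + ρ₂ coth(βt/2 + ρ₃) with
  β = √([k_off + k_on u₀ + k_on ρ_tot]² − 4k_on²u₀ρ_tot).
* **Effective diffusion** (`effective_diffusion`): the rapid-buffering
  reduction D* = D·K_d/(K_d + ρ), a 10²–10³-fold slow-down at
  sub-micromolar K_d and ρ ≥ 100 µM.
* **Trapping random walk** (`simulate_walk`, `msd_exact`): free/bound
  lattice walk with exact MSD
  ⟨x²⟩ = δ[1 − e^(−(k₋+k₊)t)] + 2dD*t, δ = 2dDk₊/(k₋+k₊)²,
  D* = Dk₋/(k₋+k₊) — transient anomalous diffusion crossing over to a
  reduced slope. Monte-Carlo simulators (Gillespie event scheduling,
  including finite-capacity multi-walker lattices) cross-check the exact
  forms.
* **Reaction–diffusion in a nucleus** (`simulate_base`,
  `simulate_nonspecific`, `simulate_competition`): radial finite-volume
  model ∂u/∂t = D∇²u − R − Rⁿ with R = k_on u(c−v) − k_off v, a
  100-fold-capacity non-specific pool Rⁿ, a Robin membrane condition
  D∂u/∂r = h_m(u_ext − u) (Biot number Bi = h_m R_n/D), a depleting shared
  bath, timed protocols (addition, cold chase, permeabilisation) and an
  optional competing ligand sharing the specific sites.
* **Image moments** (`image_moments`, `intensity_traces`): per-nucleus
  M_n(t) = Σ I r^n / Σ I on the normalised elliptic radius
  r = √(x²/a² + y²/b²), with geometric references M₂ = 2/5 (projected
  solid ball) and 2/3 (thin shell); plus I_tot, I*_tot, CV_p, radial
  profiles, saturating-exponential relaxation fits and population
  statistics (G1/G2 classification, damage dichotomisation).
* **Synthetic movies** (`population_config`, `generate_population`,
  `render_stack`, `analyze_stack`): two-channel stacks with elliptical
  nuclei, projected forward-model dye signal, shot + read noise, stage
  jitter, and full ground truth.

## Worked example

```r
library(dyefront)

site <- binding_site(k_off = 0.1, K_d = 0.01, capacity = 25)
relaxation_rate(site, u0 = 1)          # 10.1  (s^-1, the in vitro scale)
msd_offset(D = 0.088, k_plus = 0.58, k_minus = 0.035)  # 0.2699 (~0.27)
500 / effective_diffusion(500, K_d = 1, rho = 100)     # 101-fold slowdown

d <- dye_defaults()
st <- simulate_nonspecific(d$geometry, d$transport, d$specific,
                           d$nonspecific, d$bath,
                           times = seq(0, 3600, by = 120))
tr <- trace_outputs(st, frames = c(3, 31))
fit_relaxation(st$times, tr$I_tot)
#> Relaxation fit: beta = 0.001058 s^-1 (tau_1/2 = 10.92 min),
#>                 95% CI [ 0.001035 , 0.001081 ]
round(tr$M2, 3)                        # 0.530 -> 0.402
reference_m2("solid-ball")             # 0.4
round(st$u_ext[31], 3)                 # 0.117 uM left in the bath
```

The same in vitro constants that predict β ≈ 10 s⁻¹ in a cuvette give
β ≈ 1.1 × 10⁻³ s⁻¹ once explicit non-specific buffering, membrane transfer
and bath depletion are in play: the thousand-fold slow-down emerges from
the model rather than being put in. The second moment relaxes from 0.53
(a peripheral front) to the solid-ball reference 0.40 (homogenised
staining), and the 1 µM bath is drawn down to 0.12 µM — the buffering
pool, not the specific sites, soaks up the dye.

A command-line wrapper for the pipeline stages lives at
`inst/cli/dyefront` (`simulate-rd`, `walk`, `synth`, `analyze`,
`reproduce-figures`), each run writing CSV outputs and a JSON manifest.

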