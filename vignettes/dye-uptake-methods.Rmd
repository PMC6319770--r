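---
title: "Methods: modelling and measuring slow dye uptake in nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and measuring slow dye uptake in nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dyefront)
```

# Scope and units

`dyefront` models the uptake of minor-groove-binding DNA dyes (and, by
competition, intercalating drugs) into single cell nuclei, and quantifies
the resulting fluorescence movies. Throughout the package concentrations
are in µM, lengths in µm and times in seconds; fluorescence is an
arbitrary unit proportional to specifically bound dye. Dissociation
constants are always stored in µM.

# The models

## Well-mixed kinetics and why they fail

Second-order binding to sites of capacity $c$ at constant free dye $u_0$
relaxes as $v(t) = v_{st} + (c - v_{st})e^{-\beta t}$ with
$\beta = k_{on}u_0 + k_{off} = k_{off}(1 + u_0/K_d)$. With the in vitro
constants of the dye–DNA complex ($k_{off} \approx 0.1$ s⁻¹,
$K_d \approx 0.01$ µM) this predicts $\beta \approx 10$ s⁻¹ at 1 µM dye,
and free aqueous diffusion ($D \approx 500$ µm²/s) would homogenise a
20 µm nucleus in under a second ($R^2/D \le 1$ s). Observed uptake in
nuclei is of order $10^{-3}$ s⁻¹ with minutes-long front propagation; the
package exists to model that gap mechanistically.

## Buffering, trapping and anomalous diffusion

A walker that hops with diffusivity $D$ while free, binds traps at rate
$k_+$ and unbinds at $k_-$ has the exact mean-square displacement
$\langle x^2\rangle = \delta\,[1 - e^{-(k_-+k_+)t}] + 2dD^*t$ with
$D^* = Dk_-/(k_-+k_+)$ and offset $\delta = 2dDk_+/(k_-+k_+)^2$: normal
diffusion at short times, a transient anomalous plateau, then diffusion
with a reduced coefficient. The identity
$\langle x^2\rangle = 2dD\int_0^t p_0(\tau)d\tau$, where $p_0$ is the
two-state free-state occupancy, is enforced in the tests to $10^{-10}$.
In concentration language the same reduction is the rapid-buffering form
$D^* = D\,K_d/(K_d+\rho)$; sub-micromolar non-specific $K_d$ and
$\rho \ge 100$ µM of buffering sites give the observed $10^2$–$10^3$-fold
slow-down.

The Monte-Carlo walkers use exact exponential waiting times (hop, bind,
unbind) rather than fixed time steps, so the MSD carries no
discretisation bias. Because MSD values at different lags share walkers,
slope and intercept uncertainties are estimated by refitting 16
independent walker batches; single-curve regression errors would be
several-fold optimistic. The late-time fit window starts after both the
two-state transient and the first quarter of the horizon, because
spatially heterogeneous binding rates (the sinusoidally perturbed lattice,
or sparse sticky sites) produce slowly decaying transients that otherwise
bias the slope. The perturbation phase is drawn per walker unless fixed;
its amplitude defaults to half the mean binding rate.

## Bath depletion in closed form

Treating all cells as identical and ignoring spatial fluctuations, the
available-site concentration per cell-equivalent volume obeys
$\dot\rho = -k_{on}(u_0 + \rho - \rho_{tot})\rho +
k_{off}(\rho_{tot}-\rho)$, $\rho(0)=\rho_{tot}$. This Riccati equation
has constant coefficients; its rate is the square root of the
discriminant,
$\beta = \sqrt{[k_{off}+k_{on}u_0+k_{on}\rho_{tot}]^2 -
4k_{on}^2u_0\rho_{tot}}$ (a squared-rate expression would be
dimensionally inconsistent with the exponential approach; the numeric
integrator arbitrates, and agreement is held to $10^{-6}$ relative over a
$10\times10$ grid of $u_0,\rho_{tot} \in [0.1, 10]$ µM). Because the
trajectory starts at $\rho_{tot}$, *above* the upper equilibrium root, the
realised branch of the hyperbolic-tangent family is
$\rho(t) = \rho_1 + \rho_2\coth(\beta t/2 + \rho_3)$ with $\rho_1,\rho_2$
the mean and half-separation of the quadratic's roots and
$\rho_3 = \mathrm{artanh}[\rho_2/(\rho_{tot}-\rho_1)]$. The initial
amount $\rho_0$ is identified with $\rho_{tot}$ (the stated initial
condition). Degenerate discriminants (double roots, e.g. $k_{off}=0$,
$u_0=\rho_{tot}$) fall back to the numeric solver, as do the fixed-point
cases $u_0=0$ and $k_{on}=0$, which return constants analytically. The
small-$K_d$ shortcut $\beta \sim 2k_{off}\rho_0/K_d$ sometimes quoted for
$u_0 \approx \rho_0$ does not follow from the discriminant (which gives
$2k_{off}\sqrt{\rho_0/K_d}$ there); the package treats the discriminant
form, validated against the integrator, as authoritative and does not use
the shortcut.

## The radial reaction–diffusion model

The PDE is solved on a sphere of radius $R_n$ (the paper-level model is
mean-field and radial; ellipticity enters only through rendering and the
normalised elliptic radius). Internally the bound-dye convention is used
for both pools, $R = k_{on}u(c-v) - k_{off}v$ and
$R^n = k^n_{on}u(c^n-v^n) - k^n_{off}v^n$; the free-target convention
(where the reaction reads $k_{on}uv - k_{off}(c-v)$) is available through
`free_target()`, so the two sign conventions are a documented mapping,
not two models. The membrane is a Robin condition
$D\,\partial_r u = h_m(u_{ext}-u)$ at $r=R_n$; the dimensionless Biot
number $Bi = h_mR_n/D$ separates membrane-limited ($Bi \ll 1$) from
diffusion-limited uptake. A depleting bath couples one cell-equivalent
well volume (150 µl / 5·10⁴ cells ≈ 3·10⁶ µm³ per cell) through the
membrane flux. Two-ligand competition shares the specific pool
($v_1+v_2 \le c$ pointwise) while each ligand keeps its own rate
constants, transport and non-specific pool; dye fluorescence is $v_1$
only (the competitor's autofluorescence is not modelled).

Numerics: method of lines on a cell-centred grid of 96 nodes (default),
finite-volume spherical-shell fluxes so that closed systems conserve mass
to solver tolerance (the suite holds a closed run to $10^{-6}$ relative;
in practice drift is at rounding level), the membrane flux applied at the
outer face with a linear face reconstruction,
$f = h_m(u_{ext}-u_N)/(1+h_m\Delta r/2D)$. Time stepping is `lsoda` with
a banded Jacobian (bandwidth = fields per node), relative tolerance
$10^{-8}$, absolute $10^{-10}$ µM. Protocols (timed addition, bath
replacement, permeabilisation) split the integration into segments;
permeabilisation scales $h_m$, reduces the non-specific capacity, and
returns the dye released from removed buffer sites to the free pool so
that mass is conserved. Doubling the grid changes uptake traces by less
than 0.2%; a pure-diffusion run matches the Robin-sphere eigenfunction
series to a few parts in $10^5$. The Dirichlet-limit check is run at
$Bi = 500$ because the remaining Robin-vs-Dirichlet gap is physical
(of order $1/Bi$), not numerical.

## Default parameters

| Parameter | Default | Why |
|---|---|---|
| $R_n$ | 10 µm | typical epithelial nucleus |
| $D$ | 500 µm²/s | free dye in water; the explicit buffer supplies the intracellular slow-down |
| specific $k_{off}$, $K_d$, $c$ | 0.1 s⁻¹, 0.01 µM, 25 µM | in vitro dye–DNA constants; $c$ from ~1% of base pairs at nuclear DNA density |
| non-specific $k_{off}$, $K_d$, $c^n$ | 0.5 s⁻¹, 0.05 µM, $100c$ | capacity ratio from the ~100-fold excess of non-specific sites; $K_d$ sub-micromolar, chosen with $h_m$ to land the observed $10^{-3}$ s⁻¹ relaxation scale |
| $h_m$ | 1.5 µm/s ($Bi = 0.03$) | membrane-limited uptake at the observed rate scale |
| permeabilisation | $h_m \times 3$, $c^n \times 0.7$ | a tuned reference set reproducing the 2.5–3.5-fold initial-rate acceleration; a regression fixture, not a law |
| competitor | $K_d$ 0.002 µM, $k_{off}$ 0.02 s⁻¹, $h_m$ 0.3 µm/s | higher affinity, ~5-fold slower entry: yields co-addition peaks and dose-dependent pre-incubation plateaus |

No membrane coefficient or non-specific constants are reported
measurements; they are package defaults chosen once to reproduce the
stated qualitative orderings and time scales, and everything is
overridable.

# The imaging pipeline

Coordinates are 0-based pixel centres. Segmentation is Otsu thresholding
of the reference (nuclear-marker) channel only, hole filling, connected
components and a minimum-area filter — the dye channel never influences
masks. Tracking is greedy nearest-centroid within a gate, ties broken by
distance then label. The per-nucleus ellipse is the centroid plus the
eigen-decomposition of second central moments, with semi-axes rescaled so
the ellipse area equals the mask area (the eigenvalue-to-axis scale is
otherwise conventional); the normalised elliptic radius puts the fitted
boundary at $r=1$, which makes the geometric references dimensionless:
$M_2 = 2/5$ for a projected solid ball, $2/3$ for a thin shell, with
thick shells from quadrature. Moments $M_n = \sum I r^n / \sum I$ are
then invariant under translation, rotation and rescaling (held to
$10^{-3}$ under bilinear resampling in the tests). Background is the
per-frame median of non-mask pixels, subtracted from the dye channel and
clamped at zero, so a uniform additive offset cancels exactly.

The central sub-region is the 10% of mask pixels with smallest elliptic
radius — a pixel-count reading of "shrinking the nucleus proportionately",
exact up to discretisation. Relaxation rates are least-squares fits of
$I(t) = A(1-e^{-\beta t}) + B$; the buffered model is not a single
exponential, so $\beta$ is an operational summary (fits that fail, e.g.
constant traces, are flagged rather than raised). Steady-state intensity
for classification is the mean of the last three frames. The G1/G2 split
minimises within-class variance on log steady-state intensity and is
accepted only if it explains at least 75% of the variance — the optimal
split of a unimodal Gaussian explains about 64%, a genuine two-fold
DNA-content bimodality well above 85% — otherwise the population is
treated as one class. Damage readouts are dichotomised at a fixed
threshold (default 100 a.u.). Radial profiles use 20 bins by default;
empty bins are `NA`, not zero.

# The synthetic generator

`generate_population()`/`render_stack()` emulate: elliptical nuclei with
a constant reference channel; a dye channel that is the z-projected
(chord-integrated) bound-dye field of a per-cell reaction–diffusion
solve; cell-to-cell heterogeneity in membrane coefficient (log-normal)
and DNA capacity (60/40 G1/G2 bimodality, two-fold class ratio, ~12%
intra-class spread); shot (Poisson, `var = I/gain`) plus Gaussian read
noise; rigid per-frame stage jitter shared by all cells; and the
experimental protocols (single and sequential addition, cold chase,
permeabilisation, competitor co-incubation). Capacities are sampled as
total site numbers and stored as concentrations scaled by each cell's
volume, so steady-state intensity carries the class factor independent of
nuclear size — matching the observation that DNA content, not volume,
sets the plateau.

Two calibrations are themselves part of the emulated study conditions:
the membrane-coefficient CV is 0.7 so that the *fitted* relaxation-rate
CV per class is ≈0.6 (the rate responds to $h_m$ with elasticity ≈0.8
and also inherits geometry and capacity spread), and the default movie
ends at 18 h (an overnight incubation) with a two-phase schedule — dense
early frames for kinetics, log-spaced tail for the plateau — because
slow cells keep loading their buffer pool long after the operational
$\beta$ has apparently saturated.

The shared bath couples every cell in the well; the generator resolves
this with a two-pass mean-field scheme (one average-cell solve with the
coupled bath gives $u_{ext}(t)$, which then forces each per-cell solve).
This neglects the covariance between a cell's own uptake and the bath it
sees — acceptable at 5·10⁴ cells per well where any one cell's
contribution is negligible.

What the generator does *not* emulate: optics (no PSF, no z-stack
structure beyond the chord integral), chromatin substructure or
non-uniform target density within a nucleus, cell motility, division or
mitosis, photobleaching, and competitor autofluorescence. Closed-loop
tests passing on these movies therefore validate the measurement
pipeline's geometry, normalisation and statistics — not its robustness to
optical artefacts or biological heterogeneity beyond the sampled kinds.
The closed-loop recovery test renders one cell at 0.25 µm/pixel (≈36
pixels per semi-axis) because the 1%-RMS criterion demands that pixel
discretisation of the moment integrals be sub-percent; at the default
0.65 µm/pixel the geometry error, not the pipeline, would dominate.

# Problem sizes

Desk-scale defaults keep every stage in seconds to a few minutes on one
core: 96 radial nodes (48 in the generator), 2·10⁴ walkers for
Monte-Carlo/exact MSD comparisons, 25–40 cells per synthetic movie at
256–340 px frames and 50 frames, and an 8-point membrane-coefficient
lookup per cycle class for parameter recovery. All are configuration
values, not limits.

# Known limitations

* The radial model cannot represent intranuclear spatial heterogeneity
  (chromatin territories); measured $M_2$ plateaus of real nuclei differ
  from the solid-ball reference for exactly that reason.
* The mean-field bath ignores extreme-uptake outliers; protocols whose
  outcome hinges on a few dominant cells would need a fully coupled
  solve.
* Tracking has no mitosis or merge/split handling; touching nuclei are
  not watershed-separated.
* The saturating-exponential $\beta$ is biased for strongly
  non-exponential traces (very slow cells); the package reports it as an
  operational summary, as the analysis it mirrors does.
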