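---
title: "Models and methods behind monofilm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind monofilm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monofilm)
```

`monofilm` analyses the structure and thermodynamics of Langmuir monolayers
and electrode-supported bilayers built from bacterial-membrane lipids
(phosphatidylethanolamine, phosphatidylglycerol, cardiolipin and their
tail-deuterated analogues). This vignette explains the models implemented,
the parameters that matter, the numerical choices, and what the shipped
synthetic-data generators do and do not emulate.

## Specular reflectivity and the two-slab monolayer model

The optics engine computes the exact specular reflectivity of a stratified
interface by the Parratt recursion. For media $j$ with scattering length
density (SLD) $\rho_j$, the normal wavevector in medium $j$ at momentum
transfer $q_z$ is $k_j = \sqrt{(q_z/2)^2 - 4\pi(\rho_j - \rho_0)}$, and the
reflectivity is assembled from interface Fresnel coefficients
$r_{j,j+1} = (k_j - k_{j+1})/(k_j + k_{j+1})$, each multiplied by the
Nevot–Croce factor $\exp(-2 k_j k_{j+1} \sigma_j^2)$ for a Gaussian
interfacial width $\sigma_j$. Nevot–Croce is accurate when $\sigma$ is small
compared with layer thicknesses, which holds here (fitted roughnesses of
3–4.2 Å against slabs of 6–17 Å); a micro-slicing mode
(`parratt_reflectivity(..., microslice = TRUE)`) that discretises the
error-function profile into thin sharp slabs is available as a cross-check
for rougher systems. Absorption (an imaginary SLD component) is supported
and defaults to zero. The roughness model is the error-function profile
that standard reflectometry fitting packages assume.

A floating lipid monolayer is parameterised as two slabs on the subphase:

* a **tail slab** containing only the hydrocarbon chains
  (C$_{13}$H$_{27}$ per myristoyl chain), with thickness $d_\mathrm{tail}$
  and SLD $\Sigma b_\mathrm{tail} / V_\mathrm{tail}$;
* a **headgroup slab** (glycerol backbone, carbonyls, phosphate and polar
  group) of thickness $d_\mathrm{hg}$, whose SLD is the volume-weighted mix
  of headgroup material and subphase water;

with one common roughness $\sigma$ at all three interfaces. Where exactly
the tail/headgroup boundary sits at the atom level is a modelling choice;
placing the carbonyls in the headgroup region is consistent with treating
carbonyl hydration as headgroup-region behaviour in the infrared analysis,
and the boundary is encoded in an editable lipid registry
(`inst/extdata/lipids.csv`), not in code.

All areas and volumes are quoted **per pair of chains**, so a four-chain
cardiolipin contributes two pairs; this makes its parameters directly
comparable with two-chain lipids. The key derived quantities are

$$A_M = V_\mathrm{tail}/d_\mathrm{tail}, \qquad
  n_w = \frac{\rho_\mathrm{hg,slab} A_M d_\mathrm{hg} - \Sigma b_\mathrm{hg}}{b_\mathrm{w}}, \qquad
  V_\mathrm{hg} = A_M d_\mathrm{hg} - n_w V_\mathrm{w},$$

i.e. the headgroup slab SLD is inverted for the number of hydration waters
per lipid and the *unsolvated* headgroup volume, using only the known
headgroup composition — no literature headgroup volume is assumed. The
water molecular volume is fixed at $V_\mathrm{w} = 30.0$ Å$^3$ (19.5 °C)
and is configurable. `build_stack()` followed by `derive_structure()`
round-trips $(V_\mathrm{hg}, n_w)$ at machine precision, which the test
suite enforces.

### Contrasts, deuteration and H/D exchange

Neutron SLDs are computed as $\Sigma b / V$ from an embedded coherent
scattering-length table (H, D, C, N, O, P, Na); X-ray SLDs as
$r_e \cdot n_e / V$. Subphases are water, D$_2$O, or air-contrast-matched
water (ACMW, 8% v/v D$_2$O, SLD $\approx 0$). Labile headgroup hydrogens
(PG hydroxyls, the PE ammonium, the cardiolipin central hydroxyl) exchange
with the subphase and take its deuterium fraction (1.0 in D$_2$O, 0.08 in
ACMW). Because the data cannot always decide how many hydrogens exchange
(for PE in particular, zero and one exchanged ammonium hydrogen are both
defensible), the exchange scenario is a **required, explicit input** to
every neutron contrast — there is no silent default — and alternative
scenarios are compared by re-running the fit.

### Co-refinement, confidence ranges and model selection

Tail volume and roughness trade off against thickness in a single
reflectivity curve, so `cofit_grid()` follows a grid-scan strategy: $\sigma$
and $V_\mathrm{tail}$ are fixed on a grid (defaults 3.0–4.5 Å and
650–685 Å$^3$, bracketing condensed myristoyl monolayers) while
$d_\mathrm{tail}$, $d_\mathrm{hg}$, the headgroup solvent fraction and one
intensity scale per dataset are refined by bounded Levenberg–Marquardt
(`minpack.lm`), jointly across contrasts with shared structural parameters.
The figure of merit is the standard weighted chi-squared
$\chi^2 = \Sigma ((R_\mathrm{model} - R)/\delta R)^2$. Five jittered,
seeded optimiser starts per grid point guard against local minima; a
non-converged grid point is flagged, not fatal.

Confidence ranges come from one-parameter $\Delta\chi^2$ profiling
(re-optimising the nuisance parameters at each profile point;
$\Delta\chi^2 = 3.84$ for 95%), the deterministic counterpart of the
bracketed ranges a Bayesian fit would give; profiles that run into a
parameter bound are flagged one-sided. `select_best_model()` makes the
two-criterion choice — fit quality and agreement with the independently
measured molecular area from diffraction (condensed phases) or the isotherm
(expanded phases) — deterministic: among grid points within a 2% relative
chi-squared band of the minimum, the fit whose $A_M$ is closest to the
reference area wins. The 2% band is a package choice; the underlying
trade-off has no canonical weighting.

## Grazing-incidence diffraction

Condensed monolayer phases are 2D powders: hexagonally packed untilted
chains give a single in-plane Bragg peak; chain tilt distorts the cell and
splits the peak into two (tilt toward a nearest neighbour: degenerate
$\{10,01\}$ rod above the horizon plus $\{\bar 1 1\}$ at $q_z = 0$) or
three (oblique cell). `reduce_to_bragg_peaks()` integrates the map over
$q_z$, fits pseudo-Voigt peaks (shared Gaussian/Lorentzian mixing, linear
background) for $q_{xy}$ positions, then fits a Gaussian to each rod slice
for $q_z$; rod windows are clipped at half the distance to neighbouring
peaks so overlapping reflections do not contaminate each other.

`solve_unit_cell()` inverts $q_{hk} = 2\pi/d_{hk}$ and the rod condition
$q_z(G) = \tan t \, (\hat G \cdot \hat u)$ jointly for the cell, tilt
magnitude $t$ and azimuth $\hat u$: with one peak the cell is hexagonal
($A_\mathrm{chain} = 2d^2/\sqrt 3$, $t = 0$); with two, the smallest-$|q_z|$
peak is taken as $\{\bar 1 1\}$ (the nearest-neighbour-tilt convention);
with three, the assignment of the difference vector and the rod signs are
enumerated and the tilt vector refined by least squares, with an indexing
error (residuals attached) if no cell reproduces the rods within 0.5% of
$q$. Areas follow from the reciprocal cell,
$A_\mathrm{chain} = (2\pi)^2 / |G_{10} \times G_{01}|$, with
$A_\mathrm{pair} = 2A_\mathrm{chain}$ and the cross-section
$A_{xs} = A_\mathrm{chain}\cos t$. Mixing analysis (`excess_area()`)
compares measured areas with the linear ideal-mixing reference, optionally
on a chain-fraction basis in which a cardiolipin counts four chains.

## Isotherms

The compressibility modulus $C_s^{-1} = -A_M (\partial\Pi / \partial
A_M)_{N,T}$ is computed by centred finite differences after optional
Savitzky–Golay smoothing (window 9, order 3 by default; raw mode for
analytic work). Phase-transition pressures are extracted operationally:

* the liquid-expanded/liquid-condensed **onset** is the intersection of the
  tangent to the L$_e$ branch with the plateau line (the plateau being the
  contiguous run of near-zero slope flanked by steeper branches);
* the liquid-condensed/solid **kink** is located as the change point of the
  slope in the condensed region (a sliding two-window median contrast) and
  its pressure refined as the intersection of the two branch tangents.

Absent features are reported absent rather than fabricated. Because finite
differences amplify pressure noise on densely sampled isotherms, the
*detection* stage uses a wider smoothing window scaled to the series length
(about n/16 points), while the reported pressures come from branch-line
fits that are insensitive to that smoothing. All thresholds are relative,
so detection is invariant to rescaling the area axis.

## Chronocoulometry and capacitance

Potential-step transients are integrated (trapezoidal rule) to relative
charge densities between each hold potential and the desorption potential.
Absolute referencing offsets the bare-electrode curve to zero at its
potential of zero charge (pzc); a film curve is anchored through the shared
desorbed state, where the film-covered and bare surfaces are equivalent —
the paperwork of that anchor is the one genuinely underdetermined
convention in this analysis, and it is stated in the function
documentation. The film pressure follows from the Lippmann relation by a
second integration,
$\Pi(E) = \int_{E_\mathrm{des}}^{E} (\sigma_\mathrm{film} -
\sigma_\mathrm{bare})\, dE'$, with 1 μC cm$^{-2}$ V = 10 mN m$^{-1}$
hard-coded (and unit-tested). Potentials are stored on the scale given;
reference-electrode shifts are metadata, never silent conversions. Lock-in
capacitance uses the series-RC inversion
$C = (i_\mathrm{ip}^2 + i_q^2)/(\omega \, \delta E \, i_q)$, which reduces
to $i_q/(\omega\,\delta E)$ in the purely capacitive limit.

## PM-IRRAS

Band envelopes are deconvolved as sums of pseudo-Voigt components with a
shared mixing parameter on a linear baseline. In the carbonyl region the
hydrogen-bonded (solvated) fraction is the area fraction of the
low-wavenumber component. Chain tilt uses the metal-surface selection
rule: $\cos^2\theta = A_\mathrm{meas}/(3 A_\mathrm{random})$ per mode,
where $A_\mathrm{random}$ — the integrated absorbance of a randomly
oriented film — is an **input** computed with external thin-film optics
software, not by this package. The methylene symmetric and asymmetric
stretch dipoles are mutually perpendicular and perpendicular to the chain,
so $\cos^2 t = 1 - \cos^2\theta_\mathrm{sym} - \cos^2\theta_\mathrm{asym}$;
the three direction cosines close to one exactly by construction.
Fermi-resonance components are fitted but excluded from the tilt algebra.

## Synthetic data: what it emulates, and what it does not

Every stage ships a seeded generator returning data plus a truth record:

* `gen_reflectivity()`: forward two-slab model, Gaussian $dq/q$ smearing
  (7% FWHM for neutron time-of-flight, 1% for X-rays), multiplicative
  Gaussian noise with a consistent `dR` column — the high-count limit of
  counting statistics.
* `gen_gixd()`: pseudo-Voigt $\times$ Gaussian-rod peaks at the Bragg
  positions of a known cell on a linear background with Poisson counts.
* `gen_isotherm()`: piecewise-linear branches with Gaussian-rounded
  corners; symmetric rounding leaves branch tangents unchanged, so the
  constructed transition pressures are exactly the tangent-intersection
  values the detector estimates. Defaults (onset 12, kink 27 mN m$^{-1}$,
  noise 0.1–0.2 mN m$^{-1}$) sit in the range typical of myristoyl lipid
  mixtures on water near 19.5 °C.
* `gen_chrono()`: a capacitor-model electrode, $\sigma = C(E -
  E_\mathrm{pzc})$ per adsorption state with exponential transients
  $I(t) = (\Delta Q/\tau)e^{-t/\tau}$. The cell constant (300 Ω cm$^2$) is
  deliberately synthetic, chosen so transients decay fully within the
  0.15 s step; real cells are far faster. The linear capacitor extended
  over a 1.4 V window also produces film pressures well above the tens of
  mN m$^{-1}$ seen on real bilayer-coated gold.

Resolution smearing is evaluated by a 17-point Gauss–Hermite rule per data
point; against brute-force convolution this is accurate to $\sim 10^{-4}$
on smooth fringes but, like any fixed quadrature, degrades right at a
discontinuous total-reflection edge — fits should (and by default can)
truncate below the critical edge of a D$_2$O contrast.

The generators reproduce the *statistical structure* each analysis assumes,
not instrument artefacts: no Yoneda wings, dark current, beam damage,
footprint effects, barrier hysteresis, adsorption kinetics or
double-layer/Faradaic corrections. Passing the recovery suites therefore
demonstrates correctness of the inference chain under its own model
assumptions, not robustness to every systematic a beamline or potentiostat
can produce.

## Problem sizes and determinism

The test and acceptance workloads use curves of 100–200 points, diffraction
maps of roughly 400 × 90 pixels, 400-point isotherms and 30-step
chronocoulometry sequences, with 20-replicate recovery studies — sizes at
which every stage runs in seconds on one core while leaving the noise
regimes realistic. All stochastic steps take explicit integer seeds;
generators restore the caller's RNG state, and identical seeds give
bit-identical output on a given platform.

## Known limitations

Single-layer monolayer optics only (no polarised neutrons, off-specular
scattering or electrode-supported slab models — the electrochemical samples
are analysed thermodynamically, not optically); profiling rather than
posterior sampling for uncertainties; the pseudo-Voigt stands in for the
true Voigt profile; no Bragg-rod full-profile modelling, so rod widths and
coherence lengths are not interpreted; the exchange-scenario comparison is
enumerative, not inferential.
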