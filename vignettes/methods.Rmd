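---
title: "Local-in-time kinetics of vibrational energy transport: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-in-time kinetics of vibrational energy transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

## The physical picture

After a short, localized heat deposition — a photoexcited tag, a thermostatted
residue in a simulation — excess vibrational energy spreads through a peptide
on picosecond timescales. At the residue level this transport mixes a weak
ballistic (wavepacket-like) channel with dominant diffusive relaxation, and the
effective rates depend on the local temperature because the conformational
motions that carry energy are themselves activated processes.

`thermokin` post-processes per-residue kinetic-energy trajectories from such
experiments or simulations. Everything downstream is built on a master
equation for the kinetic energy $E_j(t)$ of residue $j$:

$$
\dot E_j = \sum_{(i,j)\ \mathrm{coupled}} \left[ k_{i\to j} E_i - k_{j\to i} E_j \right]
         \;-\; R_j\, k_s \left[E_j - E_{s,j}\right],
$$

with two intramolecular coupling channels — nearest neighbours along the
backbone ($j,\,j\pm1$) and hydrogen-bond contacts ($j,\,j+3$ for a $3_{10}$
helix, $j,\,j+4$ for an $\alpha$ helix) — plus relaxation to the solvent at
rate $k_s$, scaled per residue by a surface factor $R_j$ (default 1.5 at the
two termini, 1 elsewhere). $E_{s,j} = \tfrac{f_j}{2} k_B T_B$ is the solvent
energy scaled to the residue's $f_j = 3N_j$ degrees of freedom and is treated
as constant.

**Detailed balance.** One rate per coupled pair is fitted (the donor rate);
the reverse rate is fixed by requiring that equipartition
($E_j \propto f_j$) be exactly stationary:
$k_{\mathrm{rev}} = k_{\mathrm{fwd}}\, f_{\mathrm{donor}}/f_{\mathrm{acceptor}}$.
The package applies the degrees-of-freedom ratios consistently in the design
matrix, the fluxes, and the effective gradient, so that all three vanish
together at equipartition. (For a homopolymer with equal $f_j$, as in the
decaresidue helix that motivates the defaults, the ratios drop out; an
`unscaled` convention reproducing plain energy differences is available via
`assemble_system(convention = "unscaled")`.)

All quantities use a fixed unit system: eV, K, ps, nm, atomic mass units;
$k_B = 8.617333262\times10^{-5}$ eV/K.

## The inverse problem

At each analysis bin $t_n$ (default width $\Delta t = 0.1$ ps) the unknowns
are $\mathbf{k} = (k_{1,2},\dots,k_{N-1,N}, k_{\mathrm{HB}})$: one backbone
rate per link and a single shared hydrogen-bond rate. Writing
$\bar E = \tfrac12[E(t_n) + E(t_{n-1})]$ for bin-midpoint energies, the fit
solves

$$
\mathbf{k}(t_n) = \arg\min_{\mathbf{k}\ge 0} \tfrac12 \lVert G(t_n)\,\mathbf{k} - \mathbf{d}(t_n)\rVert^2,
\qquad
d_j = \frac{E_j(t_n)-E_j(t_{n-1})}{\Delta t} + R_j k_s (\bar E_j - E_{s,j}),
$$

where the backbone column for link $p$ carries the exchange term
$X_p = \bar E_p - (f_p/f_{p+1})\bar E_{p+1}$ with $-X_p$ on row $p$ and $+X_p$
on row $p+1$, and the hydrogen-bond column accumulates the analogous
antisymmetric terms over all hydrogen-bond pairs. The solver is a
Lawson–Hanson active-set non-negative least squares written for determinism:
candidate variables enter by steepest gradient with the lowest index breaking
ties, so identical inputs always take identical paths. At the solution the
KKT conditions hold to $10^{-10}$ (relative): zero gradient on free
components, non-negative gradient on active ones.

Three numerical choices matter and are worth stating explicitly.

**Midpoint evaluation.** Evaluating $G$ at the bin midpoint makes the implied
integration rule Crank–Nicolson-like (second order in $\Delta t$). Evaluating
at $t_n$ instead would bias rates by $O(k\Delta t)$ — about 17% at
$k = 1.5\ \mathrm{ps^{-1}}$ and $\Delta t = 0.1$ ps — which is why the
midpoint form is the default and only form.

**Solvent rate.** Intramolecular exchange conserves total peptide energy, so
the solvent rate is identified from the total energy budget:

$$
k_s(t_n) = -\,\frac{\sum_j [E_j(t_n)-E_j(t_{n-1})]}{\Delta t\,\sum_j R_j(\bar E_j - E_{s,j})}.
$$

This ratio-of-sums estimator is exact on data generated by the master
equation (the exchange terms cancel identically in the numerator). Terms with
$|\bar E_j - E_{s,j}|$ below a guard of $10^{-6}$ eV are omitted; if the
whole denominator is guarded out the bin is flagged degenerate; a negative
estimate (possible under noise) is clamped to zero and flagged.

**Identifiability and the stacking window.** Every column of $G$ sums to
zero — pairwise exchange moves energy, it does not create it — so a single
bin provides at most $N-1$ independent equations for $N$ unknowns. Worse, the
shared hydrogen-bond rate is *exactly* degenerate with a telescoping chain of
backbone-rate increments: transferring energy directly from residue 1 to 4 is
indistinguishable, in one bin's $\dot E$, from passing it along
$1\to2\to3\to4$. A per-bin fit on a hydrogen-bonded topology therefore
returns one member of a one-parameter family of exact solutions. `fit_rates()`
resolves this by stacking `window = 2` consecutive bins per estimate: rates
are assumed locally constant at the coarse-graining scale (the premise of the
time-local analysis), while the exchange pattern differs between bins, which
restores full rank. `window = 1` gives the bare per-bin problem for
comparison. On noiseless constant-rate data the windowed fit recovers
backbone, hydrogen-bond, and solvent rates to better than 3% in every
free-relaxation bin, and to ~1% once the fast post-release transient has
passed. The one bin immediately after the heater releases carries the
steepest transient (effective eigenrates up to several $\mathrm{ps^{-1}}$ give
an $O((\lambda\Delta t)^2)$ finite-difference bias of up to ~6%); fits during
the heater window itself are meaningless because the pinned residue is not
governed by the free master equation. Discard both when interpreting rates.

## Fluxes, gradients, and sign conventions

For each coupled pair and bin, `compute_fluxes()` reports the net exchange
flux $J = k\,[\bar E_i - (f_i/f_j)\bar E_j]$ (eV/ps) and parameterizes it by
an effective temperature gradient

$$
\Delta_{ij} T_{\mathrm{eff}} = \frac{2\,[\bar E_i - (f_i/f_j)\bar E_j]}{3 N k_B},
$$

where $N$ is the atom count of the residue the flux is incident on — the
acceptor in the away-from-heater direction. Positive flux means flow away
from the heater; for a mid-chain heater, pairs straddling it are reported in
the low-to-high index direction. Flux and gradient share the same bracket and
the same sign, so the flux–gradient characteristic is an honest
conductivity plot, and both vanish identically at equipartition.

## Transport regimes, diffusivities, and barriers

`bin_by_gradient()` pools flux records into uniform gradient bins (default
1.0 K, half-open), split by bath-temperature class — low 230–270 K, high
290–330 K, and an "all" class; bins with fewer than `min_count` records
(default 10) are flagged unreliable. `fit_linear_regime()` then fits
mean flux against gradient by weighted least squares ($1/\mathrm{sem}^2$),
excluding $|\Delta_{ij}T_{\mathrm{eff}}| < 4$ K where a residual ballistic
component inflates apparent rate constants. The slope is the per-link
effective conductivity $\kappa_{\mathrm{eff}}$ (eV K$^{-1}$ ps$^{-1}$); the
intercept is the zero-gradient (ballistic) flux offset. Conversion to a
diffusivity uses the lattice relations $k = D/\Delta x^2$ and
$J = k\,C\,\Delta T$:

$$
D_{\mathrm{eff}} = \kappa_{\mathrm{eff}}\,\Delta x^2 / C,
$$

with an explicit per-link heat capacity $C$ (default
$\tfrac32 \bar N k_B$ with $\bar N = 13$ atoms) and $\Delta x = 0.2$ nm;
both constants are configurable and always reported with the result, since
the conversion is not fixed by the flux data themselves.
`segment_regimes()` fits regions between boundaries (defaults 15, 30, 50,
77 K, labelled A–D; data beyond the last boundary — the earliest, most
strongly localized dynamics — are excluded).

**Barriers.** Activated transport $k = \Omega e^{-\Delta F / k_B T}$ implies,
at matched gradients, $J_H/J_L = e^{-\Delta F/k_B T_H + \Delta F/k_B T_L}$,
inverted by `barrier_from_ratio()`:
$\Delta F = \ln(J_H/J_L)\,/\,[1/(k_B T_L) - 1/(k_B T_H)]$, with class
temperatures defaulting to 250 and 310 K (the class means).
`barrier_profile()` applies this per gradient bin with first-order error
propagation. The `use_local = TRUE` option adds each bin's mean temperature
elevation to the class temperature; this matters whenever the rates follow
the local rather than the bath temperature. Under a single-pulse heater
protocol, gradient and elevation are strongly correlated — moderate gradients
occur mostly at early times with elevations of order $10^2$ K — so the
bath-class temperature difference controls the rate ratio only when the
generating rates are themselves set by the bath temperature. Synthetic checks
here therefore use ensembles whose rates are constant in time at
$k = \Omega e^{-\Delta G / k_B T_B}$; with locally temperature-dependent
rates the published-convention ratio estimator is systematically biased (the
local temperatures of the two classes converge at high elevation), which is a
property of the estimator, not of its implementation.

**Peak-arrival diffusivity.** `tmax_diffusivity()` implements the benchmark
model $t_{\max} = d^2/D$: per residue, the time of maximal elevation
(parabolic sub-bin refinement by default) against squared distance from the
heater, fitted through the origin. Note the model is used exactly as stated,
without the factor 2 a 1-D point-source solution would carry
($t_{\max} = d^2/2D$); with the factor included all reported $D$ would halve.
Peak-arrival estimates also absorb residual ballistic components and
generally exceed flux-gradient diffusivities — both reasons this estimator is
kept as a benchmark, not the primary analysis.

**Front velocity.** `front_velocity()` estimates a ballistic front speed from
threshold arrival times (default 5 K, two consecutive bins to reject
single-bin noise — the threshold is a convention, since a front drawn on a
profile has no unique numeric definition) and tests the arrival-time/distance
relation for curvature: diffusive spreading has $t \propto d^2$, so a
significantly positive quadratic coefficient flags the profile as
non-ballistic.

## The synthetic generators

The generators exist so that every pipeline stage can be validated by
parameter recovery, with no molecular dynamics in the loop.

**Master-equation ensembles.** `simulate_master_equation()` integrates the
master equation with classical RK4 at an internal step of $10^{-3}$ ps
(compiled; error far below all other scales), recording every 0.1 ps. The
heater protocol mirrors a transient thermostat: the heated residue (default
residue 1) is pinned at $T_B + \Delta T$ ($\Delta T = 670$ K) for 1 ps —
pinning is the deterministic analogue of thermostatting one residue — then
the whole chain relaxes freely. Rates are either constant or locally
activated, $k = \Omega e^{-\Delta G/k_B T_{\mathrm{loc}}}$ with
$T_{\mathrm{loc}}$ the arithmetic mean of the pair's instantaneous kinetic
temperatures (a symmetric, local choice).

**Noise model.** Finite-ensemble scatter is emulated by perturbing each
recorded energy with an independent Gaussian of standard deviation
$\sqrt{f_j/2}\,k_B T_j \times \mathrm{scale}$ — at scale 1 this is the full
equilibrium fluctuation of a residue's instantaneous kinetic energy (relative
size $\sqrt{2/f_j} \approx 23\%$ at $f_j = 39$), and the recorded-energy
variance matches $(f_j/2)(k_B T)^2 \mathrm{scale}^2$ by construction.
Recorded values on the 0.1 ps analysis grid, however, emulate 100-fs block
averages, whose fluctuation is smaller by roughly
$\sqrt{\tau_{\mathrm{corr}}/\Delta t}$; with a kinetic-energy correlation
time of ~12 fs this gives scale $\approx 0.35$, which is what the standard
fixture battery uses. The distinction has teeth: at scale 1 and 500-member
ensembles, the exchange terms for gradients below ~40 K sit within a few
noise standard deviations of zero, where errors-in-variables attenuation and
the non-negativity clamp bias every rate estimator — no analysis choice
recovers barriers there. Member noise streams derive from the master seed
and the member index, so ensembles are reproducible and order-independent.

**What the generator does not emulate.** Real trajectories have correlated,
non-Gaussian fluctuations, anharmonic mode structure, conformational
heterogeneity within an ensemble, and solvent with spatial structure. Passing
recovery tests shows the estimators are consistent for data generated by the
model they invert — a necessary check, not evidence about force fields or
real peptides.

**Lattice surrogate.** `simulate_lattice()` provides a genuinely nonlinear
testbed that is *not* the fitted model: a 1-D FPU-$\beta$ chain (harmonic
plus quartic nearest-neighbour potential; defaults 64 sites, mass 12 u,
$k = 3.1$ eV/nm², $\beta = 15$ eV/nm⁴, spacing 0.2 nm) integrated by
velocity Verlet with BAOAB Langevin thermostatting of a heater segment, and
a deterministic cross-platform RNG. Groups of 8 sites form pseudo-residues
so the dump feeds the same readers and fits. In the harmonic microcanonical
limit the integrator conserves total energy to $10^{-8}$ (relative) over
100 ps at $\mathrm{d}t = 2\times10^{-5}$ ps, thermostatted chains
equilibrate to the bath temperature, and a kicked-site pulse propagates at
the band-edge group velocity $a\sqrt{k/m}$ — three independent physics
checks on the surrogate itself.

## Statistical conventions in the validation suite

Ensembles are analysed either per member or — the low-noise route used by
the recovery checks — by averaging members into one mean trajectory before
fitting (`ensemble_mean_trajectory()`); at realistic noise the per-member
finite differences at 0.1 ps are noise-dominated, and averaging first is the
statistically sound option. Because consecutive rate estimates share one
stacked block, time-clustered populations of a gradient bin carry lag-1
noise correlation of about 0.5, and naive standard errors understate by about
$\sqrt{2}$; the barrier-recovery checks inflate sems accordingly and restrict
the flat-profile verdict to bins with gradients of at least 10 K (where the
exchange term exceeds ~6 noise standard deviations on a 500-member mean).
Problem sizes throughout the suite — 10-residue chains, 6 bath temperatures,
500 members per temperature, 8–10 ps of relaxation, 100-draw solver
comparisons, 100 ps lattice runs — were chosen as the smallest ensembles at
which the statistical checks are meaningful.

## Known limitations

* The per-bin rate fit is only informative where exchange terms are resolved
  above the noise floor; near equipartition the non-negativity clamp biases
  rates upward, which is why near-zero-gradient bins are excluded from
  regime fits.
* The shared-$k_{\mathrm{HB}}$ degeneracy is broken by time-locality, not by
  the data of a single bin; analyses needing strictly per-bin estimates on
  hydrogen-bonded topologies should treat the hydrogen-bond/backbone split
  as partially identified.
* The $\kappa \leftrightarrow D$ conversion depends on an assumed per-link
  heat capacity and spacing; only their combination is constrained by data.
* Barrier estimates from bath-class ratios assume the bath temperature
  controls the rates; with strongly heated systems prefer `use_local = TRUE`
  and treat the profile quantitatively only where elevations are modest.
* All dynamics are classical; no quantum corrections are attempted at low
  temperature.

## A worked miniature

```{r example, eval = FALSE}
topo <- build_topology(10, helix = "310")
model <- kinetic_model(topo, bath_temperature = 300,
                       k_backbone = 1.5, k_hbond = 0.5, k_solvent = 0.05)
ens <- simulate_master_equation(model, heater_protocol(), t_total = 8,
                                n_members = 50, seed = 1, noise_scale = 0.35)
mean_tr <- ensemble_mean_trajectory(ens)
rates <- fit_rates(mean_tr, topo)
fluxes <- compute_fluxes(mean_tr, topo, rates)
bins <- bin_by_gradient(fluxes)
segment_regimes(bins)
autoplot(bins)
```
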