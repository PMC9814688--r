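---
title: "Cavity thermodynamics of polymer cononsolvency at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cavity thermodynamics of polymer cononsolvency at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cononsolv` studies why adding a small amount of an amphiphilic cosolvent
(an alcohol) to a good solvent (water) can *collapse* a polymer that both
pure solvents dissolve — cononsolvency — and, specifically, how much of the
effect lives in purely repulsive, solvent-excluded-volume physics. The
package implements the full free-energy machinery at a scale where every
quantity can be recomputed on one CPU in minutes: a stochastic-dynamics
engine for coarse-grained bead models, umbrella sampling with WHAM along
the radius of gyration, thermodynamic integration (TI) of cavity-formation
work with soft-core potentials, and solvation-shell analysis.

## The model

The solute is the generic hydrophobic bead polymer: 32 uncharged
Lennard-Jones beads with $\sigma_p = 0.4$ nm and
$\epsilon_p = 1.0$ kJ/mol, harmonic bonds and angles
(`polymer_topology()`; the shipped bonded constants $r_0 = 0.4$ nm,
$\theta_0 = 180^\circ$, soft $k_\theta$ are package defaults — the original
bead model's bonded constants are not published with its nonbonded ones,
so ours are configurable placeholders). Unlike-pair interactions follow
Lorentz–Berthelot mixing; polymer–water and polymer–alcohol well depths
are multiplied by $\lambda_{pw} = 1.095$ and $\lambda_{pa} = 0.949$
(diameters unchanged), the scalings that put the chain under good-solvent
conditions at 300 K in the production protocol.

The binary solvent is deliberately reduced. Instead of explicit SPC/E
water and united-atom alcohols — far beyond a desk-scale budget because of
electrostatics — `reduced_solvent_spec()` defines:

* a one-site *water-like* liquid, $\sigma_w = 0.30$ nm,
  $\epsilon_w = 3.7$ kJ/mol (hydrogen-bond cohesion folded into the well
  depth so the fluid is a dense liquid at 300 K, $T^* \approx 0.67$);
* a one-site *methanol-like* cosolvent, $\sigma_a = 0.45$ nm,
  $\epsilon_a = 3.0$ kJ/mol — larger and less cohesive per unit surface
  than water, hence interfacially active, which is the microscopic premise
  of the surfactant mechanism;
* a two-site bonded *ethanol-like* cosolvent (two $\sigma = 0.40$ nm
  sites, bond 0.25 nm), so the cosolvent-size trend is testable as a pure
  size effect;
* a water–alcohol cross-interaction factor $\xi_{wa} = 0.90$ scaling the
  mixed well depth below its Lorentz–Berthelot value. This is the
  documented tuning knob that strengthens the cosolvent's surface
  activity while keeping the mixture miscible; it was set once against
  the wall-enrichment fixture (below) and not revisited.

Per-molecule liquid volumes ($v_w = 0.0321$, $v_{MeOH} = 0.120$,
$v_{EtOH} = 0.121$ nm$^3$) were calibrated once from barostatted
pure-liquid runs of this model at 300 K and 1 atm; they are used only to
size initial boxes, which a Monte Carlo volume barostat then
re-equilibrates.

What the reduced model *does* emulate: liquid-state packing, the
water/alcohol size and cohesion asymmetry, preferential adsorption of the
cosolvent on repulsive (hydrophobic) surfaces, and composition-dependent
cavity work. What it does *not* emulate: hydrogen-bond networks,
electrostatics, temperature-dependent hydration entropy, and any
quantitative mapping to real water–alcohol thermodynamics (surface
tensions, mixing enthalpies). Passing tests on this model demonstrate the
mechanism's internal consistency, not atomistic accuracy.

## Dynamics

`run_segment()` propagates BAOAB-discretised Langevin dynamics (time step
2 fs, inverse friction constant 0.1 ps, 300 K) under orthorhombic periodic
boundaries with minimum-image pair evaluation (a Verlet neighbour list
with a 0.25 nm skin inside the propagation loop, a cell list for
single-point evaluations when the box admits three cells per dimension,
all-pairs otherwise — all verified mutually equal in the tests). Positions are stored unwrapped, so molecules are never broken
across images and the radius of gyration needs no re-assembly; an
integrity guard errors if any bond ever exceeds half the box. In the
limit of zero friction and temperature the integrator reduces to velocity
Verlet (checked by an energy-drift test); at finite friction it samples
the exact Gaussian distribution in a harmonic well and equipartitions an
LJ fluid within 2%.

Constant pressure uses Monte Carlo volume moves (ln-V proposals,
molecular centre-of-mass scaling, acceptance
$\exp[-\beta(\Delta U + P\Delta V) + (N_{free}+1)\ln(V'/V)]$). Molecules
held by position restraints are *excluded* from the scaling and from
$N_{free}$ — the analogue of fixed-reference-coordinate scaling. This
matters: scaling the restraint references with the box lets an internally
strained (overlapping-bead) globule ratchet the box open move by move,
because each accepted expansion of the reference scaffold releases
intramolecular strain after the fact. With fixed references the volumes
equilibrate to the correct liquid densities at every coupling value.

## Collapse free energy: umbrella sampling + WHAM

The collective variable is the equal-mass radius of gyration (all beads
are identical, so this coincides with the mass-weighted one). Windows
carry the harmonic bias $V(R_g) = \tfrac{k_b}{2}(R_g - R_g^o)^2$ with
$k_b = 20000$ kJ mol$^{-1}$ nm$^{-2}$ on the grid 0.4–1.2 nm, spacing
0.025 nm (33 windows). `wham_solve()` runs the standard self-consistent
iteration to tolerance $10^{-8}\,RT$ on the window free energies (bin
width 0.01 nm — finer than the window spacing; halving it moves the
two-state free energy by under 0.05 kJ/mol on fixtures); uncertainties
come from a Bayesian bootstrap over windows (Dirichlet weights, 50
resamples) since the production protocol does not state an error method.

The two-state collapse free energy is
$e^{-\Delta G^{C\to G}/RT} = \int_0^{R^\#} e^{-w/RT} dR_g \big/
\int_{R^\#}^{\infty} e^{-w/RT} dR_g$ with $R^\# = 0.7$ nm, the barrier
top separating the globule and coil basins. `collapse_free_energy()`
treats the tabulated profile as piecewise linear and integrates each
segment on a refined trapezoidal grid; the upper limit truncates at the
last finite bin, justified because $e^{-w/RT}$ is negligible there on all
profiles we generate (the coil basin is well inside the sampled range).
The result is invariant to the profile's additive anchor.

WHAM correctness is validated against analytic double-well profiles
(two-Gaussian mixtures) whose mixture weight is solved so that the exact
two-state integral equals a prescribed $\Delta G^*$; biased samples are
drawn by inverse-CDF sampling and pushed through the full pipeline, which
must recover $\Delta G^* \in \{-4, -2, 0, +2\}$ kJ/mol within 0.2 kJ/mol.

## Cavity work: thermodynamic integration

$\Delta G_{Excl\text{-}Vol}$ — the reversible work of carving a
polymer-shaped, purely repulsive (WCA) cavity into the solvent — is
computed for the most probable coil ($R_g = 1.0$ nm) and globule
($R_g = 0.5$ nm) conformations, frozen by stiff position restraints
($k = 10^5$ kJ mol$^{-1}$ nm$^{-2}$). Polymer–solvent interactions are
coupled through the Beutler soft-core form
$r_{sc} = (\alpha\sigma_{sc}^6(1-\lambda)^p + r^6)^{1/6}$,
$V = \lambda V_{WCA}(r_{sc})$ with $\alpha = 0.5$, $p = 1$,
$\sigma_{sc} = 0.3$ nm, which keeps $\partial U/\partial\lambda$ finite
everywhere including $r = 0$. $\lambda = 0$ is the cavity-free binary
solvent (the restrained polymer is a ghost; its intramolecular terms are
retained — they are $\lambda$-independent and cancel in all differences).

Two numerical choices matter at desk scale and are worth stating plainly:

1. **Schedule.** The production protocol's 21 evenly spaced $\lambda$
   values remain the default. For the desk-scale campaigns we use 10--13
   points on a quadratic map (`lambda_schedule(n, power = 2)`): $\langle\partial U/\partial\lambda\rangle$
   decays on a scale $\lambda \sim kT/\bar u \approx 0.01$ (set by the
   $\sim$200 kJ/mol soft-core energy of a solvent molecule inside the
   ghost region), and a uniform grid neither resolves that boundary layer
   nor damps its large statistical variance, which a clustered grid
   suppresses through its tiny quadrature weights.
2. **Direction.** $\lambda$ points are chained downward from the fully
   coupled state. Softening the cavity lets solvent seep *into* the
   opening region — fast, barrier-free relaxation — whereas growing it
   from $\lambda = 0$ requires squeezing solvent *out through* the
   solute interior, which for a compact globule traps molecules in deep
   soft-core overlap and produces severe hysteresis. Points with
   $\lambda < 0.1$ get triple equilibration because the ghost region must
   refill by diffusion.

Each (conformation, composition) system is solvated in a box sized from
the conformer's spatial extent plus a 0.5–0.6 nm clearance per side
(`conformer_box()`), filled at the model's liquid molar volumes and
pressure-equilibrated; the coil therefore sits in roughly 1100–1500
solvent sites and the globule in 300–450. Trapezoidal quadrature
integrates $\langle\partial U/\partial\lambda\rangle$ with block-averaged
standard errors (5 blocks), and
$\Delta\Delta G^{C\to G}_{Excl\text{-}Vol} = \Delta G^G - \Delta G^C$.
TI is cross-checked against a Widom test-particle oracle for a single
small site in a 100-particle liquid, where both estimators are sharp.

## Adsorption, saturation and SASA

First-shell occupancies count solvent molecules with any site within
0.55 nm (the first minimum of the polymer–solvent RDF of this model;
`shell_cutoff_from_rdf()` recomputes it on demand) of any polymer bead.
The preferential binding coefficient is the standard estimator
$\Gamma = \langle n_a\rangle_{shell} -
(N_a^{bulk}/N_w^{bulk})\langle n_w\rangle_{shell}$ with per-frame bulk
counts taken outside the shell; the exact production-protocol estimator
lives in supplementary material not available to this package, so the
standard form is a documented decision. For coil/globule comparisons both
conformations are solvated in the *same* box size so their reservoirs are
identical. Saturation of the shell versus bulk composition is fitted to a
Langmuir form $n(X) = n_{max} K X/(1+KX)$, and the saturation composition
is the smallest grid point where the fitted local slope drops below 10%
of its initial value (closed form $(1/\sqrt{0.1}-1)/K$); profiles that
stay linear return `NA` with a warning.

Solvent-accessible surface areas use Shrake–Rupley golden-spiral
quadrature (bead radius $\sigma_i/2$, probe 0.14 nm, 960 points — within
1% of the closed form for an isolated sphere). `sasa_scaling()` grows
extended and collapsed conformers over chain lengths (default
16–128) and fits log–log slopes: an ideal rod gives
$\alpha \to 1$, compact packing $\alpha \to 2/3$, and the package asserts
$\alpha_{coil} > \alpha_{globule}$ — the geometric fact behind the
molecular-weight dependence of cononsolvency.

## Conformer generation

`make_conformers()` builds coils as correlated self-avoiding walks whose
bending persistence is bisected until $R_g$ hits its target within 5%
(with a bound on the largest pairwise extent so the conformer is globally
isotropic and fits a desk-scale box), and globules by centroid-biased
compact growth with the site-spacing floor bisected the same way. Default
targets follow the production states at $N = 32$ (coil 1.0 nm, globule
0.5 nm) scaled as $N^{3/5}$ and $N^{1/3}$. All generators are pure
functions of (spec, seed).

## Problem sizes and determinism

The shipped test and acceptance runs use: 33 windows $\times$ 2$\times$10$^4$
synthetic samples for WHAM validation; 100-particle fluids for the
TI–Widom cross-check; 32-bead chains with 300–1500 solvent sites, 13
$\lambda$ points and 2–3 ps production per point for the mechanism
campaigns; 10$^4$ decorrelated samples for the harmonic-well
distribution test. These sizes were chosen so the full pipeline
reproduces its qualitative claims in minutes on a single CPU; every
stochastic stage takes an explicit integer seed and derives per-window /
per-$\lambda$ streams from it (`derive_seed()`), so any single stage is
reproducible in isolation.

## Known limitations

* The reduced solvent cannot reproduce atomistic numbers. In particular,
  the production-scale result that the *unscaled* polymer collapses at
  about $-2$ kJ/mol in explicit SPC/E water requires the atomistic stack
  (5000-molecule boxes, PME electrostatics, 21 ns windows) and is out of
  scope here; the configuration defaults record that protocol's
  parameters with provenance tags, but no desk-scale run reproduces its
  values.
* Cavity works carry finite-size effects from the 0.5–0.6 nm solvent
  clearance and the truncated (1.0–1.4 nm, unshifted, no tail
  correction) LJ potential; trends across composition at fixed protocol
  are the meaningful output, not absolute values.
* The soft-core boundary layer near $\lambda = 0$ is integrated with a
  clustered grid; residual quadrature bias is a few percent of the
  cavity work and largely cancels in coil–globule differences.
* Downward $\lambda$-chaining removes trapping hysteresis but means
  successive $\lambda$ points share history; block-averaged errors are
  per-point and do not account for that correlation.
* At desk-scale box sizes the cosolvent reservoir is small, so strong
  adsorption depletes the bulk; the common-box setting mitigates the
  coil/globule asymmetry but absolute $\Gamma$ values are
  reservoir-limited at low composition.
* The *interior minimum* of
  $\Delta\Delta G^{C\to G}_{Excl\text{-}Vol}(X)$ -- the defining
  signature of excluded-volume cononsolvency -- is at the edge of what
  this reduced model can resolve. The coil exposes about 2.6 times the
  globule's surface, so the area-proportional part of the cavity-work
  decrease always favours the coil; the counteracting
  differential-adsorption term is of order
  $\int(\Gamma_G - \Gamma_C)\,d\mu_a \approx$ a few kJ/mol (from the
  measured $\Gamma_G - \Gamma_C \approx 0.6$ molecules at low $X$),
  an order of magnitude below the few-tens-of-kJ/mol precision of the
  desk-scale TI difference. The same applies to the adsorption route:
  replicate campaigns leave the absolute-excess ordering
  $\Gamma_{globule}$ vs $\Gamma_{coil}$ unresolved (point estimates
  mostly favour the coil, as its larger surface suggests), even though
  positive adsorption on the repulsive surface itself is strong and
  reproducible. The pipeline therefore resolves the monotone
  composition dependence, the always-negative coil/globule difference and
  the existence of surfactant-like adsorption, while the *differential*
  coil-versus-globule screening signatures (interior minimum, excess
  ordering) need reservoirs and run lengths far beyond desk scale.
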