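---
title: "Modelling microtubule tip dynamics with curved protofilaments"
author: "mtdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling microtubule tip dynamics with curved protofilaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mtdyn` simulates the plus-end of a 13-protofilament (PF) microtubule as a
mechanochemical system.  Every tubulin monomer is a 2 nm sphere confined to
the radial plane of its PF, with three degrees of freedom: radial deviation
from the wall cylinder `x`, axial position `z`, and in-plane rotation
`tau`.  The alpha- and beta-monomers of a dimer are treated identically,
and the 13-PF ring is unstaggered (no seam, no helical rise) — the minimal
geometry consistent with strictly planar per-PF motion.

Interactions:

* **Intra-dimer springs.** The two monomers of a dimer are joined through
  longitudinal sites at their poles by a Hookean spring,
  `U(r) = k r^2 / 2` with `k = 310` kcal mol^-1 nm^-2.
* **Bending.** Adjacent monomers in a PF pay
  `W(theta) = B (theta - theta0)^2 / 2` with an *intrinsically curved*
  equilibrium `theta0 = 0.2` rad per monomer hinge (a relaxed PF is a
  "ram's horn" of ~20 nm radius; this curvature is shared by both
  nucleotide states).  The default stiffness `B = 174`
  kcal mol^-1 rad^-2 sits between literature extremes of 14-300, which
  map to dynamic persistence lengths of roughly 0.2-4 um (see below).
* **Breakable bonds.** Inter-dimer longitudinal and lateral contacts use
  `E(r) = 2 a (r/w)^2 exp(-r/w) - b exp(-r^2/w^2)`: a well of depth `b`
  at contact, separated from the unbound state by an activation barrier
  whose height scales with `a` (for `b = 0` the maximum is exactly
  `8 exp(-2) a` at `2 w`).  The lateral barrier `a_lat` is the
  model's key control parameter: it sets how much force the tip can
  generate and how ragged it grows.
* **Steric repulsion.** Tubulin vs Dam1 subunits or the obstacle:
  `rho(d) = k_rep (R + r - d)^2` inside contact (no 1/2 prefactor — the
  potential is defined that way, unlike the spring convention; the code
  implements it as defined).
* **Dam1 linkers.** A flat well of depth `E_depth` out to the
  equilibrium linker length `l0 = 5` nm, rising harmonically to zero at
  `l_max = 6` nm; continuity fixes
  `E_depth = k_linker (l_max - l0)^2 / 2`.  With the linker stiffness of
  0.01 kcal mol^-1 nm^-2 the well is ~0.008 kBT — the ring is held by
  sterics against the flared PFs, not by adhesion.

Dynamics use the overdamped (Ermak-McCammon / Euler-Maruyama) update
with per-monomer drags `gamma_q = 6 pi r eta` and
`gamma_tau = 8 pi r^3 eta` at `eta = 1e-3` Pa s and `T = 310` K, with a
fast compiled kernel shared by every experiment in the package (isolated
PF, full lattice, couplers).  A kinetic Monte-Carlo layer runs every
`t_kin = 13` ms of physical time: each PF gains a GTP dimer with
probability `P = k_on c_tub t_kin`, appended co-tangentially to the tip
with unstretched bonds and hinge increments `theta0`; each GTP dimer
hydrolyses with probability `1 - exp(-k_hydr t_kin)` (`k_hydr = 0.24`
/s).  Hydrolysis switches parameters instantaneously at dimer
granularity, in one of two modes: weaker lateral bonds
(`b_lat` 8 -> 4.7 kcal/mol) or stiffer PFs (`B` 78 -> 174).

## Numerical choices

* **Time step.** The stiffest interactions (intra-dimer spring; bond
  wells) set relaxation times of ~17 ps; the stochastic integrator uses
  `dt = 2` ps by default and construction refuses
  `dt > gamma_q / (5 k_eff)` for the stiffest effective spring constant
  of the parameter set.  Zero-temperature relaxations are pure gradient
  descent, which only requires Euler stability; they use a larger step
  derived from both the translational and rotational stability bounds
  (rotation sees bond stiffness amplified by `r_tub^2`).
* **RNG.** One xoshiro256++ generator per run, seeded from the single
  run seed, with a ziggurat normal sampler; identical seed and
  configuration give bit-identical trajectories.
* **Detachment.** An oligomer is removed when its connecting inter-dimer
  bond satisfies `|E_long| < 0.1 kBT` *and* is stretched beyond the
  barrier (`2 r_long`).  The second clause disambiguates the energy
  criterion: `|E|` also transits 0.1 kBT briefly at the well-to-barrier
  zero crossing during ordinary vibration, which must not count as
  detachment.  The scan runs on its own interval (default 0.1 us; it is
  cheap next to the Brownian layer).
* **Computational window.** Only the terminal `window_dimers` (default
  20) dimers of each PF are mobile; deeper layers are frozen as the
  lattice boundary and the window follows the tip.
* **Lateral geometry.** PF n lives in the radial plane at azimuth
  `2 pi n / 13`; lateral sites sit at the azimuthal midpoint between
  neighbouring planes (offset `R tan(pi/13)`), so a perfect wall has all
  lateral pairs exactly at contact and curling by ~1 nm strains the
  bond by ~1 nm.  In-plane rotation does not move the lateral site — a
  monomer disengages laterally by displacing, not by rotating.
* **Curl origin rule.** The hand-tracing of tip shapes has no
  algorithmic origin definition, so the package uses its own: walking
  back from the tip-ward crossing of `wall_tolerance` (default 1.5 nm),
  the origin is where the radial deviation stops decreasing.  The
  tolerance and the back-walk slack are exposed, and the fixture
  generator quantifies the recovery error (< 10% over curvature
  0.02-0.06 rad/nm, curls 15-80 nm, noise <= 1 nm).
* **Mean curvature** is estimated as the least-squares slope of segment
  direction angle on arc length over the curl — identical to net
  turning / length for a uniform arc, far less noise-sensitive at the
  endpoints.
* **Raggedness** uses the sample (n-1) standard deviation of curl-origin
  axial positions.
* **Persistence length.** The tangent-correlation estimator fits
  `log <cos(delta(s') - delta(s'+s))>` against arc-length separation
  through the origin; the mean shape is the per-position average over
  snapshots.  For a hinge chain with iid deflection variance `s2` and
  spacing `l` the closed form is `xi_d = 2 l / s2 = 2 l B / kBT`, which
  for 4 nm monomer spacing maps `B` = 14-300 kcal mol^-1 rad^-2 onto
  ~0.18-3.9 um — the basis of the stiffness range quoted above.

## Timescales, and what desk-scale runs can and cannot show

At experimentally calibrated bond depths, every lattice event is a
thermally activated barrier crossing.  A longitudinal rupture at a
~11 kcal/mol effective barrier costs ~1e9 Brownian steps; reproducing a
shortening rate of hundreds of nm/s therefore needs ~1e10-1e11 steps —
parallel-computing territory, not a workstation test suite.  The package
exposes three devices for desk-scale work, all documented rather than
hidden:

1. **Desk operating points** (`desk_params()`).  The bond widths
   (`r_lat = 1.0`, `r_long = 0.5` nm) and depths are artifact
   parameters (not fixed by the printed model constants); the desk sets
   keep every printed constant (`theta0`, `B`, `k`, `k_rep`, ring
   geometry, `t_kin`, `k_hydr`, `k_on`) and reduce the *depths* so that
   unzipping and rupture happen on microsecond timescales.  The
   low-barrier (`a_lat = 2.1`) GDP set disassembles with 30-60 nm curls;
   the high-barrier (`a_lat = 6.3`) set follows the protocol of
   selecting the lateral depth per barrier height so that shortening
   speeds match.  Force-balance quantities (stall forces, force-velocity
   orderings) and shape statistics are comparatively insensitive to this
   re-scaling because they are dominated by quasi-static mechanics;
   absolute rates are not, and the package reports desk rates as desk
   rates.
2. **Kinetic-clock compression** (`time_compression`).  For
   addition-limited growth, the kinetic layer interval is compressed
   relative to the Brownian clock (per-event probabilities unchanged,
   recorded times re-expanded).  This is the separation-of-timescales
   argument: lateral zip/unzip runs orders of magnitude faster than
   subunit arrival, so compressing the arrival clock leaves the tip's
   mechanical steady state approximately intact.  Two distortions are
   acknowledged: tip shapes relax for less Brownian time between events,
   and thermal loss processes become relatively rarer (growth runs
   therefore overestimate retention; the measured critical
   concentration at strong compression is an underestimate).  Growth
   velocities of compressed runs are estimated as the net subunit flux
   (8 nm per completed 13-dimer layer): on desk windows the curl-origin
   length lags behind the flux by the zipping transient, while at steady
   state the two estimators agree.
3. **Zero-temperature force balance.**  Maximal sustainable forces are
   computed by bisection over gradient-descent relaxations, which is
   exact for the model and cheap; a stationary configuration is also
   accepted when the descent has stalled (gradient < 5e-2 with the
   dragged bead immobile over 1e5 steps), a tie-break needed near the
   critical force where the approach is along a very soft valley.

The synthetic-data generator (`make_fixture_traces()`) emulates traced
PF shapes — wall segment, circular-arc curl, scattered origins,
Gaussian point noise.  It does not emulate the cryoET missing wedge
beyond allowing partial rings, anisotropic point-spread, or tracing
ambiguities at crossings, so passing recovery tests bounds estimator
error on clean geometry, not tracing error on real tomograms.

## Parameters that matter

| parameter | default | units | status |
|---|---|---|---|
| `theta0` | 0.2 | rad | model constant |
| `B` | 174 (GTP modes: 78) | kcal/mol/rad^2 | model constant, range 14-300 |
| `k_intra` | 310 | kcal/mol/nm^2 | model constant |
| `k_rep` | 100 | kcal/mol/nm^2 | model constant |
| `a_lat` | 6.3 (regimes: 2.1, 4.2) | kcal/mol | key control parameter |
| `b_lat` | 8 (GTP) / 4.7 (GDP) | kcal/mol | nucleotide effect, mode 1 |
| `r_lat`, `r_long` | 1.0, 0.5 | nm | artifact defaults (widths unpublished) |
| `a_long`, `b_long` | 2.1, 7.0 | kcal/mol | artifact defaults, config-exposed |
| `k_on` | 0.26 | /uM/s/PF | yeast tubulin starting value |
| `t_kin` | 0.013 | s | kinetic layer interval |
| `k_hydr` | 0.24 | /s | hydrolysis rate |
| `detach_threshold` | 0.1 | kBT | detachment criterion |
| `dt` | 2e-12 | s | accuracy-bounded integrator step |
| `eta` | 1e-3 | Pa s | water at body temperature |
| `window_dimers` | 20 | dimers | mobile window |

## Design decisions taken where the design was open

* Passage counting for straightening uses two-threshold hysteresis
  (0.15/0.05 rad): dithering at a single threshold can never count.
* The equilibrium shape for the persistence-length deflection is the
  global per-position mean over snapshots (not per-snapshot detrending).
* New dimers land on the instantaneous tip tangent, not a relaxed one.
* Hydrolysis is permitted in any GTP dimer including the terminal one.
* Lateral bond depth for a mixed GTP/GDP pair is the arithmetic mean of
  the two monomers' depths.
* The ring keeps its centre on the MT axis by projecting the two lateral
  centre-translation modes out of the subunit displacement field each
  step; stiff neighbour springs (an artifact parameter) keep the ring
  coherent.  After linker rupture a subunit rebinds the nearest tubulin
  within `l_max`.
* The ring starts 16 nm below the lowest curl origin; the obstacle
  starts just clear of the highest tip monomer.

## Known limitations

* Strictly planar PF motion: no out-of-plane sheets or PF clusters, no
  twist.
* No seam and no helical stagger; lateral partners always share a layer
  index.
* Catastrophe statistics at physiological tubulin are out of reach (they
  are rare even for the original study); dilution protocols are used
  instead.
* Desk-scale rates are not physical rates (see the timescale section);
  every simulated-rate claim in the tests states the operating point it
  was measured at.
* The trace reader assumes an upstream tool has already projected each
  PF into its radial plane and exported ordered points.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run, per invocation, single-PF
trajectories of 0.2-2 ms (the straightening window), free-hinge and
free-monomer checks of 1e4-2e5 steps, persistence-length runs of
~0.05 ms, force-balance bisections over 3-4 stiffness values, lattice
runs of 5-30 us at the desk operating points, and compressed growth runs
equivalent to a few physical seconds.  These sizes were chosen as the
smallest that leave each statistical assertion with comfortable margin
over its own Monte-Carlo error.
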