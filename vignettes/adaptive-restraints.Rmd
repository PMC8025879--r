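---
title: "Adaptive reference restraints: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive reference restraints: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restraintr)
```

## The problem

Refining a macromolecular model against low-resolution data is
underdetermined: there are more coordinates than independent observations,
and the refinement will happily distort a chemically sensible model to chase
noise. A standard remedy is to restrain the working model towards a
*reference* -- its own starting coordinates, another chain of the same
assembly, or a homologous high-resolution structure. Such restraints must be
*top-out*: strong where model and reference agree, but progressively weaker
as the deviation grows, so that genuine differences supported by the data
are not fought. restraintr implements a family of such restraints for
interatomic distances and for backbone/side-chain torsions, the protocol
that derives a full restraint network from a model/template pair, tools to
classify, adjust and release restraints, a per-residue torsion chord score
for model comparison, and a simple relaxer that settles a model under its
restraint network.

## The distance potential

The distance restraint is a flat-bottomed generalised robust loss. With
deviation $x = \max(|d - r_0| - \tau,\, 0)$,

$$E(d) = k\,\frac{|\alpha-2|}{\alpha}\left[\left(\frac{(x/c)^2}{|\alpha-2|}
  + 1\right)^{\alpha/2} - 1\right],$$

where $r_0$ is the target distance, $\tau$ a tolerance half-width inside
which no bias at all is applied, $c$ the half-width of the approximately
quadratic core, and $\alpha$ the fall-off exponent. The $\alpha$ family
contains the classical losses as special cases: $\alpha = 2$ is harmonic,
$\alpha = 0$ the logarithmic (Cauchy-like) limit, $\alpha = -2$
Geman--McClure, and $\alpha \to -\infty$ the Welsch loss, whose bias
vanishes entirely at large deviations. $\alpha = 0$ and $\alpha = 2$ are
removable singularities of the general expression; the implementation
dispatches to the closed-form limits whenever $|\alpha| < 10^{-6}$ or
$|\alpha - 2| < 10^{-6}$, and accepts `-Inf` as an explicit Welsch
sentinel rather than relying on numeric overflow. Note that convergence to
the Welsch limit is first order in $1/|\alpha|$ (the prefactor
$|\alpha-2|/\alpha$ approaches $-1$ only as $2/|\alpha|$), so moderately
negative $\alpha$ values still sit visibly above the Welsch curve.

The flat bottom is symmetric about $r_0$. Asymmetric bounds (e.g. for
cross-link upper bounds) are out of scope; for reference restraints the
reference distance is the best available point estimate and a symmetric
tolerance reflects its uncertainty.

## The torsion potential

Angular deviations are periodic, so the torsion restraint is built from the
von Mises distribution, the periodic analogue of the normal distribution.
Starting from the negated numerator $g(\theta) = -e^{\kappa\cos\Delta}$
(with $\Delta = \theta - \theta_0$), the gradient
$\kappa\sin\Delta\,e^{\kappa\cos\Delta}$ peaks at

$$\cos\Delta_{F\max} = \frac{\sqrt{1 + 4\kappa^2} - 1}{2\kappa},$$

and dividing by the peak value $G(\kappa) = \sqrt{s}\,e^{s}$, with
$s = \kappa\cos\Delta_{F\max}$, renormalises the well so that the maximum
restraining gradient is exactly the spring constant $k$ *independent of the
well width* -- the property that makes the width a free parameter rather
than a strength dial. Choosing the integration constant so the minimum is
zero gives the top-out form

$$E_{10}(\Delta) = k\,\frac{e^{\kappa} - e^{\kappa\cos\Delta}}{\sqrt{s}\,e^{s}},$$

evaluated internally as $k\,e^{\kappa-s}(1 - e^{\kappa(\cos\Delta-1)})/\sqrt{s}$
so that it is overflow-safe up to very large $\kappa$. The natural width
parameter is $\Delta\theta_0 = 2\Delta_{F\max}$; the inverse map is closed
form, $\kappa = \cos(h)/\sin^2(h)$ with $h = \Delta\theta_0/2$, giving the
calibration pairs $\Delta\theta_0 = 60^\circ \leftrightarrow \kappa = 3.46$
and $120^\circ \leftrightarrow \kappa = 0.67$.

Outside its well $E_{10}$ is essentially flat. The adaptive extension adds
a tuneable fall-off by blending in a plain cosine:

$$E_{14}(\Delta) = (1-\alpha)\,E_{10}(\Delta) + \alpha\,k\,(1 - \cos\Delta).$$

This form was chosen (the design here was genuinely open) because it
satisfies every property required of the extension simultaneously: it is
*identical* to $E_{10}$ at $\alpha = 0$; for $\alpha > 0$ the gradient
outside the well is restraining and nonzero; negative $\alpha$ makes the
outside repulsive; $\alpha > 1$ is steeper than a plain cosine; it is
smooth and periodic everywhere; and its peak gradient drifts from $k$ by at
most about 36% over $\alpha \in [0, 0.5]$ and well widths
30--150°, consistent with the expected "small (typically
20--40%)" variation. Values of $\alpha$ between 0 and 0.5 are the
practically useful range; the default is 0.3.

Peptide-bond omega dihedrals are a special case: they are two-state
(cis/trans), so instead of the adaptive form they get a cosine penalty with
a ±30° flat bottom around the target isomer,
$E = \tfrac{k}{2}\bigl(1 - \cos\bigl((|\Delta| - 30^\circ)\cdot
\tfrac{180}{150}\bigr)\bigr)$ outside the flat region -- $C^1$ at the
boundary and maximal ($= k$) at the opposite isomer. The exact wall shape
is this package's choice; only the ±30° flat bottom and the cosine
character are fixed by convention. The omega spring constant defaults to
the torsion `spring_constant` (250 kJ/mol), another package choice, since
omega restraints conventionally ride on top of a force field's own omega
term and no separate value is established.

## Restraint generation

`generate_distance_restraints()` follows a five-step protocol:

1. Polymer residues of model and template are concatenated into per-class
   super-sequences (protein and nucleic acid separately).
2. The sequences are aligned globally (Needleman--Wunsch via Biostrings:
   BLOSUM62 with gap open/extend 12/1 for protein, +5/−4 with 8/1 for
   nucleic acids). Unaligned residues are simply not restrained. The
   original protocol uses a secondary-structure-based matcher here; a
   sequence aligner is a documented substitution, and for the dominant use
   cases (self-restraint, high-identity templates) yields identical
   pairings. Gap parameters are this package's choices, not established
   values.
3. The paired principal atoms (CA for protein, C4′ for nucleic acids) are
   superposed to find the largest pseudo-rigid body within a residual
   tolerance (5 Å default) by iterative superpose-and-trim: fit, drop the
   worst 10% of residuals, refit, until all members comply. Exact maximal
   coplanar-subset search is exponential; the greedy trim is deterministic
   and honours the tolerance semantics.
4. Within each rigid group, restraints are laid between eligible atom pairs
   -- the sparse default set (CA, CB, CG, CG1, OG, OG1 for protein, plus
   key base/ribose/phosphate atoms for nucleic acids), extendable via
   `custom_atom_names`, each atom present in *both* paired residues --
   whenever the template distance is below the cutoff (8 Å default),
   excluding intra-residue pairs and (unless `restrain_interfaces`)
   cross-chain pairs. Each unordered pair is restrained once. Parameters
   scale with the template distance $r_0$, on the reasoning that longer
   distances are less certain: $k$ = `kappa` (default 5),
   $\tau = 0.025\,r_0$, $c = 0.05\,r_0$, $\alpha = -2 - 4\ln r_0$ (defaults
   `tolerance` 0.025, `well_half_width` 0.05, `fall_off` 4, which place the
   loss between Geman--McClure and Welsch for typical distances).
5. Steps 3--4 repeat on the residues trimmed away, until fewer than three
   remain. Cross-group pairs are never restrained: each group was fitted
   independently, so inter-group template distances carry no meaning in the
   model frame.

`generate_torsion_restraints()` (protein only) restrains phi and psi to the
template values with the adaptive form (`angle_range` 60°,
`spring_constant` 250 kJ/mol, `alpha` 0.3 by default), chi torsions only
for residues whose identity matches, and omega to the template's cis/trans
state -- except that a cis-proline in the template facing a non-proline in
the model keeps the model's own isomer, since the cis state is essentially
a proline phenomenon. chi torsions are restrained to any depth where
defined; torsions with two-fold symmetric termini (Asp chi2, Glu chi3,
Phe/Tyr chi2) wrap deviations with a 180° period so the minimal
symmetry-equivalent deviation is used.

## Classification, adjustment, release, and the chord score

`classify_restraints()` labels each restraint `satisfied`, `strained` or
`beyond_well`. The boundary constants are display conventions, documented
rather than derived: a distance restraint is satisfied inside its flat
bottom and beyond the well once the effective deviation exceeds $2c$; an
adaptive torsion restraint is satisfied within one sixth of the well width
and beyond it past the full width; omega restraints are satisfied inside
the 30° flat bottom and beyond past 90° (the isomer boundary).
`release_restraints()` disables (never deletes) restraints by atom
selection, deviation cutoff, or classification state -- the pruning step
for restraints that visibly disagree with the data. `adjust_restraints()`
re-derives per-restraint parameters from new protocol-level values,
leaving targets untouched.

The chord score compares two models per residue through their torsion
deviations. Each torsion contributes $\sin^2(\Delta/2)$, the squared
half-chord of the deviation on the unit circle; backbone mode averages phi,
psi, omega and side-chain mode chi1/chi2 (optionally weighted, e.g. by
burial -- unweighted by default, with the weighting hook exposed). The raw
chord $2\sin(|\Delta|/2)$ evaluates to 0.765 at 45°, which is
inconsistent with the conventional calibration that 0.15 corresponds to an
average deviation of about ±45°; the squared half-chord gives
$\sin^2(22.5^\circ) = 0.146$, just under the 0.15 threshold, and is
therefore the default, with the raw form available via `form = "chord"`.
This is an interpretation choice, recorded as such.

## Settling

`settle()` relaxes coordinates by chunked L-BFGS-B minimisation
(`stats::optim`) of the total restraint energy with analytic gradients,
recording a monotone energy trajectory and stopping on a force tolerance
(0.01 kJ/mol/Å per component by default). Minimisation was chosen over a
simpler steepest-descent scheme after the latter proved unable to traverse
the stiff, strongly coupled distance/torsion network; L-BFGS-B is equally
deterministic and its per-chunk line searches preserve monotonicity. The
relaxer is a stand-in for settling a model by simulated-annealing molecular
dynamics in an interactive environment; it claims no equivalence with a
force-field simulation.

Two optional terms accompany the restraints. A soft-sphere clash penalty
(quartic repulsion below scaled van der Waals contact, default off) keeps
non-bonded atoms apart. A *stereochemistry regulariser* (default on in
`settle()`, absent from `total_energy_and_forces()` so restraint energetics
remain testable in isolation) holds backbone, CB and gamma-atom bond
lengths and angles at ideal dictionary values with harmonic terms
($k_\text{bond}$ 2000 kJ/mol/Å², $k_\text{angle}$ 200 kJ/mol/rad²). The
regulariser reflects how these restraints are used in practice: the sparse
restraint network deliberately excludes the peptide-bond atoms, delegating
covalent geometry to the MD force field it normally runs alongside. A bare
restraint network leaves each N and C atom a one-dimensional slack manifold
(three torsion constraints minus the omega flat bottom), so a pure-restraint
minimiser reaches zero restraint energy while those atoms keep most of
whatever distortion they started with; the regulariser supplies exactly the
missing covalent information and nothing else.

## The toy-structure generator

`build_toy_structure()` builds ideal-geometry helices, strands and
dipeptides from internal coordinates (standard bond lengths and angles;
phi/psi/omega/chi1 set exactly, so the generator doubles as its own torsion
oracle), with seeded Gaussian coordinate noise and/or torsion kicks. Each
residue carries N, CA, C, CB and its gamma heavy atom -- precisely the
atoms that participate in restraint generation, backbone torsions and chi1.
Carbonyl O and hydrogens are not built: they take part in no restraint
term, so under a restraint-driven relaxer they would only ever retain their
injected noise, telling us nothing about the restraints while obscuring
what the recovery experiments measure.

What the generator emulates: local covalent geometry, secondary-structure
torsion patterns, tunable Cartesian/torsional error. What it does not:
side chains beyond the gamma atom (so chi2+ restraints are exercised only
via the dictionary, not the fixtures), packing of multiple chains, solvent,
B-factor/occupancy structure, and real experimental error correlations.
Passing tests therefore demonstrate the correctness of the potentials,
protocol and bookkeeping -- not that the default parameters are optimal on
real crystallographic or cryo-EM data, which is established elsewhere by
refinement experiments that require deposited structure factors and are out
of scope here.

## Numerical choices

* Angles are degrees at every public interface, radians internally;
  wrapping is onto $(-180, 180]$, with per-torsion reduced periods for
  symmetric termini.
* The torsion energy and gradient are evaluated in shifted-exponential form
  ($e^{\kappa\cos\Delta-s}$ rather than $e^{\kappa\cos\Delta}/e^{s}$), safe
  for $\kappa$ far beyond the useful range.
* The von Mises density uses the exponentially scaled Bessel function for
  the same reason.
* `kappa_from_well_width()` and `max_gradient_angle()` are closed form; no
  numeric inversion is involved.
* Dihedral gradients use the standard four-point analytic formulas; all
  gradients in the package (distance, torsion, omega, clash, stereo) are
  verified against central finite differences in the test suite.
* Degenerate geometry (collinear atoms in a dihedral, coincident atoms in a
  distance gradient) raises an error or contributes zero force rather than
  NaN.
* Ties in altloc occupancy resolve to the first conformer code; hydrogens
  are dropped on read.

## Problem sizes used by the test suite

Unit and property tests run on toy structures of 5--50 residues. The
recovery experiment settles a 20-residue helix perturbed with 0.5 Å
per-coordinate Gaussian noise, self-restrained with all defaults, over ten
seeds; the suite verifies that at least nine of ten seeds return within
0.3 Å heavy-atom RMSD of the template and that stronger distance restraints
(kappa 5 vs 1) give a smaller median final RMSD. These sizes exercise every
code path (multiple rigid groups, glycine handling, termini) while keeping
the full suite to a couple of minutes.

## Known limitations

* Torsion restraints are protein-only; nucleic acids get distance
  restraints only.
* The aligner is sequence-based; templates with high structural but low
  sequence similarity will pair fewer residues than a structure-based
  matcher would.
* The rigid-body search is greedy; a pathological residual landscape could
  split what a maximal search would keep together.
* The relaxer finds local minima; it will not re-fold a model across
  barriers the way annealed interactive MD can.
* Per-restraint Bayesian weighting (conservation, local flexibility,
  burial) is out of scope; parameters are global or simple functions of
  $r_0$.
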