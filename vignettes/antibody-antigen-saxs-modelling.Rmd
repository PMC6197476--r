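---
title: "Methods: ensemble modelling of antibody-antigen complexes against SAXS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble modelling of antibody-antigen complexes against SAXS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, assumptions and
numerical choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The modelling problem

An IgG-class antibody has two antigen-binding arms (Fab) connected to a
central hub (Fc) through a short polypeptide hinge whose backbone
torsions make the arms mobile. When its antigen is a D2-symmetric
homotetramer with two accessible binding faces, mixtures can form
higher-order species. Three solution measurements constrain the outcome:
the complex molar mass (SEC-MALS), binding kinetics (SPR), and the
scattering profile I(Q) (SEC-SAXS). The package's pipeline builds
explicit atomistic (here: pseudo-atomistic) candidate models of every
plausible composition, computes their theoretical scattering, and asks
which composition and topology class can explain both the profile and the
mass.

## Stoichiometry enumeration

`stoichiometry_search()` enumerates integer compositions
(i antigens, j antibodies), i, j = 0..n_max, i + j >= 1, predicting
masses i m_ag + j m_ab with propagated uncertainty
sqrt(i^2 s_ag^2 + j^2 s_ab^2). A composition is accepted when the
predicted and measured masses differ by at most `z_limit` combined
standard deviations. `z_limit` defaults to 1: masses are reported with
one-sigma uncertainties, and matching within one combined sigma is the
natural reading of "agreement within reported uncertainties". With the
component masses used throughout (antigen 63.3 +/- 0.8 kDa, antibody
160 +/- 3 kDa, measured complex 447 +/- 12 kDa) the acceptance window
contains exactly one composition, (2, 2), predicting 446.6 kDa.

## Binding kinetics

`simulate_sensorgram()` implements the closed-form 1:1 interaction
(Langmuir) model: association R(t) = Req (1 - e^(-(ka C + kd) t)) with
Req = Rmax ka C / (ka C + kd), dissociation R(t) = R0 e^(-kd t), additive
Gaussian noise. `fit_one_to_one()` refits (ka, kd, Rmax) globally across
all concentrations by Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`) on a log-parameter scale, sharing one Rmax (one
sensor surface); kD = kd/ka. Residuals are unweighted. Mass-transport
limitation and baseline drift are deliberately omitted: the simple model
is the quantity of interest. Default simulated conditions mirror a
standard titration: concentrations spanning 1-1000 nM, 60 s association,
and rates chosen so kD is 40 nM, the nanomolar regime typical of
antibody-antigen binding.

## Toy structures: what the generators emulate

Real inputs to this kind of analysis are a homology-model antibody, a
crystal-structure antigen, and docked Fab-antigen poses. The generators
reproduce the features the pipeline's logic actually depends on:

* `make_toy_antibody()` - three compact domains of `atoms_per_domain`
  carbon-like pseudo-atoms on a jittered lattice inside spheres of
  `domain_radius` (default 25 Angstrom, 150 atoms), joined as one chain
  Fab1-hinge1-Fc-hinge2-Fab2. The hinges are real 5-residue N/CA/C
  backbones with ideal bond lengths (N-CA 1.458, CA-C 1.525, C-N 1.329
  Angstrom) and a 114-degree zigzag, so phi/psi pivots are well defined.
  The two Fab clouds are congruent (one is a rotated copy), which makes
  every Fab-onto-Fab rigid alignment exact - the property the assembly
  steps rely on. Defaults give a radius of gyration near 49 Angstrom and
  an arm-arm angle of 80 degrees, the scale and anatomy of an IgG.
* `make_toy_tetramer()` - four identical pseudo-subunit clouds placed as
  exact images under two orthogonal 2-fold rotations (D2), centre of
  mass exactly at the origin, with the two generating axes recorded as a
  geometric frame that rigid transforms carry along. Defaults (subunit
  radius 18 Angstrom, 110 atoms, centre offset 1.285 radii) give an Rg
  near 27 Angstrom, the scale of a compact tetramer.
* `make_docked_pose()` - a stand-in for a docking run: the antigen is
  spun (seeded) about the approach axis and walked in until the minimum
  Fab-antigen atom distance is near the requested `gap` (default 4
  Angstrom, a typical interface contact distance).
* `make_synthetic_profile()` - Debye profile plus Gaussian noise with
  sigma(Q) = a I(Q) (1 + b Q), defaults a = 0.02, b = 5 Angstrom:
  a 2% relative floor with the monotone relative-error growth toward
  high Q seen in real SEC-SAXS after buffer subtraction.

What the toys do **not** emulate: amino-acid sequence, side chains,
excluded-volume and hydration-layer scattering, physically calibrated
counting statistics, and docking energetics. Tests passing on toys
therefore validate the pipeline's geometry, statistics and logic - not
force-field realism.

## Torsion-angle Monte Carlo

`tamc_sample()` iterates: pick one pivot uniformly from the pivot set
(default: the interior hinge residues, the toy analogue of upper-hinge
heavy-chain residues), draw a step from Uniform(-max_step, +max_step)
degrees, rotate all atoms C-terminal of the pivot bond within the chain,
and accept if and only if no atom pair belonging to different rigid units
is closer than `overlap_cutoff`. Acceptance is pure hard-sphere - no
energy function - because "non-overlapping" is the defining property of
the production ensembles this mirrors. Choices:

* `overlap_cutoff` = 1.8 Angstrom, a heavy-atom contact distance; the
  production protocol's value is not stated, so it is configuration.
* One pivot per move; `max_step` = 30 degrees by default.
* Covalently bonded neighbours across the pivot (residue separation
  <= 2) are excluded from the clash scan, otherwise the backbone itself
  would count as a clash.
* Chain-growth-style restart: after 1000 consecutive rejections the
  state resets to the input structure, preventing permanent trapping in
  a jammed conformation.
* "Downstream" of a phi/psi pivot means all atoms C-terminal of the
  rotated bond in the same chain; inter-chain contacts are never treated
  as connectivity. Dihedrals follow the IUPAC sign convention, and a
  rotation of +delta changes the measured dihedral by +delta.

Tests verify, member by member, that an independent brute-force scan
finds no inter-unit contact below the cutoff, that bond geometry is
preserved to 1e-6 Angstrom, and that sampling is bit-reproducible per
seed. Test and acceptance runs use ensembles of 40-1000 members; the
production scale this emulates (tens of thousands) is out of scope.

## Complex assembly

All assembly is rigid-body: units are never deformed, so internal
geometry is exact by construction, and geometric filters do all the
structure determination (the energy minimization and short relaxation MD
a production pipeline would run afterwards are out of scope; the clash
filter is their stand-in).

* `symmetrize_pose()` replicates a docked Fab by a 180-degree rotation
  about a recorded antigen 2-fold, giving a Fab2-antigen block; rejected
  if the two Fabs come within `clash_min`.
* `attach_antibody()` superposes one antibody arm onto an anchor Fab of
  a complex. The alignment selection excludes the binding face
  (paratope), mirroring the practice of aligning on residues away from
  the interface so the docked pose is maintained. The clash scan covers
  newly apposed pairs only: the anchor Fab itself is excluded because
  the arm that replaces it is covalently attached to the rest of the
  antibody.
* `build_monodentate_ensemble()` chains antigen-Ab1-antigen(shared)-Ab2:
  two antibodies on a shared Fab2-antigen block plus a pendant antigen
  on a free arm. Linkage graph: a simple path.
* `build_bidentate_ensemble()` first collects antibody conformers with
  arm-arm (Fab-Fc-Fab, domain-centroid) angles inside
  `angle_window` = [70, 90] degrees; places a block on each arm;
  requires the ring-closure distance between the two free-site anchor
  atoms (the analogue of the heavy-chain residue-211 C-alpha, here the
  Fc-proximal hinge C-alpha) to be below `ring_calpha_max` = 40
  Angstrom; and then places a second angle-filtered antibody by jointly
  superposing both of its arms onto the two free sites. Linkage graph:
  a single 4-cycle.

Filter semantics: the clash rule rejects strictly below
`clash_min` = 8.0 Angstrom (a pair at exactly 8.0 passes); it is
evaluated over all atoms of the two molecules being apposed, with docked
interfaces exempt. The arm-angle reference points are domain centroids.
The ring-closure distance is evaluated before the closing antibody is
committed, following the build order free-sites-first.

Two genuinely open choices and their resolutions:

* **Ring closure tolerance.** A rigid second antibody cannot land on
  both free sites exactly; a production pipeline absorbs the residual by
  energy minimization. Here the joint two-arm superposition RMSD must be
  at most `closure_tol` = 12 Angstrom (about a 10-degree arm-angle
  mismatch at the toy's 70-Angstrom arm length) - small enough that the
  ring is genuinely closed at the resolution SAXS sees at Q <= 0.19
  inverse Angstrom, large enough that closure is reachable without a
  force field.
* **Closing-antibody search order.** Candidates are tried in order of
  how well their arm-centroid separation matches the free-site
  separation - a necessary condition for a small closure RMSD - rather
  than at random; this changes speed, not the accepted set.

Every emitted member is re-checked in the tests by brute-force distance
scans, direct angle measurement, and linkage-graph classification.

## Theoretical scattering and 1-D analyses

* `debye_profile()` is the exact orientational average for point
  scatterers, I(Q) = sum_ij f_i f_j sinc(Q r_ij), with sinc(0) = 1 and
  I(0) = (sum f(0))^2, evaluated in compiled code. Form factors: "point"
  mode (constant, for pseudo-atoms) or "element" mode (f = electron
  count, the small-angle limit of the atomic form factor, flat to well
  under 1% over the working range Q <= 0.3 inverse Angstrom).
* `golden_vector_profile()` averages |sum_j f_j e^(i q.r_j)|^2 over M
  quasi-uniform directions from a spherical Fibonacci (golden-angle)
  lattice; it agrees with the Debye sum to within quadrature error that
  falls with M (about 1% or better at M ~ 300 for toy structures).
* Profiles are **in vacuo**: no excluded-volume or hydration-layer
  term. This is the main fidelity gap versus real solution data; it is
  irrelevant to the toy-scale validation because synthetic experiments
  are generated by the same physics.
* `guinier_fit()` fits ln I against Q^2 on the largest low-Q window
  satisfying Qmax Rg <= 1.3 (the conventional Guinier validity bound),
  found self-consistently: fit, shrink the window to honour the bound
  with the fitted Rg, repeat to a fixed point (cycle-safe). The fit is
  sigma-weighted (delta-method weights (I/sigma)^2 in log space) when
  uncertainties are present, unweighted otherwise. A non-negative slope
  is an error: there is no Guinier regime.
* `pair_distribution()` histograms all pairwise distances weighted by
  f_i(0) f_j(0), normalized to unit area; Dmax is the exact maximum
  distance, and Rg^2 = integral(r^2 p dr)/2 reproduces the coordinate
  Rg to within binning error.
* `reduced_chi2()` interpolates both profiles linearly onto the fit
  grid - 19 equally spaced points on (0, 0.19] inverse Angstrom by
  default, starting one spacing above zero because Q = 0 is
  unmeasurable - fits the scale analytically when requested, and divides
  by N - p with p = 1 when the scale is fitted (0 otherwise). The grid
  is assumed linear (detector-matched binning is not modelled). When the
  experimental profile carries no uncertainties, the caller must state a
  constant-sigma policy explicitly; the function refuses to invent one.

## Ranking, the mass rule, and the verdict

`run_analysis()` evaluates seven candidate classes by default: antigen
alone, antibody alone, 1:1, 2:1, 1:2, and the two 2:2 topologies
(monodentate chain, bidentate ring). Per class it builds an ensemble,
scores every member by reduced chi-square against the experimental
profile, and marks the class chi-square-consistent when its best member
is at or below `chi2_threshold` (default 2 on toy data - roughly "within
twice the noise floor"; the production analogue of a rejected class is a
chi-square larger by two orders of magnitude). Independently, the class
composition must pass the molar-mass window. The verdict lists classes
passing both. Ranking ties are broken by smaller Rg (documented,
otherwise arbitrary). All stage seeds derive deterministically from the
master seed, so the verdict is a pure function of the configuration.

The end-to-end validation is a **recovery experiment**: the synthetic
"experimental" profile is generated from a bidentate 2:2 model drawn
from the pipeline's own model space (same master seed) with an
independent noise seed, and the analysis must (a) rank every
artificially extended decoy below every compact model and (b) pass only
2:2 classes through the joint verdict. Drawing the truth from the model
space is the standard design for a recovery study - it tests the
statistics and the decision logic, not extrapolation beyond the
generator; the toy ensembles are too discrete for an out-of-space truth
to be matched within the noise floor, and that discreteness is a
property of the desk scale, not of the method.

## Problem sizes and determinism

Default test and acceptance scales: 150-atom domains (480-atom antibody,
440-atom antigen, 1840-atom 2:2 complexes), ensembles of 10-40 members
per candidate class (1000 for the torsion-MC property suite), a 10^4
point stratified ball for the sphere-oracle checks, and 100 refit seeds
for the kinetics study. These sizes keep every check comfortably
repeatable on a single CPU while leaving each statistical margin wide.
All stochastic stages take explicit integer seeds; every generator
restores the caller's RNG state.

## Known limitations

* In-vacuo scattering; no solvent contrast terms, no smearing, no
  absolute calibration.
* Hard-sphere acceptance and clash filters replace all energetics;
  emitted complexes are geometrically, not energetically, relaxed.
* Docking is emulated by seeded rigid placement at a contact gap, not
  predicted.
* The toy hinge is the only flexible element; Fab internal flexibility
  and Fc glycans are absent.
* PDB output uses fixed columns with serials wrapping at 99,999 -
  adequate for toy scale; hybrid-36 encoding is not implemented.
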