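---
title: "Phantomless QCT densitometry and voxel-based FEA: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantomless QCT densitometry and voxel-based FEA: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative computed tomography (QCT) turns CT attenuation (Hounsfield
units, HU) into volumetric bone mineral density (vBMD, mg/cc) by scanning
the patient together with a calibration phantom: rods of known
K~2~HPO~4~-equivalent density lie in the same image, and the linear fit

$$\mathrm{BMD} = \alpha \cdot \mathrm{HU} + \beta$$

through the rod measurements gives the patient-specific calibration
$(\alpha, \beta)$. Routine clinical CT is acquired *without* a phantom, so a
voxelwise density map -- and hence any finite-element (FE) strength
assessment built on it -- is not directly available. The phantomless route
replaces the in-scan phantom with a regression model that maps the
trabecular HU value and patient physical factors to BMD. The factors matter
because body habitus changes attenuation: the same bone reads different HU
in a larger body. The site-specific phantomless models this package
implements and refits are

$$\mathrm{BMD} = 0.848\,\mathrm{HU} + 0.148\,C - 7.4 \quad \text{(lumbar spine)},$$
$$\mathrm{BMD} = 0.784\,\mathrm{HU} + 16.6 \quad \text{(hip)},$$

with circumference $C$ in cm and BMD in mg/cc. At the abdomen the
soft-tissue mantle is thick and variable, so circumference carries
information; at the hip it does not survive selection.

Downstream, each bone voxel becomes one 8-node hexahedral finite element
whose Young's modulus comes from a density--modulus law:

* spine: $E = 5124\,\rho^{1.7}$ MPa,
* femur: $E = 6850\,\rho^{1.49}$ MPa for $\rho \le 1.64$ g/cm^3^,
  $E = 4293\,\rho^{2.39}$ MPa above,
* linear bone-volume-fraction (BVF) rule: $E = E_0 \cdot \mathrm{BVF}$ with
  BVF the voxel intensity rescaled linearly to $[0, 1]$ between pure-marrow
  and pure-bone intensities ($E_0$ = 10.2 GPa spine, 8.4 GPa femur).

Poisson's ratio is 0.3 everywhere. Load cases: 2000 N uniform vertical
compression on the superior endplate (spine, inferior surface constrained)
and a 1000 N resultant distributed over the superior head surface toward
the head centre with the distal layer fixed (hip). Under load control,
total strain energy is inversely related to apparent stiffness, so
comparing strain energies between calibration routes quantifies what a
density error does to a strength assessment.

## Units and conventions

* Arrays are `[y, x, z]`, 1-based (R convention); axial slices are the
  third index. ROI specifications use the same convention.
* Volumes: HU; densities mg/cc; the laws above take g/cm^3^, so
  `map_materials()` divides by 1000. This unit bridge is a modelling
  decision: the source laws were derived for apparent/ash density, and the
  femoral branch point (1.64 g/cm^3^) sits above the usual QCT BMD range,
  so in practice the low-density femoral branch does nearly all the work.
  The laws are applied as printed.
* FEA works in mm / N / MPa, so energies are mJ and strain energy density
  (SED) is reported in µJ/mm^3^ (1 mJ/mm^3^ = 10^3^ µJ/mm^3^).

## The synthetic world

No patient data ship with the package; every stage is exercised against a
generator whose ground truth is known exactly (`generate_case()`,
`generate_cohort()`):

* an axial slice holds a soft-tissue ellipse (~0--60 HU on air at
  -1000 HU), a bone disc with a 3 mm cortical shell (900 mg/cc) around a
  trabecular core, and five phantom rods (0/50/100/200/400 mg/cc --
  configurable; commercial rod values are proprietary) below the body;
  the slice is extruded along z (3 mm slices), matching a single-axial-level
  measurement protocol while giving the FEA a volume;
* body circumference is sampled uniformly on 65.941--97.356 cm, the
  published cohort range, and the ellipse is rasterized to hit the sampled
  perimeter via two fixed-point refinements against the sub-pixel measured
  perimeter;
* HU is generated from truth BMD through an inverse calibration line whose
  slope equals the published site coefficient and whose intercept drifts
  with circumference at the published circumference coefficient
  (spine: $\beta = -7.4 + 0.148\,C$; hip: fixed 16.6). Circumference
  therefore carries exactly the information the phantomless spine model
  attributes to it, and a noiseless cohort refit recovers the published
  coefficients to numerical precision;
* additive Gaussian HU noise, default SD 5 HU -- small enough that
  coefficient recovery stays within a few percent at cohort size 39;
* for the spine only, the mean trabecular BMD also co-varies with
  circumference (3.5 mg/cc per cm around the range midpoint, subject SD
  40 mg/cc). This is the body-size/density correlation seen in vivo, and it
  is what makes circumference significant already in the *univariate*
  screen at n = 39 (power ~0.99 by design calculation); the intercept
  drift alone is a conditional effect that only a joint fit can see. The
  hip generator sets both slopes to zero, reproducing the hip's
  HU-only pattern.

What the generator does **not** emulate: bone microarchitecture,
beam-hardening/scatter physics, scanner kernels, anatomical shape. A green
test therefore establishes correctness of the estimation and mechanics
machinery under the stated statistical world, not clinical accuracy.

`generate_cohort(..., table_only = TRUE)` skips rasterization and builds
the cohort table from the closed-form truth (analytic ROI mean of the
radial BMD profile; ROI-averaged HU noise). It samples the same per-subject
factors and exists so repeat-heavy statistical checks (50-cohort
significance patterns) run in seconds.

`published_recovery_cohort()` is a separate, deliberately minimal
benchmark: HU ~ U(80, 300), circumference ~ U(66, 97) cm, BMD from the
published equations plus 2 mg/cc Gaussian noise, n = 39, seed 7, with a
frozen draw order. Its purpose is coefficient recovery, and its realization
is pinned. A caveat worth stating: with these ranges the standard error of
the circumference coefficient is ~0.035 mg/cc/cm -- about 24% of the
coefficient itself -- so any single 39-subject realization estimates that
coefficient only coarsely; the recovery of the HU coefficient (se ~0.6% of
its value) is the sharp check.

## Stepwise selection: a design choice

The selection procedure is *backward stepwise on the joint fit*: all
candidate factors enter a multiple OLS of reference BMD on the factors, the
least significant factor with $p \ge 0.05$ is dropped (the HU term is
protected), and the model is refit until all survivors are significant.
P-values are two-sided t-tests with $n - p - 1$ degrees of freedom; exact
collinearity (condition number > 10^8^) is an error.

A univariate pre-gate (screen each factor marginally, admit only
$p < 0.05$) is available via `screen = TRUE` and as the standalone
diagnostic `univariate_screen()`, but it is not the default inside
`fit_conversion()`. Reason: a factor can be conditionally certain yet
marginally invisible. In the recovery benchmark the HU term explains ~98%
of BMD variance, so the marginal BMD--circumference correlation is ~0.02
and a univariate gate would discard circumference even though its joint-fit
t-statistic is ~4. The univariate screen remains the right tool for the
*pattern* question (which factors correlate with BMD at all, as a cohort
property); the joint backward elimination is the right tool for building
the conversion equation.

## Numerical choices

* **Calibration and regression**: ordinary least squares throughout
  (`stats::lm`), density as response, matching the direction in which the
  conversion is applied. A fitted $\alpha \le 0$ warns (physically
  implausible) rather than errors.
* **Perimeter**: marching squares on a 3×3 box-smoothed coverage field with
  linearly interpolated 0.5-crossings, summed per cell. Pixel-edge counting
  overestimates a circle's perimeter by ~27%; binary-midpoint marching
  squares by ~6%; the smoothed sub-pixel contour is within ~1% for discs at
  realistic radii. The two ambiguous saddle cases map onto each other under
  90° rotation, keeping the measure rotation-invariant.
* **Body segmentation**: threshold at -200 HU (soft tissue vs air; the
  clinical software's internal threshold is unpublished, only the
  120--2000 HU bone window is), largest 4-connected component, holes
  filled. Bone area is always measured inside the body contour so phantom
  rods never count as bone.
* **FE element**: trilinear hexahedron, full 2×2×2 Gauss integration.
  Commercial codes may use incompatible modes or reduced integration, so
  absolute stiffness will differ from any specific solver even on identical
  geometry; all package-level claims are therefore about *relative*
  energies or closed-form-verifiable cases.
* **Solver**: direct sparse Cholesky (Matrix) with the relative residual
  checked against 10^-8^; a Jacobi-preconditioned conjugate gradient is
  available (`method = "cg"`). Direct is the default because the
  0.01 MPa modulus floor (kept so marrow-adjacent elements never make the
  system singular) can push the spectral contrast to ~5×10^5^, where plain
  PCG convergence is unreliable.
* **Boundary conditions**: the spine default fixes the whole inferior node
  layer ("fixed" convention) and splits the 2000 N equally over superior
  nodes; end effects are accepted. The uniaxial verification instead uses
  vertical rollers plus minimal lateral constraints and area-consistent
  ("tributary") nodal loads, under which the FE solution is exactly the
  homogeneous closed-form state $U = F^2 L / (2EA)$ -- the bar test passes
  at solver precision, not by tolerance charity. The hip loading
  concretizes a sideways-fall-style case as equal-magnitude nodal forces on
  the superior head patch pointed at the head centre, rescaled so the
  resultant magnitude equals the configured force; this is a documented
  modelling choice, not a replication of any particular published fall
  configuration.
* **Meshing**: floating voxel fragments disconnected from the main
  component are removed with a warning before solving.
* **Femoral branch point**: $\rho = 1.64$ g/cm^3^ takes the low branch, as
  printed. The printed coefficients make the law step *down* by ~2.2%
  across the branch, so global monotonicity is intentionally not asserted;
  the jump is verified to stay under 3% instead of being smoothed away.

## The mechanism the FEA comparison reproduces

Against the power law with the same maximum modulus, the linear BVF rule
assigns higher moduli at every intermediate density (linearity vs convexity
of $\rho^{1.7}$ on $[0, \rho_{\max}]$). A bone modelled with the BVF rule
is therefore apparently stiffer, and under load control stores *less*
strain energy -- an optimistic bias in a strength assessment. The
acceptance suite asserts this ordering numerically on a seeded synthetic
vertebra: SED(BVF) < SED(power law) < SED(uniformly softened power law).

## Known limitations

* The generator's geometry is an extruded convex phantom; no claim is made
  about anatomically realistic stress fields.
* RMSE between BMD maps defaults to the bone mask; a whole-array mode
  exists for parity with full-slice comparisons but is background-dominated.
* The phantomless coefficients are protocol-specific (tube voltage,
  reconstruction kernel, scanner); refitting on a new protocol's cohort is
  the supported route, not coefficient transfer.
* Single-slice rod ROIs are assumed for calibration (configurable); the
  number of slices entering clinical rod means is generally unreported.
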