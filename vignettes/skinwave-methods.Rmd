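---
title: "Predicting in vivo skin growth from simulated elastic-wave measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting in vivo skin growth from simulated elastic-wave measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tissue expanders stretch skin past its homeostatic tension to stimulate the
growth of new tissue for reconstructive surgery. Clinically, there is no
non-invasive way to tell how much of the observed deformation is reversible
elastic stretch and how much is permanent growth, nor to measure the
patient's skin stiffness, natural pre-stretch or growth rate. `skinwave`
implements, end to end, a simulation-based inverse approach: a
volumetric-growth finite-element model of a skin block under a rectangular
tissue expander generates a virtual population of subjects, each subject is
"measured" three times by a simulated surface-wave probe, and a neural
network is trained to recover the subject's material properties and its
future (day-7) growth field from the three waveforms alone.

## Constitutive model

Skin is a compressible neo-Hookean solid with multiplicative elastic/growth
kinematics. The deformation gradient splits as `F = Fe Fg`. Growth is
transversely isotropic: area grows in the plane of the skin, thickness does
not, so

    Fg = sqrt(theta_g) (I - N o N) + N o N,

where `N` is the reference surface normal and `theta_g >= 1` is the areal
growth. The stored energy acts on the elastic part only,

    Psi = mu/2 (I1e - 3) - mu ln Je + lam/2 ln^2 Je,

with `I1e = tr(Fe^T Fe)`, `Je = det Fe`, and Lame parameters `mu` and
`lam = 40 mu` (nearly incompressible, Poisson ratio about 0.488). The
`- mu ln Je` term makes the undeformed reference stress-free; it is exactly
the energy whose push-forward is the Cauchy stress used throughout,

    sigma = (1/Je) [ mu (Fe Fe^T - I) + lam ln(Je) I ],

and the package verifies this stress against finite differences of the
energy rather than trusting either closed form (`test-material.R`).

Growth follows a stretch-driven first-order law: with
`theta_e = ||cof(Fe) N||` the elastic areal stretch and `theta_nat` the
subject's natural (homeostatic) pre-stretch,

    d theta_g / dt = k max(0, theta_e - theta_nat).

The clamp at zero makes growth irreversible: skin that ends up slack never
"ungrows". At a material point held at total areal stretch `theta_total`
the law integrates to a relaxation of `theta_e` towards `theta_nat`, with
equilibrium `theta_g = theta_total / theta_nat`; `point_driver()` computes
this trajectory and is the oracle for the finite-element growth stepper.
Integration uses Heun's method with substeps capped at a growth increment
of 0.01, which keeps the trajectory within 1e-4 of a stiff ODE reference.

## Finite-element engine

The quarter skin block (50 x 37.5 x 3 mm; the full block is four times the
area, with the two expander symmetry planes as mirror boundaries) is meshed
with trilinear hexahedra. Nearly incompressible response would lock with
full integration, so the volumetric `lam` term is integrated at the element
centroid only (selective reduced integration) while the `mu` term uses the
full 2x2x2 rule. Static phases use Newton's method with an analytic
consistent tangent (cross-checked against a finite-difference tangent in
the tests), a backtracking line search on the residual norm, adaptive load
stepping with bisection, and a Cholesky factorisation with symbolic reuse
(LU fallback for indefinite tangents).

The protocol phases are:

1. **Pre-stretch.** An isotropic in-plane stretch of `sqrt(theta_nat)` per
   direction (areal stretch `theta_nat`) through displacement boundary
   conditions; the solution is homogeneous and serves as a patch test.
2. **Expander inflation.** The expander is a cosine dome
   `w = h cos(pi x / 2a) cos(pi y / 2b)` over a quarter footprint of
   40 x 30 mm, with apex height `h` calibrated so the volume under the
   quarter dome is exactly a quarter of the nominal 60 cc. (The footprint
   itself is a free geometric parameter: with a much smaller footprint the
   60 cc calibration would demand an apex height exceeding the block
   dimensions and stretches far past skin failure.) The skin's underside
   inside the footprint is displaced onto this surface as if bonded to a
   uniformly inflating membrane whose stretch is largest at the pole
   (`pole_bias = 0.3`), and the rim drags about 1 mm of surrounding skin
   inward ("recruitment" of skin over the expander). These two kinematic
   choices reproduce the two qualitative features reported for expander
   inflation: elastic deformation (hence growth) is largest at the apex,
   and the skin around the expander is visibly tensioned, which is what
   speeds up the surface wave at day 0. A purely vertical dome prescription
   with free sliding -- the obvious alternative -- concentrates stretch at
   the dome flank instead (the flank spans the steepest arc), which
   contradicts the apex-dominated growth fields reported for tissue
   expansion; this is why the bonded-membrane kinematics were adopted.
   Because a flat sheet cannot wrap a doubly-curved dome without in-plane
   compression, a band of the footprint near the rim stays at or below the
   natural pre-stretch and never grows; grid cells whose growth varies by
   less than 0.1 percent of area across a test fold are therefore excluded
   from the growth-field accuracy average instead of being scored against
   numerical-noise variance.
3. **Growth hold.** The inflated configuration is held; every growth step
   advances `theta_g` per quadrature point with the local growth law at
   frozen total stretch, then re-solves static equilibrium (a staggered
   scheme). For a homogeneous state this is exactly the material-point
   trajectory, which the tests exploit.
4. **Wave excitation.** From each measurement state, an explicit
   central-difference analysis applies 0.5 MPa for 2e-5 s on one surface
   element face on the expanded skin (at x = 20 mm on the symmetry axis --
   clinically, the expanded area is the monitored site, and it is where the
   relaxing tension encodes the growth rate) and records the surface-normal
   displacement of the node 5 mm further out for 12.5 ms. The stable time
   step is computed from the largest eigenvalue of `M^-1 K` at the
   pre-impact state (power iteration) with a safety factor of 0.6, and one
   common step -- the smallest across the subject's three states -- is used
   for all three measurements so their arrival times share one time
   discretisation. Tangent stiffness-proportional damping
   (`beta = 0.3 dt`, evaluated as the internal force at `u + beta v`)
   suppresses node-scale ringing while leaving the physical band (damping
   ratio proportional to frequency) essentially untouched; production
   explicit codes apply comparable high-frequency dissipation by default,
   and without it the recorded waveforms are dominated by grid-frequency
   ringing, which buries the subtle between-measurement shifts that the
   inverse problem relies on.

### Numerical choices and degenerate inputs

* Static convergence demands a free-dof residual below 1e-8 of the reaction
  norm (absolute floor 1e-12 for unloaded states).
* Growth stepping caps the growth increment per equilibrium re-solve at
  0.2 and halves the step on a rejected solve; the local ODE is always
  substepped at increments of at most 0.01.
* `theta_total = theta_nat` holds are exact fixed points (zero growth);
  `k = 0` subjects never grow, and their day-0 and day-3.5 measurements
  coincide to solver tolerance.
* The explicit phase subtracts the static internal force, so a
  zero-pressure excitation returns an identically zero waveform.
* Energy in the undamped explicit phase stays bounded but oscillates by
  tens of percent about the injected work: the 2e-5 s impulse excites
  node-scale modes whose discrete (shadow) energy differs from the
  continuous energy by O((dt omega)^2), an O(1) quantity at any practical
  step near the stability limit. The tests therefore assert boundedness
  (no secular growth, and the kinetic-energy instability guard stays
  quiet) rather than sub-permille energy closure.

## Virtual cohort and measurement protocol

Subjects are drawn by Latin hypercube (one sample per equal-probability
stratum per dimension) over `mu` in [0.01667, 0.1] MPa, `k` in [0.2, 1.92]
per day, `theta_nat` in [1.05, 1.2] and `rho` in 1116 kg/m^3 plus or minus
5 percent, with `lam = 40 mu` throughout. Each subject yields three
waveforms -- baseline (pre-stretched only), day 0 (inflated, held 1e-5
days) and day 3.5 -- resampled by a cubic interpolating spline onto 1001
points spanning [0, 0.0125] s, and the day-7 growth field coarsened to a
5 x 5 grid: the quarter top surface is split into equal 10 x 7.5 mm
reference regions and each region is represented by the growth of the
element containing its centroid. The extra grown area is
`sum((theta_g - 1) * A_ref)` over top-surface elements.

## Inverse surrogate

The surrogate is a fully connected network with hidden layers (32, 64, 32),
ReLU activations and a linear output, mapping the 3003 concatenated
waveform samples to 28 targets (25 grid growth values, then `mu`, `k`,
`theta_nat`; density is not a target). Inputs and targets are standardized
per column with statistics fitted on the training rows only. Training uses
Adam (learning rate 1e-3, minibatch 64, decoupled weight decay available
but off by default, mean squared error on standardized targets) with early
stopping on an inner 10 percent validation split (patience 45, cap 200
epochs), deterministic given the seed. Architecture evaluation follows the
repeated cross-validation protocol: 10 folds, 5 repeats with
repeat-specific shuffles, R-squared per target computed on the held-out
fold only, and the growth-field summary is the mean R-squared over the
grid targets with measurable growth.

## Problem sizes

At full scale this kind of analysis runs 1,000 subjects on a mesh of tens
of thousands of elements in a commercial solver, with cross-validation
training on 900 subjects per fold. This package's defaults are a
scaled-down configuration chosen for a single-CPU workflow: a 20 x 10 x 1 element quarter-block mesh (2.5 mm
in-plane resolution along the impact-probe line, one element through the
thickness; the physics checks -- waveform ordering and apex-dominated
growth -- were verified across the parameter-range corners at this
resolution) and a 600-subject cohort; one subject's full protocol takes
about 0.7 seconds, the packaged acceptance analysis (600 subjects plus the
full 10-fold x 5-repeat cross-validation of the (32, 64, 32) network)
about a quarter of an hour. Surrogate accuracy is strongly sample-limited
at this scale -- the inverse problem's hardest target, the growth rate, is
encoded in small relative shifts between a subject's own waveforms, which
takes many training subjects to learn -- so the cross-validated medians
reported by the acceptance analysis should be read as the accuracy of the
scaled-down configuration, not as the method's ceiling. The training cap
(200 epochs) is likewise a compute budget, not a convergence point.

## What the generator does and does not emulate

The simulated waveforms are smooth, noiseless, and come from one fixed
mesh, one expander geometry, and one constitutive family; the inverse
problem is therefore easier than it would be on clinical data (no device
noise, no anatomy variation, no model error). Passing the replication
criteria shows that the pipeline recovers its own generating parameters at
the reported accuracy, not that a clinically deployed version would. Known
resolution limits at the working mesh: first-peak arrival times are
converged only to about ten percent under in-plane refinement, and the
waveform's fine structure is mesh-filtered. Within one cohort this is immaterial for the
inverse task -- every subject is simulated on the same mesh -- but absolute
arrival times should not be compared against other discretisations.

## Limitations

* Growth is isotropic in-plane with a single rate; anisotropic extensions
  (separate transverse/longitudinal rates) are out of scope.
* The expander acts through displacement boundary conditions (bonded
  membrane map); there is no contact mechanics and no fluid model of the
  expander.
* No viscoelasticity; the only time scale is the growth rate.
* Uncertainty quantification of the surrogate's predictions is out of
  scope; the network returns point estimates.
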