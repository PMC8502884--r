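---
title: "Tracking white matter through vasogenic edema: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking white matter through vasogenic edema: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Peritumoral vasogenic edema floods the extracellular space around a brain
tumor with free water. In diffusion MRI this raises the isotropic signal
fraction of every affected voxel, which collapses the fractional anisotropy
(FA) of the single diffusion tensor even when the axons running through the
edema are intact. Deterministic tractography terminated at the standard FA
floor of 0.20 therefore truncates motor tracts at the edema boundary, and a
presurgical map can miss exactly the fibers the surgeon most needs to avoid.

The Watson-NODDI model separates the voxel signal into three compartments —
restricted (intracellular), hindered (extracellular) and free isotropic water
— and summarizes the angular spread of the neurite compartment with the
orientation dispersion index (ODI). Because the ODI and the fitted Watson
axis are estimated after the free-water signal has been accounted for, they
remain informative inside the edema. This package swaps the tracker's
termination metric from an FA floor to an ODI ceiling, and its direction
field from the tensor's principal eigenvector to the fitted Watson axis, and
quantifies what the two reconstructions see inside the edema.

## The models

**Diffusion tensor.** Fitted by signal-squared-weighted log-linear least
squares on the sub-scheme with b < 1,500 s/mm² (so only the b = 0 and
b = 1,000 shells of the two-shell protocol enter; the b = 2,000 shell is
outside the quasi-Gaussian regime the tensor assumes). The weighted
log-linear fit is deterministic and exact on noise-free single-tensor data,
which the tests exploit. Voxels where a diffusion-weighted frame exceeds the
b = 0 signal are fitted on log-clamped values (floor 1e-6 of S0) and flagged;
negative eigenvalues are clamped to zero for FA/MD with the voxel flagged.

**Watson-NODDI.** The normalized signal is

    A(b, g) = (1 - viso) * [ vic * A_ic + (1 - vic) * A_ec ] + viso * exp(-b * d_iso)

with fixed diffusivities d_par = 1.7e-3 mm²/s and d_iso = 3.0e-3 mm²/s (the
standard in-vivo values of the model, which treats them as constants rather
than free parameters). `A_ic` is the stick signal `exp(-b d_par (g·n)²)`
averaged over Watson-distributed orientations `n`; `A_ec` is a Gaussian
compartment whose tensor is the Watson average of an axially symmetric
tensor with tortuosity-scaled perpendicular diffusivity
`d_par (1 - vic)` (the mean-tensor approximation that is standard practice
for Watson-NODDI). The absolute fractions reported everywhere are
`VF_iso = viso`, `VF_ic = (1 - viso) vic`, `VF_ec = (1 - viso)(1 - vic)`,
which sum to one identically — the test suite asserts the identity to 1e-10.

Because the Watson density is axially symmetric, the orientation average
reduces by the Funk–Hecke theorem to a sum over even Legendre orders,

    A_ic = sum_l c_l(b d_par) * p_l(kappa) * P_l(g·mu),

where both coefficient sequences are one-dimensional integrals in
t = cos(angle to mu): `c_l` against the stick kernel and `p_l` against the
Watson weight `exp(kappa t²)`. Both are evaluated by 200-point
Gauss–Legendre quadrature with even orders up to 24. Two numerical choices
matter here. The truncation order 24 keeps the expansion error below 1e-9 at
the largest argument the protocol produces (x = b·d_par = 3.4). The node
count 200 (rather than a more customary 64) is forced by the upper end of
the concentration range: at kappa = 64 the weight `exp(kappa t²)`
concentrates within about 0.008 of |t| = 1, and 64 nodes cannot resolve it
to the 1e-6 relative agreement with a dense spherical-quadrature oracle that
the tests demand. ODI = (2/pi)·atan(1/kappa) maps concentration to a 0–1
dispersion scale.

**The fitter.** Per voxel the signal is normalized by the mean b = 0 frame.
A coarse grid search over viso, vic ∈ {0, 0.1, …, 1} and
kappa ∈ {0.25, 1, 4, 16}, with the orientation held at the tensor's
principal eigenvector, seeds a Nelder–Mead refinement of all five free
parameters on transformed coordinates: logit fractions, log kappa clamped to
[0.01, 64], spherical angles for the orientation. Nelder–Mead was chosen as
the bounded-by-transformation, derivative-free option: the objective is
cheap (the forward model runs compiled), the parameter count is five, and
no gradient code needs to be trusted. If the refinement ends above the grid
optimum the voxel keeps the grid solution and is flagged unconverged.
Voxels are fitted independently; results do not depend on evaluation order.

## The tracker

Fixed-step (0.5 mm) bidirectional Euler integration with nearest-neighbour
direction lookup and trilinear interpolation of the stopping metric — the
lookup pair balances fidelity against determinism, since the reference
deterministic tracker's internals are not published. At each step the local
direction is sign-aligned with the incoming one (an exactly perpendicular
local direction keeps its stored sign); propagation terminates when the
metric rule fires, the turning angle reaches 60°, the voxel is invalid, or
the streamline leaves the grid. Streamlines shorter than 30 mm or longer
than 300 mm are discarded. Seeds are drawn uniformly at random inside the
seed-mask voxels (the inferior inclusion slab in the pipeline — the seeding
region of the reference tracker is likewise unpublished), and seeding
repeats until 3,000 streamlines are accepted or 100× that many seeds have
been spent, in which case the partial result carries a starvation flag.

Two rule directions are supported. The FA rule is a floor: terminate at
FA ≤ θ. The ODI rule is a ceiling: continue while ODI < θ, terminate at
ODI ≥ θ. The ceiling reading is the physically meaningful one — coherent
white matter has low ODI, gray matter and CSF high ODI — and it is the
reading under which sweeping the threshold to 1 admits everything, matching
the behaviour of the published Dice-versus-threshold curve. In ODI mode the
tracker additionally requires a successfully fitted voxel with VF_iso <
0.95: where the voxel is nearly pure free water the Watson axis is
unidentifiable and following it would be noise-chasing. This guard is an
addition of this implementation, stated here because the source method does
not mention one.

The streamline quota counts finally reconstructed streamlines: when an
ROI set is supplied, acceptance (and hence the quota) is applied after the
inclusion/exclusion filter. ROI filtering keeps streamlines intersecting
every inclusion mask and no exclusion mask, intersection meaning any point
falls in a mask voxel. Whether the published 60° angle criterion was reused
for the dispersion-terminated runs is unstated there; this implementation
reuses it — same tracker, different metric.

## The threshold calibration

`calibrate_odi_threshold()` sweeps the ODI ceiling over 0.20–1.00 in steps
of 0.05 (the step must resolve the published optimum of 0.45; it is
configurable), tracks each subject at each candidate, voxelizes, and scores
Dice overlap `2|A∩B| / (|A|+|B|)` against that subject's FA-floor reference
mask. Overlap is computed on voxelized tract masks, not on streamline point
sets: the Dice denominator divides by tract "volumes", and voxel counting is
the only reading that makes that denominator well defined. The optimum
maximizes the mean Dice across subjects, ties resolving to the smallest
threshold. The comparison runs on the native grid of each subject. The
published healthy-cohort optimum (0.45, mean Dice 0.81) is not reproducible
here because no cohort data are deposited; the sweep itself is validated on
constructed cases and phantom cohorts instead.

## Quantification

Within the edema mask, voxels are classified by tracker agreement: DN (both
trackers), D-only, N-only. The three masks are pairwise disjoint and
partition `(DTI ∪ NODDI) ∩ edema` — asserted property-style on random
masks. PIV divides a condition volume by the whole-tract volume, taken as
the volume of the **union** of the two tract masks: the alternative reading
(arithmetic sum of the two volumes) double-counts DN voxels and can push the
PIV sum past one, so the union is used. Lesion-to-tract distance (LTD) is
the minimum Euclidean distance, between voxel centres, from the lesion
boundary (lesion voxels with a non-lesion 6-neighbour; 6-connectivity is the
tightest standard choice) to any tract voxel, computed as an exact pairwise
minimum and verified against an all-pairs scan. A tract touching the lesion
gives LTD = 0, and the distance-weighted indices volume/LTD and PIV/LTD are
then flagged undefined rather than infinite — the source tables contain no
such case (their minimum is 2.3 mm), so the convention is this package's.

## The statistics

AUC is the Mann–Whitney probability with ties counting one half, which
equals the trapezoidal integral of the empirical ROC curve; candidate
thresholds are midpoints between consecutive distinct values plus ±∞
(published cutoffs are accepted as *inputs* to `sens_spec_at()` rather than
required outputs of the Youden rule, whose cutpoint conventions differ
between packages). Sensitivity is the fraction of the designated
larger-value class strictly above the cutoff; class orientation is always an
explicit argument, never inferred. Youden's J maximizes sensitivity +
specificity − 1, ties resolving to higher specificity then smaller
threshold. The paired Wilcoxon signed-rank statistic is the smaller rank
sum, with an exact two-sided p by full enumeration of the 2^n sign patterns
(tied ranks included) for n ≤ 12 and a tie- and continuity-corrected normal
approximation beyond. The fraction triple maps to the barycentric triangle
with vertices VF_ic → (0,0), VF_ec → (1,0), VF_iso → (0.5, √3/2).

The packaged 24-patient table stores the decline labels exactly as printed
in its source (seven "yes" rows, although the accompanying text counts six),
and reads case 19's edema volume as 17,875 mm³ — its printed thousands
separator is misplaced, and the published edema-volume ROC row only
reproduces under this reading. Published figures that do not reproduce from
the table under any threshold orientation (the LTD sensitivity of 0.647 and
LTD AUC of 0.828; recomputation gives 0.588 and 0.819) are not asserted
anywhere.

## The phantom

`build_phantom()` lays out a corticospinal-tract-like tube (radius 3 voxels,
optionally gently curved) running inferior→superior through a 40³ grid of
2.5 mm voxels, an edema block intersecting its middle, a lesion block
abutting the edema laterally, a CSF block, dispersed gray-like background
tissue inside a brain region, axial inclusion slabs at both tube ends
(sensorimotor- and brainstem-like) and lateral exclusion slabs. Tissue
parameters: bundle kappa = 16 (ODI ≈ 0.04), vic = 0.6, viso = 0.05;
edematous bundle keeps the orientation and kappa but raises viso; gray-like
tissue kappa = 0.5 (ODI ≈ 0.70), vic = 0.4, viso = 0.1. The acquisition is
the two-shell protocol (4 × b = 0, 30 × b = 1,000, 60 × b = 2,000 s/mm²)
with directions from seeded electrostatic repulsion, since the original
gradient tables are unpublished. Noise is Rician — the magnitude-MRI noise
model, two independent Gaussian channels at sigma = 1/SNR — at a default
SNR of 30, chosen as a realistic clinical diffusion SNR at 2.5 mm isotropic
voxels and the level at which the FA-fails/ODI-passes contrast must hold
honestly rather than only in the noise-free limit.

**Why edema viso defaults to 0.9.** The defining regime of the study is
that the tensor FA inside the edematous bundle falls below the 0.20
tracking floor while the Watson orientation stays recoverable. For a single
perfectly coherent bundle the required free-water level follows from closed
forms: with kappa = 16 and vic = 0.6, the composite b = 1,000 signal gives a
log-linear-fit FA of roughly 0.42 at viso = 0.6, 0.21 at 0.85 and 0.15 at
0.90. In vivo the FA collapse happens at lower free-water fractions because
real tissue adds crossing fibers and baseline dispersion that the phantom
deliberately omits; a single-tube phantom must compensate with more free
water. The default is therefore 0.9 — the value that puts the edematous
bundle clearly (not marginally) below the floor at SNR 30 — and the tests
that depend on the regime state it through the spec default rather than
re-deriving it.

The optional graded-edema variant (`edema_mild_viso`) lowers the free-water
level in the half of the edema block on one side of the tube axis, so that
the FA-floor tracker traverses the mild half while the severe half is seen
only by the ODI-ceiling tracker. That populates the DN and N-only
conditions simultaneously, which is what makes the fraction-contrast
property (N-only voxels carry more free water and fewer neurites than DN
voxels) testable at all — by construction the contrast direction matches
the clinical finding, which is precisely what the phantom is for.

**What the phantom does not emulate** — and hence what passing tests do not
show about patient data: crossing and fanning fibers (a single-axis Watson
tube only), tumor infiltration as opposed to pure vasogenic edema, partial
volume at tissue interfaces beyond what the block geometry induces, scanner
artifacts (susceptibility distortion, eddy currents, motion — their
correction is explicitly out of scope), inter-site protocol variability,
and anatomically realistic ROI placement. Quantitative edema signal levels
are design choices, not measured values; no quantitative edema model is
published in the source.

## Problem sizes and runtime

The reference conditions (40³ grid, ~5,500 fitted voxels, 3,000-streamline
quota) complete in about two minutes on one CPU: the Watson-NODDI fit is
~13 ms per voxel with the compiled objective, and tracking visits a few
hundred thousand seeds at microseconds each. The test suite reuses one
reference run and one graded-edema run through a memoised fixture; unit
tests run on single voxels, small tubes (20×20×24) and 8³ random masks so
the whole suite stays inside a coffee break.

## Known limitations

- The Watson axis is unidentifiable in near-pure free water; the VF_iso <
  0.95 guard is a pragmatic cut, not a model fix.
- Nelder–Mead can stall on the flat viso≈1 ridge; such voxels keep the grid
  optimum and are flagged rather than re-polished.
- The tensor fit is single-tensor by design; free-water-corrected or
  two-tensor variants are deliberately out of scope.
- LTD is voxel-centre resolution: sub-voxel surface distances are not
  estimated.
- The ODI threshold of 0.45 is a corticospinal-tract calibration; other
  tracts would need their own sweep.
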