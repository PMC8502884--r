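# nodditract

Deterministic fiber tractography that survives peritumoral vasogenic edema,
with the quantification and diagnostics to say what the recovered tract is
worth clinically.

## The problem

Vasogenic edema around a brain tumor floods the extracellular space with
free water. The fractional anisotropy (FA) of the single diffusion tensor
collapses in the flooded voxels, so standard deterministic tractography —
which *terminates* wherever FA ≤ 0.20 — truncates motor tracts at the edema
boundary even when the axons are intact. Surgeons planning a resection then
see a corticospinal tract (CST) that stops short of exactly the region they
need mapped.

The three-compartment Watson-NODDI model explains the multi-shell diffusion
signal as

    A(b, g) = (1 − viso)·[ vic·A_ic + (1 − vic)·A_ec ] + viso·exp(−b·d_iso)

a restricted intracellular compartment `A_ic` (sticks with
Watson-distributed orientations, concentration κ), a hindered extracellular
compartment `A_ec` (tortuosity-scaled anisotropic Gaussian) and free
isotropic water `viso`, with fixed diffusivities d_par = 1.7×10⁻³ and
d_iso = 3.0×10⁻³ mm²/s. Because the free water is modelled out, the
orientation dispersion index

    ODI = (2/π)·arctan(1/κ)

and the fitted Watson axis stay informative inside the edema. This package
re-terminates the deterministic tracker on an **ODI ceiling** (continue
while ODI < 0.45) and follows the Watson axis instead of the tensor
eigenvector; the FA-floor tracker is kept alongside for comparison. Inside
the edema mask, voxels are classified by tracker agreement (DN / D-only /
N-only), and each condition is quantified by volume, percentage of involved
volume (PIV = condition volume / whole-tract volume), lesion-to-tract
distance (LTD), and the LTD-weighted indices volume/LTD and PIV/LTD.
ROC/AUC with Youden's J and paired Wilcoxon signed-rank tests relate those
indices to motor outcome. A synthetic multi-shell phantom (a CST-like tube
through an edema block, with known per-voxel ground truth and Rician noise)
stands in for patient data, which are not publicly deposited.

## Worked example

One command runs the whole pipeline on a small phantom — simulation, tensor
and Watson-NODDI fits, both trackings, quantification, ROC:

```sh
Rscript inst/cli/nodditract demo --seed 17 --out demo-run
```

```
simulate: 24x24x28 grid, snr 30, seed 17
fit-dti: weighted log-linear fit, b < 1500
fit-noddi: grid init + Nelder-Mead refinement
track (dti): 0 streamlines, 20000 attempts [starved]
track (noddi): 200 streamlines, 20000 attempts
quantify: LTD 7.07 mm, N-only PIV 0.2513
roc: edema-volume AUC 0.689, LTD AUC 0.819
```

The two tracking lines are the point: the FA-floor tracker **starves** —
not one of 20,000 seeds produces a streamline connecting the inclusion
slabs, because every path is cut at the edema — while the ODI-ceiling
tracker fills its 200-streamline quota straight through the edema block.
The quantify line reads those reconstructions: about a quarter of the tract
volume (PIV 0.2513) exists *only* in the dispersion-terminated
reconstruction, 7.07 mm from the lesion at its closest. From
`demo-run/metrics.tsv`, the N-only voxels average VF_iso = 0.896 against a
ground-truth edema free-water fraction of 0.9, and the LTD-weighted index
PIV/LTD = 0.0355.

The same functions work on real data read with `read_dwi()` /
`read_mask()` (NIfTI + FSL bval/bvec in, TCK tractograms out). The
clinical fixture shipped with the package reproduces the published
edema-volume diagnostics from its per-patient table:

```r
library(nodditract)
tab <- read_table1()
r <- roc(tab$edema_volume_mm3, tab$motor_decline, larger = "no")
r$auc
#> [1] 0.6890756
sens_spec_at(tab$edema_volume_mm3, tab$motor_decline, 20260, larger = "no")
#> sensitivity specificity
#>   0.4705882   1.0000000
```

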