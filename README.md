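# gfdemons

Deformable (Demons) registration of 3-D medical volumes with
**supervoxel-guided filtering** in place of Gaussian regularization, so
that sliding motion at organ interfaces — lung against pleura, liver
against the abdominal wall — is preserved instead of smoothed away, and
without any prior segmentation of the sliding surface.

The package is aimed at medical image analysts working with respiratory
or contrast-enhanced abdominal data (4D-CT, DCE-MRI) who need
discontinuity-preserving motion estimates, and at method developers who
want a compact, fully tested reference implementation of the guided-filter
regularization idea with a synthetic ground-truth benchmark.

## The method in brief

Demons registration alternates two steps on a displacement field
`u` (transformation `phi(x) = x + u(x)`, pull-back convention):

1. **Force.** The symmetric SSD force
   `f = (I_F − I_M∘phi) / (‖∇I‖² + λκ²) · ∇I` with
   `∇I = (∇I_F + ∇(I_M∘phi))/2` and `κ = I_F − I_M∘phi`; each step is
   bounded by `1/(2√λ)` voxels. A local-correlation-coefficient force is
   available for contrast-varying data. The field is updated
   compositively, `u ← u ∘ f`.
2. **Regularization.** Classically a Gaussian convolution. Here, instead,
   a linear-time **guided image filter**: within each window the output
   is the best local linear function of a *guidance image*
   (`Γ = (Σ + εU)⁻¹ cov(g, p)`), so the filter smooths where the guidance
   is flat and preserves jumps where it has edges. The guidance is a
   stack of supervoxel mean-intensity images from SLIC clustering of the
   fixed image — either several randomly perturbed clusterings
   (`rnd-gif`) or a ladder of cluster counts (`mls-gif`). The classical
   Gaussian baseline (`iso-dem`) is retained, bandwidth-matched to the
   filter by default.

Everything runs in a coarse-to-fine multiresolution pyramid. Accuracy is
evaluated as landmark target registration error (TRE, mm), and a
synthetic sliding-motion phantom with exact ground truth makes the
discontinuity-preserving behaviour verifiable without any external data.

## Worked example

```r
library(gfdemons)

ph <- make_sliding_phantom(seed = 1)   # 64^3, 6-voxel sliding discontinuity
configs <- list(
  "iso-dem" = demons_control(levels = 2, iter_max = 30,
                             regularizer = "iso-dem", K = 140),
  "rnd-gif" = demons_control(levels = 2, iter_max = 30,
                             regularizer = "rnd-gif", K = 140),
  "mls-gif" = demons_control(levels = 2, iter_max = 30,
                             regularizer = "mls-gif", K = 140))
run_benchmark(ph, configs)
```

```
   method tre_mean_mm tre_sd_mm mean_abs_residual frac_nonpos_jacobian
1 initial       3.000     3.038            0.0420                    0
2 iso-dem       1.374     0.769            0.0256                    0
3 rnd-gif       0.724     0.339            0.0218                    0
4 mls-gif       0.755     0.394            0.0217                    0
  interface_jump_voxels
1                  0.00
2                  1.35
3                  3.54
4                  3.49
```

Reading the table: landmarks start 3 mm off on average (the sliding side
carries the full 6-voxel shift, the static side none). Both guided
variants roughly halve the error of the Gaussian baseline, and they
retain 3.5 of the 6-voxel jump across the interface where the Gaussian
keeps only 1.35 — the discontinuity survives the regularization. No voxel
in the region interiors has a non-positive Jacobian determinant, i.e. the
fields stay fold-free away from the interface.

A single fit exposes the usual modelling verbs:

```r
fit <- register_demons(ph$fixed, ph$moving,
                       demons_control(levels = 2, iter_max = 30,
                                      regularizer = "rnd-gif", K = 140))
fit
#> Demons registration (ssd force, rnd-gif regularizer)
#>   grid: 64 x 64 x 64 voxels, 2 level(s), 37 iterations total
#>   displacement |u|: mean 2.733, max 5.859 voxels
#>   mean |residual|: 0.02184 (before: 0.04203)

summary(fit)      # residuals, Jacobian range, convergence
coef(fit)         # the displacement field
predict(fit)      # warped moving volume; predict(fit, landmarks) maps points
residuals(fit)    # intensity residual volume
plot(fit)         # convergence trace
```

Volumes read and write as NIfTI (`.nii`, `.nii.gz`) or MetaImage
(`.mha`/`.mhd`); displacement fields as 3-component vector volumes;
landmarks as plain text in mm. A thin command-line front end is installed
as `exec/gfdemons` (`register`, `phantom`, `benchmark` subcommands).

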