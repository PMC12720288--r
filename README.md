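# kinr — meta-learned implicit neural representations for registration-driven volumetric MRI estimation

`kinr` estimates a 3D MR volume from two inputs: a fully sampled,
high-quality **prior volume** of the same subject and a handful of
**golden-angle radial k-space spokes** of the new anatomy (tens-of-fold
below Nyquist, as on MR-guided treatment platforms). Instead of
reconstructing from the sparse samples, it solves a deformable registration
problem: a SIREN implicit neural representation (INR) predicts a dense
displacement field \(\hat d(v)\), the prior is backward-warped through a
spatial transformation layer, projected by a non-uniform discrete Fourier
transform (NUDFT) onto the measured trajectory, and optimised until the
projection matches the data. The estimated volume is the warped prior, so
anatomical detail survives extreme undersampling.

For whom: researchers in MR-guided radiotherapy / real-time volumetric MRI
who want a fully inspectable, CPU-scale implementation of
cohort-informed meta-learned INR registration, with synthetic phantom
cohorts standing in for clinical data.

## The method

Per case, adaptation minimises (step B)

```
L = λ1 · L_kspace + λ2 · L_embed + λ3 · L_smooth        (λ = 1.0, 0.5, 0.5)
L_kspace = (1/N_k) Σ_i |S_DK(k_i) − T_UK(k_i)|²
L_embed  = − (1/N_e) Σ_i cos( E(S_DI)_i , E(T_UI)_i )
L_smooth = Σ_j (1/N) Σ_i ( (∂d_j/∂x)² + (∂d_j/∂y)² + (∂d_j/∂z)² )
```

preceded by a prior-guided step A that pulls the INR toward the reference
field of a frozen population registration network (mean absolute
per-component deformation discrepancy). The INR template is a 5-layer sine
MLP, hidden layers conditioned by a token-aware modulator
(`F_l = sin(γ_l ⊙ (w_l F_{l−1}) + β_l ⊙ b_l)`), and is meta-trained across a
cohort Reptile-style: per subject, inner step-A/step-B loops; the averaged
parameter difference moves the template; the modulator is updated by
backpropagating the step-B loss. Test-time adaptation then needs only a few
unsupervised epochs. Baselines and ablations (`ks_iterative`, `ks_inr`,
`meta_inr`, `meta_inr_a`, `meta_inr_b`, `cmeta`) are run modes of the same
pipeline.

Everything — SIREN, attention modulator, UNet-style prior, trilinear warp,
NUDFT, losses — is differentiated by the package's own tape-based
reverse-mode autodiff engine, property-tested against finite differences.

## Worked example

Scratch-INR registration of one synthetic subject (32×32×8 phantom with
smooth respiratory-like motion of ≈3.4-voxel peak, 13 spokes — ≈31-fold
acceleration at a 256 matrix):

```r
library(kinr)

cfg  <- meta_config("desk", variant = "ks_inr", n_spokes = 13L,
                    samples_per_spoke = 64L, n_adapt = 150L)
subj <- generate_cohort(1, default_phantom_spec(c(32, 32, 8)),
                        motion = motion_model(c(1.5, 1, 3), 10, 4),
                        seed = 42)[[1]]
case <- make_case(subj, target_bin = 3, cfg, seed = 9)

metric_re(magnitude(case$S_FI), case$truth$target_mag)   # 70.05 % unregistered

res <- adapt_case(init_template(cfg$widths, seed = 1), NULL, NULL, case, cfg)
res$metrics$re_percent                                   # 8.66 %  registered
res$metrics$dice                                         # 0.930  lesion Dice
```

The unregistered volume differs from the target by 70 % relative error;
after 150 unsupervised step-B epochs driven only by 13 spokes of k-space
data, the warped prior matches the hidden ground-truth target to 8.7 % RE
and the propagated lesion mask overlaps the true one with Dice 0.93.

The full pipeline (simulate → train prior → meta-train → adapt → evaluate)
runs from one config:

```r
report <- cmd_pipeline(run_config(seed = 3, out_dir = "runs/demo"))
report$metrics   # ssim / re_percent / dice / hd95_mm / come_mm per held-out bin
```

or from the shell via the CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/kinr.R", package="kinr"))')" \
    pipeline --config my_run.yaml
```

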