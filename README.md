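# mwtomo

Simulation and deep-learning detection for 2D microwave breast tomography,
end to end in one R package: stochastic dielectric breast phantoms, a
Method-of-Moments electromagnetic forward solver, receiver-noise
corruption, a 10-layer convolutional detector that scores multistatic
scattering matrices for the presence of malignant tissue, and full
ROC/EER evaluation.

## The problem

Microwave tomography surrounds the breast with a ring of antennas in a
coupling medium; each antenna transmits a 1 GHz wave in turn and all
antennas receive, yielding the complex multistatic **scattering matrix**
`S` (here 30 x 30), with `S[t, r]` the scattered field at receiver `r`
for transmitter `t`. Malignant tissue has markedly higher permittivity
and conductivity than healthy tissue, but recovering dielectric maps from
`S` is a nonlinear, ill-posed inverse problem, and small tumors fall
below the resolution of practical inverse solvers. `mwtomo` implements
the alternative: skip imaging entirely and classify `S` directly with a
convolutional network, which can flag tumors far smaller than the imaging
resolution limit.

The forward model is the 2D transverse-magnetic pair of volume integral
equations

    Es = Ae(chi, Et)            (data equation)
    Et = Ei + Ai(chi, Et)       (state equation)

with contrast `chi = (eps_c - eps_cb)/eps_cb`,
`eps_c = eps' - j sigma/(omega eps0)`, discretised by pulse-basis /
point-matching MoM with Richmond's equal-area-circle cell integrals, and
solved either by FFT-accelerated conjugate gradients on the normal
equations (CG-FFT) or by an exact direct factorisation on the contrast
support. The solver is validated against the analytic
cylindrical-harmonics series for a homogeneous cylinder (< 1% RMS at
108 x 108, improving monotonically with refinement), dense-matrix
oracles, reciprocity, and Born-scaling checks. The detector is the
trunk the study describes — 10 convolutional stages, 32 features each,
3 x 3 kernels — implemented natively (single-precision C++ with BLAS
im2col convolutions), trained with Adam on binary cross-entropy with
best-validation-epoch checkpointing. Evaluation reports AUR
(trapezoidal, equal to the Mann-Whitney statistic), EER (rate at the
FPR = FNR crossing), and accuracy/sensitivity/specificity at `Th = 0.5`.

## Worked example

```r
library(mwtomo)

cfg  <- generator_config(grid = grid_spec(15, 54))   # 15 cm domain, 54 x 54
geom <- acquisition_geometry()    # 30 antennas, 12 cm ring, 1 GHz, eps_b 15

# one pathological class-B phantom and its scattering matrix
ph <- generate_phantom(cfg, class = "B", pathological = TRUE, seed = 42)
ph
#> <mwt_phantom> class B, pathological, 1 tumor(s), 54 x 54 grid (seed 42)
ph$tumors[[1]]$area_cm2
#> [1] 7.638889

S <- assemble_scattering_matrix(ph, geom)
S
#> <mwt_scattering> 30 x 30, solver direct (residual 8.1e-16)

# corrupt at 30 dB SNR
S30 <- add_awgn(S, snr_db = 30, seed = 1)
```

A complete scaled-down study — generate a balanced database, simulate,
corrupt, train one detector per SNR condition, and evaluate — runs
through one configuration:

```r
cfg <- run_config(list(
  seed = 1L,
  phantoms = list(n_pixels = 54L, n_per_cell = 42L,
                  split = list(train = 4/7, val = 1/7, test = 2/7)),
  noise = list(snr_db = list("Inf", 30)),
  detector = list(epochs = 20L, batch_size = 32L,
                  learning_rate = 1e-3, augment = TRUE)))
res <- run_pipeline(cfg)
res$summary
```

`summary` is a tibble with one row per SNR condition and columns
`aur`, `eer`, `accuracy`, `sensitivity`, `specificity`, `n_test`: the
probability that a random pathological profile outscores a healthy one
(AUR), the rate at which false alarms equal misses (EER), and the
`Th = 0.5` operating point.

A caveat that matters when reading desk-scale numbers: the reference
study trained on 128,000 simulated profiles, and the tumor's imprint on
`S` is small (a few percent in Frobenius norm) relative to
profile-to-profile anatomical variability, so detection power is
strongly data-limited. At the few hundred to few thousand profiles a
single CPU can simulate and train on, test AUR sits far below the
reference figures (near 0.55-0.6) even though the physics and training
chain are fully validated — with artificially strong tumor contrast the
same pipeline reaches AUR above 0.9 from under a hundred profiles. The
methods vignette quantifies this and records the supporting
experiments.

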