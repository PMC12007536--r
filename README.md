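# dualmt

Protocol optimization and tract-specific magnetization transfer (MT) for
co-encoded MT-diffusion MRI.

Myelin-sensitive MT contrast and diffusion-based tractography can be
acquired in a single spin-echo EPI sequence by playing a pulsed off-resonance
MT preparation before each slice. `dualmt` provides the two computational
pieces such an experiment needs:

1. **A pulsed MT saturation simulator** — a two-pool (free water +
   macromolecular) Bloch model with a dipolar-order reservoir, used to
   optimize the preparation (offset frequency, polarity, pulse count and
   duration, per-slice repetition time `TR_MT`) for *MTR efficiency*:
   macromolecular MTR per unit scan time, at the maximum flip angle allowed
   by SAR and under a total scan-time budget. Dual (alternating-polarity)
   irradiation is modeled explicitly: a constant offset sign pumps dipolar
   order, which throttles bound-pool saturation; alternating the sign
   cancels it.

2. **A global tract-specific MTR estimator** — for each of the MT-on and
   MT-off diffusion datasets, every streamline gets one non-negative weight
   (signal per unit length) under a zeppelin-and-ball forward model

   `S(q) / S(b=0, MT_off) = Σ_i x_i · L_i(voxel) · R_zeppelin(q; dir) + x_ball · R_ball(q)`

   solved by non-negative least squares over the whole brain (or phantom) at
   once. Streamlines with positive weight in both fits are grouped by the
   gray-matter node pair they connect, and each bundle's MTR is

   `MTR_bundle = 1 − Σ_j L_j x_j^on / Σ_j L_j x_j^off`.

   Because the ball compartment absorbs isotropic (free-water / gray-matter)
   signal and crossing fibers are unmixed by the global fit, this estimate
   resists the partial-volume bias that affects conventional tractometry
   (sampling a scalar MTR map along streamlines). A tractometry baseline,
   single-fiber-voxel references, and method-comparison statistics are
   included, as is a synthetic crossing-fiber phantom generator with known
   per-bundle MTR for end-to-end validation.

Readers and writers for NIfTI, FSL `bval`/`bvec` and MRtrix TCK streamline
files are built in, plus a thin command-line front end
(`inst/cli/dualmt.R`).

## Worked example

Optimize the preparation over `TR_MT` at the optimal pulse train, then
recover bundle MTRs from a synthetic crossing phantom:

```r
library(dualmt)

## -- protocol optimization ---------------------------------------------
tissue <- two_pool_tissue()      # M0b 0.1, T1d 3 ms, T2a 60 ms, R 26 /s ...
sar    <- default_sar_model()    # 97% of 3.2 W/kg at FA 596 deg, TR 90 ms
base   <- sequence_protocol(prep = mt_prep(offset_hz = 3000, n_pulses = 7,
                                           tau = 1e-3))
grid <- optimize_protocol(list(tr_mt = seq(0.09, 0.15, 0.01)), tissue, sar,
                          base_protocol = base)
print(grid)
#> MTR-efficiency grid: 7 protocols, 7 feasible
#> Optimum:
#>  tr_mt fa_mt       mtr scan_time_s   efficiency feasible
#>   0.09   596 0.2990342      345.96 0.0008643607     TRUE

## -- phantom -> fit -> bundle MTR --------------------------------------
ph  <- make_crossing_phantom(seed = 42)      # true MTRs 0.30 / 0.40
sc  <- make_scheme()                         # 1 b0 + 30 dir, b = 1500
dat <- synthesize_dwi(ph, sc)
fit <- dual_fit(dat$mt_on, dat$mt_off, ph$tractogram, sc, ph$voxel_size,
                max_iter = 20000, segments = ph$segments)
bundle_table(fit, ph$node_pairs)
#>   node_a node_b n_streamlines vol_on vol_off mtr
#> 1      1      2            40  985.6    1408 0.3
#> 2      3      4            40  844.8    1408 0.4
```

The optimum sits at the shortest `TR_MT` (90 ms): the SAR-matched flip angle
shrinks as `sqrt(TR_MT)`, but scan time grows faster than the MTR gain. The
dual acquisition at the optimum lasts `0.090 × 62 slices × 31 volumes × 2 =
345.96 s` (≈5.8 min). On the noiseless phantom the tract-specific bundle
MTRs equal the generating truth to solver precision, while conventional
tractometry on the same data is biased low by the isotropic background and
the crossing (see the methods vignette, `vignettes/dualmt-methods.Rmd`).

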