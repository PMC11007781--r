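# bistatus

Bistatic dual-aperture ultrasound imaging and vascular strain
elastography in R.

Imaging a large vessel such as the abdominal aorta with a single
ultrasound probe is anisotropic by physics: the anterior and posterior
wall reflect specularly and track precisely along the beam, while the
lateral walls show poor contrast and the lateral displacement estimates
drift, corrupting circumferential strain exactly where it matters. This
package implements the dual-aperture remedy end to end. Two curved
arrays share one imaging plane and alternately transmit steered
diverging waves while both receive on every event, yielding four signals
per frame — the monostatic pairings T1R1, T2R2 and the trans-probe
pairings T1R2, T2R1. The package

* simulates dual-probe channel data from a pulsating-vessel
  point-scatterer phantom with analytic ground-truth displacement and
  strain (a stand-in for in vivo recordings, which are not publicly
  available);
* reconstructs every pairing by delay-and-sum on complex baseband data,
  on Cartesian and beam-aligned sector grids;
* registers the probes automatically by gradient descent on the
  negative signal power `P- = -Σ|A_i|²` of the compounded trans-probe
  image (coherence is maximal at the true pose), with an
  envelope-correlation pre-alignment and a scan along the weakly
  identified rotation-about-vessel direction;
* fuses the four images coherently,
  `I_bistatic = I_T1R1 + I_T2R2 + (I_T1R2 + I_T2R1)/2`,
  averaging the trans-probe terms related by acoustic reciprocity;
* estimates wall motion per pairing by 2-D coarse-to-fine speckle
  tracking (envelope then RF normalized cross-correlation, parabolic
  sub-sample refinement, median filtering), projects axial estimates to
  the vessel-radial direction `u_rad = u_ax / cos θ`, and compounds them
  with cosine angular masks `M = cos(2θ)/2 + 1/2` (70°–110° cut out);
* tracks a 5-layer wall mesh through the compounded field and estimates
  radial and circumferential strain with a 5×5-node 2-D least-squares
  estimator against the first frame;
* reports the quality metrics of the trade: generalized
  contrast-to-noise ratio (gCNR) between wall and eroded lumen, globally
  and in eight 45° regions; the mean drift error (ME) of the wall over a
  cardiac cycle; the elastographic signal-to-noise ratio
  `SNRe = 20 log10(|μ_ε|/σ_ε)`; and paired t / Wilcoxon mode
  comparisons.

The methods vignette
(`vignettes/bistatic-aortic-elastography.Rmd`) documents the models,
parameters, numerical choices and limitations.

## Worked example

```r
library(bistatus)

cfg <- pipeline_config(seed = 42, mode = "bistatic")
run <- run_pipeline(cfg)
print(run$register)
print(run$metrics)
```

prints (seed 42):

```
probe registration: converged after 19 iterations, P- -1.325e+09 -> -1.328e+09
rigid transform: tx -39.3912 mm, tz 33.1731 mm, phi -80.1429 deg
metric report (bistatic):
  gCNR (wall vs lumen): 0.953
  mean drift error:     0.001 mm (frames 1 -> 11)
  SNRe circumferential: 30.8 dB
  SNRe radial:          -4.4 dB
```

The registered pose is 0.12 mm / 0.14° from the true probe-2 placement
(the optimizer started 5 mm, 5 mm, 3° away — the configured read-out
error of the mechanical arch). The wall returns to within 0.001 mm of
its start after one simulated cardiac cycle, and the circumferential
strain at the mid-wall layer is uniform enough for a 30.8 dB SNRe; at
the peak of the cycle it matches the incompressible ring's analytic
value (0.0170) within 0.0014 at every analyzed node. Re-running the last
stages in `mode = "single_perspective"` on the same simulated
acquisition (see the vignette) gives the single-probe baseline:

```
metric report (single_perspective):
  gCNR (wall vs lumen): 0.956
  mean drift error:     0.020 mm (frames 1 -> 11)
  SNRe circumferential: -3.0 dB
  SNRe radial:          -1.3 dB
```

— a twenty-fold larger drift and a ~34 dB lower circumferential SNRe,
the desk-scale analogue of the improvement dual-aperture imaging brings
in vivo.

A thin command-line front end wraps the same pipeline:

```sh
inst/cli/bistatus all --config cfg.yaml --out run_dir --png
```

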