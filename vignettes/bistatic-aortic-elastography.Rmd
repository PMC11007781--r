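---
title: "Bistatic dual-aperture ultrasound imaging and vascular strain estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistatic dual-aperture ultrasound imaging and vascular strain estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Conventional single-probe ultrasound of a large vessel such as the
abdominal aorta sees the anterior and posterior wall well — those
interfaces are perpendicular to the beam and reflect specularly — but the
lateral walls poorly. The same anisotropy afflicts motion estimation:
displacement is precise along the beam (phase-sensitive, sub-wavelength)
and poor laterally, so wall tracking drifts and strain maps are noisy
exactly where the circumferential direction aligns with the beam's
lateral direction.

`bistatus` implements the dual-aperture remedy: two curved arrays in one
imaging plane alternately transmit steered diverging waves while *both*
receive on every event. One frame therefore yields four signals — the
monostatic pairings T1R1 and T2R2 and the trans-probe (bistatic) pairings
T1R2 and T2R1 — which, once the relative probe pose is known, are
reconstructed in one frame of reference, compounded coherently, and used
jointly for speckle tracking.

Because the in vivo recordings such a rig produces are not publicly
available, the package ships a first-class simulator: a point-scatterer
phantom of a pulsating vessel with analytic ground-truth displacement and
strain, which stands in for the unavailable recordings and gives the
validation that in vivo data cannot (there is no in vivo ground truth).

## Geometry and acquisition model

Coordinates are x lateral (positive right) and z depth (positive down),
with the origin at the probe-1 surface apex; everything is reported in
this frame. Probe 2 is placed by a rigid transform `T` (two translations
and a rotation), the registration variable.

Each transmit is a diverging wave: the virtual source sits behind the
array on the line through the probe origin along the steering direction,
at a standoff that defaults to the radius of curvature (so an unsteered
wave appears to emanate from the arc center). Steering angles are
measured at the probe origin against the z axis; the defaults span
-12 to +12 degrees, mirroring a curved-array ultrafast protocol, with a
Tukey (ratio 0.25) transmit apodization against side lobes. Element count
(64 per probe at desk scale), pitch 0.508 mm, curvature radius 49.57 mm
and center frequency 3.7 MHz parameterize a C5-2v-class array; none of
the tests depend on these exact values. The speed of sound (1540 m/s)
and the virtual-source standoff are configuration parameters, since a
scanner's exact wave definition varies.

The forward model is linear scattering: each channel sample is a sum over
scatterers of reflectivity x element directivity (cosine to a
configurable power, applied on both the transmit and receive side so that
single-element transmit/receive traces obey acoustic reciprocity) x a
Gaussian-modulated pulse at the arrival time. Transmit arrival is the
*first arrival* over the aperture (minimum of element delay plus travel
time) — a geometric approximation of the diverging wavefront that avoids
full wave simulation while keeping the delay geometry exact. No
attenuation, aberration or multiple scattering is modeled, so the
simulator makes no claim of matching absolute in vivo contrast; it is a
geometry-and-speckle phantom.

## The pulsating-vessel phantom

The scene is an echogenic wall ring (uniform scatterers in the annulus,
default 10 per mm^2) around an anechoic lumen, embedded in weaker
background speckle, with an optional bright "spine" arc below the vessel
(off by default). Wall motion follows an incompressible-ring law: a wall
particle at rest radius $r$ moves to

$$r' = \sqrt{r^2 + r_i(t)^2 - r_{i0}^2},$$

which conserves the annulus area exactly; the analytic circumferential
strain at rest radius $r$ is $r'/r - 1$ and the radial strain $r/r' - 1$.
The default inner-radius waveform is a raised cosine with a 2% peak
excursion over an 11-frame cycle (it returns exactly to rest, so true
end-of-cycle drift is zero). Eleven frames per cycle is far coarser than
an ultrafast scanner's 130 Hz would give over a heartbeat; it keeps a
full study in minutes while the per-frame wall displacement (under
0.1 mm) stays well inside the tracker's search range, i.e., the tracking
problem per frame pair is equivalent.

## Beamforming

All reconstruction is delay-and-sum on complex baseband data (analytic
signal via the frequency-domain Hilbert transform, mixed down by the
carrier), with linear inter-sample interpolation and carrier phase
restoration `exp(+2i pi f0 tau)`, so every image is the analytic,
carrier-preserving signal and images compound coherently across steering
angles and pairings. Receive contributions are restricted to a 45-degree
acceptance cone about each element normal; there is no receive
apodization. Three grids are used, all tied to the wavelength
$\lambda$: a half-wavelength Cartesian grid for registration, a
quarter-wavelength Cartesian grid for the fused image

$$I_{bistatic} = I_{T_1R_1} + I_{T_2R_2} + \tfrac12\,(I_{T_1R_2} + I_{T_2R_1}),$$

(the two trans-probe terms carry the same information by acoustic
reciprocity, hence their averaged contribution), and per-probe sector
grids — 2 lines per pitch laterally, $\lambda/8$ axially — for tracking,
because on a sector grid the axial direction is the physical beam
direction of the receiving array.

## Automatic probe registration

The probe-2 pose is found by maximizing the coherence of the compounded
trans-probe image: the objective is the negative signal power
$P^- = -\sum_i |A_i|^2$ of the envelope-detected, angle-compounded T1R2
image, minimized by gradient descent
$\mathbf{T} \leftarrow \mathbf{T} - \mu \nabla_\mathbf{T} P^-$ with a
central-difference numerical gradient (six reconstructions per
iteration). Convergence is declared when the objective change stays
within 5% of the total improvement since the start for three consecutive
iterations; if ten consecutive proposals increase the objective the run
is flagged divergent and the best-seen pose returned, never a silent
claim of optimality.

Two practical facts shape the optimizer around this core:

* The raw gradient mixes units (power per mm vs per degree). Steps are
  therefore taken along the negative gradient direction in a parameter
  space scaled by per-parameter learning rates (mm, mm, degrees), with
  the rate halved on a rejected (objective-increasing) step and grown
  30% on acceptance. Finite-difference steps default to $\lambda/4$ in
  translation and 0.1 degree in rotation, below which the coherence
  surface is locally smooth.
* The coherence surface has a sharp basin (of order 1 mm / 1 degree at
  desk scale) surrounded by a flat speckle floor, and one *sloppy*
  direction: rotating probe 2 about the imaged vessel changes the data
  little, because the vessel stays registered while the probe swings
  around it. Descent alone therefore cannot capture a realistic
  initialization error of several mm. `register_probes()` optionally
  precedes the descent with (a) an envelope-correlation alignment of the
  two monostatic images — the automated analogue of manually registering
  the images on the vessel before optimization — which collapses the
  initialization error onto the sloppy direction, and (b) a 1-D scan of
  $P^-$ along that rotation-about-vessel direction with parabolic
  refinement. Both stages use the same physics (the coherence objective
  and the reconstructed images); the descent then polishes the pose to a
  fraction of a wavelength, typically in 10-20 iterations.

Receive-element decimation (default factor 2 inside the pipeline) speeds
up objective evaluations proportionally with no measurable loss in final
accuracy at desk scale.

## Speckle tracking and displacement compounding

Frame-to-frame motion is estimated per pairing on its receive sector grid
by a 2-D coarse-to-fine block matcher: a coarse pass on the envelope
(kernel 2.6 mm axially x 4.5-5.9 mm laterally, interpolated over depth;
zero-mean normalized cross-correlation), an 11 x 11-pixel-equivalent
median filter (0.6 mm x 4.5-5.9 mm), then a fine pass on the RF (real
part; kernel 0.8 mm x 2.1-2.7 mm, raw normalized correlation) seeded by
the coarse integer lags, refined per axis by parabolic interpolation of
the correlation samples, and median filtered again. Ties at equal
correlation resolve to the smallest lag magnitude (zero-bias prior);
nodes whose kernel or search window leaves the grid are invalid rather
than padded. The axial kernel sizes are tied to the wall: the coarse
kernel covers the full 1.7 mm thickness, the fine kernel about half of
it so radial gradients survive. Tracking nodes are a strided lattice of
the sector grid (default every 4th axial sample, every line) — the field
is smooth at the kernel scale, and the mesh tracker interpolates.

Axial estimates are projected to the vessel-radial direction,
$u_{rad} = u_{ax} / \cos\theta$, where $\theta$ is the angle between the
pairing's effective beam direction and the outward radial direction. For
the monostatic pairings the beam direction is the receive beam; for the
trans-probe pairings it is the *bisector* of the transmit and receive
directions, since a bistatic echo is specular normal to the bisector.
Tracked axial shifts in a bistatic image additionally over-state the
geometric motion by $1/\cos(\gamma/2)$ ($\gamma$ the transmit/receive
angular separation), because the round-trip path changes by
$(\hat d_{tx} + \hat d_{rx})\cdot\delta$; the package applies this
bistatic range conversion before projecting. Angles within 70-110
degrees are cut out entirely (the projection diverges there), and the
remaining estimates are fused per node with cosine masks

$$M = \tfrac12\cos 2\theta + \tfrac12,$$

weighted 1 : 1 : 1/2 : 1/2 (trans-probe reciprocity again) and
normalized so the active weights sum to one — un-normalized weights
would scale displacements by an angle-dependent factor. Lateral
displacement estimates are computed (the coarse-to-fine matcher is 2-D)
but never compounded; they enter only the single-perspective comparison
mode, which applies the raw axial + lateral estimates of T1R1 without
projection — exactly the configuration whose lateral drift the bistatic
method is designed to remove.

## Wall mesh, strain, and quality metrics

A circular segmentation of the lumen-wall border at rest (the phantom's
true border; segmentation itself is out of scope) is extruded along
outward normals to a 5-layer mesh of uniform 1.7 mm thickness, nodes
ordered clockwise from the anterior point, circumferential spacing
chosen so 5 nodes span about 2.6 mm at the rest mid-wall radius. Five
layers are the smallest odd count with a genuine middle layer that fits
the 5 x 5 strain kernel. The mesh is advected frame to frame by the
compounded radial displacement sampled at current node positions
(Eulerian accumulation) along radial directions fixed at the reference
frame — consistent with estimating local displacement against a fixed
reference and midpoint; nodes that leave field coverage are flagged and
carried by their last valid displacement.

Strain relative to the first frame comes from a 2-D least-squares
estimator: over each 5 x 5 node neighborhood (radially truncated at the
wall surfaces, circumferentially wrapped), the reference-frame-relative
displacement, expressed in the center node's radial/circumferential
frame, is regressed linearly on the local radial/circumferential
coordinates; the two fitted gradients are the radial and circumferential
normal strain. Both displacement components are fitted and both normal
strains reported. The estimator is exact for affine deformations and
reproduces the incompressible ring's analytic strain profile to a few
1e-4 when fed ground-truth displacement.

Quality metrics mirror the strain-imaging literature: the generalized
contrast-to-noise ratio between the wall annulus and the lumen (one
minus the histogram overlap of envelope amplitudes, 256 bins over the
pooled range — stable against 128/512), with the lumen mask eroded by a
0.6 mm disk so wall specular reflections are excluded; a regional
analysis over eight 45-degree sectors anchored on the right (probe-1)
transducer's beam direction, clockwise; the mean drift error (mean
end-of-cycle middle-layer node displacement between the two end-diastolic
frames, read as the frames of minimal inner radius — exact for the
simulator's closed waveform); and the elastographic signal-to-noise
ratio $20\log_{10}(|\mu_\varepsilon|/\sigma_\varepsilon)$ on the middle
layer, using the absolute mean so that compressive strains of equal
precision report equal positive dB. Strain statistics exclude a
37.5-degree section at the left and right wall where neither aperture
contributes sufficient signal. Paired mode comparisons run a Shapiro-Wilk
check on the differences and choose a paired t-test or a Wilcoxon
signed-rank test accordingly, reporting which ran.

## Desk-scale study conditions

The default configuration — the "standard study" used by the test suite
and by `scripts/acceptance.R` — is: both 64-element probes aimed at a
vessel of 10 mm inner radius and 1.7 mm wall at 40 mm depth, inter-probe
angle 80 degrees, 5 steering angles, ~5,000 scatterers, noiseless
channels, 11 frames over one cycle with 2% peak inner-radius excursion.
A full bistatic + single-perspective evaluation runs in a few minutes on
one CPU. What passing at this scale shows — and what it does not — should
be read together: the pipeline recovers probe pose to a fraction of a
wavelength, tracks the wall with an order-of-magnitude smaller drift
than the single-perspective configuration, and reproduces the analytic
circumferential strain within a small fraction of its peak value, all
under a linear, aberration-free, in-plane acoustic model. Real tissue
adds sound-speed heterogeneity, attenuation, out-of-plane motion and
physiological variability that this phantom deliberately omits. One
consequence worth flagging: a diffuse point-scatterer wall has no
specular reflection, so the severe lateral-wall contrast loss that
motivates dual-aperture imaging in vivo appears only weakly here — the
vessel-lumen gCNR sits near 1 in every region at desk scale, and
contrast comparisons between modes are informative as lateral-region
aggregates, not per region. The added wall signal itself is directly
visible in the bistatic image's wall-region energy, which roughly
doubles the best single pairing's.

## Worked example

```{r}
library(bistatus)

cfg <- pipeline_config(seed = 42, mode = "bistatic")
run <- run_pipeline(cfg, verbose = TRUE)
print(run$register)
print(run$metrics)

## single-perspective comparison on the same simulated acquisition
cfg_sp <- pipeline_config(seed = 42, mode = "single_perspective")
run_sp <- new.env(parent = emptyenv())
for (nm in c("sim", "T2_init", "seed", "config_hash"))
  run_sp[[nm]] <- run[[nm]]
run_sp$config <- cfg_sp
run_pipeline(cfg_sp, stages = c("beamform", "track", "strain", "metrics"),
             run = run_sp)
print(run_sp$metrics)
```

## Numerical choices and degenerate inputs

* Demodulation is exact for band-limited pulses (FFT Hilbert); no filter
  design enters.
* Delay interpolation is linear on baseband samples with carrier phase
  rotation; delays outside the recorded window contribute zero.
* Flat (zero-variance) correlation kernels return zero displacement with
  zero quality; parabolic refinement is skipped at search-edge maxima
  and for non-concave triples.
* The convergence reading "within a 5% range of the difference compared
  to the starting value" is implemented as
  $|P^-_k - P^-_{k-1}| < 0.05\,|P^-_0 - P^-_k|$ for 3 consecutive
  iterations.
* An all-zero image cannot be log-compressed, a registration region must
  be non-empty, an eroded lumen must remain non-empty, and a mesh offset
  that folds (thickness beyond the local curvature radius) is an error —
  each is refused loudly rather than propagated.

## Known limitations

Single plane only (out-of-plane motion is invisible); no aberration or
sound-speed estimation (the registration compensates geometry, not
medium); lateral displacements are discarded rather than modeled; the
local strain frame is fixed at the reference configuration; gradient
descent finds the nearest coherence optimum — with initialization errors
far beyond the prealignment capture range, multiple local minima exist
and the objective history is the honest record of what was found.
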