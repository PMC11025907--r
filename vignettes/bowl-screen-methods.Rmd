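---
title: "Bowl-screen geometry and receptive-field mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bowl-screen geometry and receptive-field mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowlvr)
```

`bowlvr` implements the computational core of a projector-based panoramic
visual-stimulation arena for insects: a bowl-shaped screen whose profile is
derived analytically from the projector's optics so that the number of
projector pixels per ommatidium is constant across the visual field. This
vignette describes the models the package implements, the assumptions they
rest on, the parameters that matter, and the design decisions taken where
the problem was genuinely open.

## The screen model

The observer (a fly, or any sensor) sits at the origin; the projector sits
at distance $d_{proj}$ on the optical axis. Two constants of the projector
optics enter the model: the throw ratio $r_{throw}$ (projection distance
over image width) and the image aspect ratio $r_{aspect}$, combined into
$r = r_{throw} \cdot r_{aspect}$. A projection offset of 100% (the optical
axis grazing the lower image edge) is required and enforced.

In the two-dimensional cross-section through the optical axis, the facet of
the compound eye looking at elevation angle $\alpha \in (0, \pi)$ views
along the unit vector $(\cos\alpha, \sin\alpha)$ (`fly_ray()`). A
commercial projector produces uniform pixel spacing on a *planar* screen,
so the ray addressing elevation parameter $\alpha$ leaves the projector
with direction $(1, \alpha/(\pi r))$ (`projector_ray_line()`); the full
image height sweeps $\alpha$ from $0$ to $\pi$. Intersecting the two lines
gives the screen profile

$$X(\alpha) \;=\; \frac{d_{proj}\,\alpha}{\alpha - \pi r \tan\alpha}
\begin{pmatrix}1\\ \tan\alpha\end{pmatrix},$$

the curve along which one ommatidium always receives the same number of
projector pixels (`profile_point()`). The 3D screen is the surface of
revolution of this profile about the optical axis (`surface_point()`,
`screen_surface()`); the published form of the surface as a product of a
$\beta$-dependent and an $\alpha$-dependent vector is read component-wise
as exactly this rotational extrusion, which is the only reading that
produces a surface point and matches the stated 180° rotational extrusion
used for fabrication.

Numerically, the profile is evaluated in the stabilized form
$d_{proj}\,\alpha/(\alpha\cos\alpha - \pi r\sin\alpha)\cdot
(\cos\alpha,\sin\alpha)$, obtained by multiplying numerator and denominator
by $\cos\alpha$. This removes the $\tan\alpha$ blow-up at
$\alpha = \pi/2$, where the raw formula is $0\cdot\infty$ but the limit
$(0, -d_{proj}/2r)$ is finite; the stable form evaluates to the limit
automatically. For $\pi r > 1$ (every realistic projector; the default
$1.4 \times 16/9 = 2.49$ gives $\pi r = 7.8$) the stabilized denominator
has no root in $(0, \pi)$, so the profile is smooth over the whole usable
range. For $\pi r < 1$ a genuine singularity appears below 90°;
`screen_profile()` scans for sign changes and refuses such ranges by
naming the offending elevation. The fabricated field of view defaults to
15°–140° of elevation, leaving out the pole (occupied by the holder) and
the extreme rim.

Profiles are exported as SVG polylines and surfaces as binary STL meshes
(`write_profile_svg()`, `write_surface_stl()`), both with readers for
round-trip verification. Default sampling is 200 profile points, uniform in
$\alpha$ — at a 100 mm scale the chord error is far below 0.1 mm, well
under printer accuracy.

## Projection: equidistant azimuthal pixel maps

Because of the screen shape, the image the projector must display is
exactly the equidistant azimuthal projection of the sphere around the bowl
pole: image-plane radius proportional to the polar angle $\alpha$, image
angle equal to the azimuth $\beta$ (`eqaz_forward()`). With the 100%
upward offset the pole sits at the bottom-center of the projector image
and the image height spans $\alpha = 0$–$180°$.

Stimuli are authored as equirectangular spherical textures
(`spherical_texture()`; rows = elevation with row 1 at the top, columns =
azimuth, luminance in $[0,1]$, coordinates at pixel centers). For every
projector pixel, `build_pixel_maps()` precomputes the texture pixel whose
view direction that projector pixel illuminates, plus a mask restricting
light to the screen. The maps depend only on geometry, so rendering a frame
(`apply_maps()`) is a single nearest-neighbour gather — nearest-neighbour
rather than interpolating, so displayed luminances are exactly texture
values; bilinear lookup is available but off by default. The view-direction
convention is `elevation = alpha − 90` (bowl pole at elevation −90,
straight down) and `azimuth = beta`; the default texture covers the
180° × 125° screen field of view.

Spherical rotations (`rotate_equirect()`, with `rotation_between()` /
`rotation_axis_angle()`) resample a texture under a 3D rotation by
bilinear lookup at the inverse-rotated direction. Rotations of the sphere
are exact; the only error is resampling, which conserves the solid-angle
integral of smooth 1°-resolution textures to within about 2%.

## Distortion evaluation on a compound-eye model

The compound eye is modeled as a Goldberg polyhedron GP(3,3): 272 faces
(260 hexagons, 12 pentagons), each face standing for a patch of visual
space roughly nine *Drosophila* ommatidia wide. The polyhedron is built as
the dual of the icosahedral geodesic triangulation of the same frequency
(`goldberg_polyhedron()`); class-I frequencies GP(m,0) and achiral
class-II GP(m,m) are supported, the latter via the Eisenstein-integer
factorization $(m + m\omega) = (1+\omega)(m)$ — subdivide the pentakis
dodecahedron class-I by $m$.

The published model has hexagons of equal area within ±1%. How that
equality was achieved is not stated, so the package makes its own choice
(`equalize_areas()`): the face generators fall into orbits of the
icosahedral symmetry group (for GP(3,3): two orbits pinned on symmetry
axes, four free orbits on mirror planes); a quasi-Newton optimizer moves
one representative per free orbit (all others following by symmetry) to
minimize the variance of hexagon solid angles. This reduces a
544-parameter problem to 8 parameters, keeps the polyhedron exactly
icosahedrally symmetric, and drives the hexagon solid-angle spread to
$10^{-6}$ — far inside the ±1% criterion — in under a second. A local
diffusion-style relaxation was tried first and stalls near ±25%, because
in a centroid dual a generator's own cell area is insensitive to its own
position at first order; the orbit parameterization sidesteps this.
Note the published "pentagon ≈ 66% of the largest hexagon" refers to
planar face areas of the solid; equalizing *solid angles* (the quantity
that matters for pixels-per-ommatidium) leaves pentagons at ~92% of a
hexagon's solid angle.

`project_faces()` projects each face boundary radially onto a flat,
cylindrical, or bowl screen and measures the resulting polygon in the
screen's own image chart — the chart in which area is proportional to
projector pixels: physical plane coordinates for the flat screen, the
developed surface for the cylinder (projection distortions neglected, as
in the published evaluation), and the equidistant azimuthal image for the
bowl. `distortion_metrics()` normalizes each face's area per steradian to
the central reference face and measures elongation/width as the extents
along/perpendicular to the radial direction from the screen center,
divided by the source face's own angular extents along the same
directions ("aspect-corrected").

The package asserts the analytic limits rather than the published
rendering-pipeline numbers (whose measurement chain — render, vectorize,
measure — is not reproducible from the text): small flat-screen faces
follow the gnomonic $\sec^3\theta$ magnification to within 2%; cylinder
faces on the equator are undistorted; the bowl's elevation scale (pixels
per degree of elevation) is constant along a meridian by construction,
with its azimuthal distortion growing as $\psi/\sin\psi$ (1.14 at 50°,
1.77 at 100° from the pole); and at matched eccentricity ≥ 40° mean
distortion orders bowl < cylinder < flat. The physical screen area needed
to cover a common field of view orders the same way
(`screen_area_for_fov()`).

## Stimuli

All stimuli are spherical textures generated at a configurable resolution
(default 1°/pixel; discretization places pixel centers at half-degree
offsets, so point probes of nominal luminances are exact only to second
order in the resolution):

* `cylinder_grating()` — a square-wave (or sine) vertical grating lining a
  virtual cylinder from the horizon down by `height` degrees; the period
  must divide 360° for seamless wraparound. The published pairing of
  cylinder height with a diameter/height ratio follows no simple geometric
  identity we could find, so `cylinder_angular_height()` /
  `cylinder_dh_ratio()` provide an advisory conversion (observer at the
  top-rim height of the cylinder) while both parameters remain
  independently settable.
* `moving_edge()` — a luminance step at `start + velocity * t`; bright and
  dark edges are exact complements.
* `dark_bar()` — a wrap-safe dark vertical bar on a bright background.
* `cuboid_interior()` — the panorama of an infinitely tall four-walled
  enclosure with smooth luminance dips into the four vertical edges at 90°
  spacing. Only the central edge luminances (defaults 0.67/0.77) and the
  wall luminance (0.98) are specified by the emulated setup; the falloff
  into an edge is modeled as a raised cosine of configurable half-width
  (default 10°), a smooth, symmetric choice with no free shape parameters.
* `binary_noise()` on a `noise_grid()` — binary white noise, i.i.d.
  Bernoulli(1/2) per cell and frame, 60 Hz; 5° cells over the
  180° × 140° arena field of view give the 36 × 28 grid. Frames derive
  from a master seed through a per-frame counter, so any frame is
  reproducible out of order (enabling lazy and windowed access). The
  counter is passed through a nonlinear mix (two Lehmer rounds and an
  xor-fold) before seeding, because nearby Mersenne-Twister seeds yield
  measurably correlated first draws; with the mix, the empirical
  spatiotemporal autocorrelation of an 8-minute sequence matches the
  binomial sampling bound exactly.

`trial_timeline()` / `trial_frames()` / `schedule_trials()` express the
behavioral trial structure (2 s reference + 6 s stimulation + 6 s post at
60 Hz = 840 frames, with frame-accurate phase boundaries and seeded
randomized condition order).

## Receptive-field estimation

`reverse_correlate()` estimates the spatiotemporal kernel as the sliding
cross-correlation of the contrast-coded stimulus ($0/1 \to -1/+1$) with
the mean-subtracted, frame-integrated response:
$k[\ell, y, x] = \tfrac1N \sum_t s[t-\ell, y, x]\,\tilde r[t]$. The
recoding and mean subtraction make this the standard unbiased linear
kernel estimator for binary noise; the implementation is one matrix
product per lag (zero-padding the response instead of re-slicing the large
frame matrix) and is tested to agree with the naive triple loop to
machine precision.

Derived statistics: `rf_center()` (magnitude-weighted center of mass of
the dominant-lag map, restricted to the above-half-maximum region so
far-field estimation noise cannot bias the centroid); `recenter_rf()`
(every lag's map rotated on the sphere so the center lands at the
distortion-free map origin, resampled at 1°); `rf_stats()` (half-maximum
contour area in solid-angle-weighted square degrees, interpolated FWHM of
azimuth/elevation slices through the peak, the temporal kernel at the
spatial peak, and a noise floor flagged at 3 SD of the far-lag weights —
lags 10–20 by default, a criterion the package defines since none is
published). `kernel_temporal_support()` counts the consecutive
above-floor frames from lag 0.

For a zero-latency sensor the kernel has single-frame support, so
validation measurements evaluate the spatial map at lag 0; time-window
averages (defaults 0–0.1 s and 0.2–0.6 s) are intended for neurons with
extended temporal kernels.

## The synthetic rig

All hardware is replaced by seeded software models
(`photodiode_model()`, `ln_neuron_model()`, `camera_capture()`,
`wingbeat_image()`); every default is documented on the respective help
page and everything is deterministic given a seed.

* The photodiode integrates luminance over a boxcar window or a circular
  Gaussian acceptance profile (solid-angle weighted, so the profile is
  genuinely circular on the sphere), with optional latency and additive
  Gaussian noise.
* The LN neuron weights contrast by a circular Gaussian receptive field
  (FWHM 10° by default), convolves with a biphasic temporal kernel built
  from two alpha-function lobes (negative lobe peaking at 50 ms, weak
  positive rebound near 570 ms), applies a saturating tanh nonlinearity,
  and adds noise. The defaults echo the qualitative filter properties of
  an OFF-center medullary interneuron for demonstration; they are
  synthetic, not a fit to recordings.
* The camera is an ideal Lambertian observer at the screen center: for
  each output direction it reports the luminance of the projector pixel
  illuminating the screen there. An optional multiplicative shading field
  can emulate imperfect brightness uniformity for robustness tests; paint
  reflectance and vignetting are otherwise ignored as optical properties
  that software cannot reproduce.
* The wingbeat-image generator renders a stylized top view (body silhouette
  plus wing-envelope sectors sweeping forward from straight-back), giving
  `wingbeat_amplitudes()` a ground-truthed monotone test signal.

## Behavior analysis

`process_steering()` implements the open-loop chain: resample left/right
wingbeat amplitudes to 50 Hz, low-pass with a symmetric Gaussian FIR
(SD 0.4 s, truncated at ±3 SD and renormalized — the emulated pipeline
states only the Gaussian width), subtract left − right, and subtract the
mean of the 2-s reference period. `optomotor_response()` rectifies a
clockwise/counterclockwise trial pair (sign-flipping the counterclockwise
trace, then averaging — for an exactly antisymmetric pair this reproduces
the common trace exactly) and summarizes the response as the mean over the
6-s window starting 2 s after stimulus onset. Two consequences worth
knowing: the summary window deliberately spans the last 4 s of stimulation
plus the first 2 s post (that is how the emulated protocol defines it),
and the smoothing kernel leaks the stimulus-onset step back into the
baseline window, so a unit step reads as ~0.92 rather than 1.0 — the
pipeline is validated against an independent direct-convolution oracle
rather than against an idealized step response. Where clockwise and
counterclockwise responses differ in magnitude the package averages the
per-direction rectified traces (rather than rectifying the average), one
of two defensible readings of the emulated analysis.

Closed loop: `closed_loop_step()` advances texture yaw by
`gain * steering` deg/s clipped to ±140°/s (the rotation-speed range the
emulated rig allows a fly), wrapping modulo 360°. `simulate_fixation()`
runs a steering policy at the frame rate with zero-order hold and an
optional fixed loop delay (default 0 s; the hardware lag is
rig-specific). `dark_seeking_policy()` is a deliberately simple agent —
steer proportionally toward the darkest azimuth in the frontal ±90° —
sufficient to demonstrate that the 0.67 edges of the cuboid texture
attract more dwell time than the 0.77 edges. `fixation_density()` bins
resampled yaw into a proper density over the circle (default 3.6° bins,
100 bins; unstated in the emulated protocol).

## What the synthetic tests do and do not show

The synthetic rig makes every pipeline testable end to end, at the study's
own problem sizes: 8-minute 60 Hz sessions on the 5° grid for the temporal
(kernel support ≤ 3 frames, peak-lag jitter ≤ ±1 frame) and spatial
(center vs. >50° off-center RF size within 8% after recentering) precision
checks; 5-minute sessions on a 2.8° grid for LN-parameter recovery
(center within one cell, FWHM within one cell of 10°, over 10 seeds; the
azimuth extent is 179.2° = 64 cells, since the cell size must divide the
extent). The sensor noise levels (0.02 additive SD on a drive of SD ~0.1;
neuron noise 0.05) are fixed study conditions chosen to represent clean
photodiode recordings and moderately noisy intracellular data.

These simulations validate the *algorithms* — geometry, remapping,
estimator, statistics — under ideal optics and ideal timing. They do not
emulate light scatter between screen regions, projector gamma and flicker,
paint reflectance, camera optics, tethering artifacts, or real neural
adaptation; agreement here therefore bounds the software's contribution to
error, not the instrument's. Real-fly effect sizes (e.g. the factor ~2
preference for darker edges) are not asserted, only their direction.

## Known limitations

* Only class-I and achiral class-II Goldberg frequencies are supported;
  chiral GP(m,n) with m ≠ n, n > 0 is refused.
* The published distortion factors obtained through the
  render-and-vectorize pipeline (3.3/1.9/5.5 and kin) are not reproduced;
  the package asserts analytic limits and orderings instead.
* The relation between a cylinder's diameter/height ratio and its
  on-screen angular height is advisory (see above).
* `rotate_equirect()` is bilinear; delta-like images are spread by one
  pixel and mass conservation holds only for band-limited content.
* The closed-loop simulator updates at the frame rate with zero-order
  hold; sub-frame latency effects are not modeled.
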