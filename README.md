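# bowlvr

Screen-geometry design and validation tools for projector-based panoramic
visual-stimulation arenas for insects.

Flies and other insects see almost the whole sphere around them, but the
flat and cylindrical displays commonly used to stimulate them cover only a
fraction of that field of view, with brightness and perspective distortions
that grow toward the periphery. A bowl-shaped screen solves this in
hardware: if the bowl profile is chosen so that each ommatidium of the
compound eye always receives the same number of projector pixels, the
displayed image needs no per-frame distortion correction, brightness is
uniform across the field of view, and receptive fields measured anywhere on
the screen are directly comparable.

`bowlvr` implements that computational core, end to end and fully in
software:

* **Screen geometry** — the analytic bowl profile. With the observer at the
  origin and the projector at distance $d_{proj}$, throw ratio
  $r_{throw}$, aspect ratio $r_{aspect}$, $r = r_{throw} r_{aspect}$, the
  profile is the intersection of the ommatidial viewing ray at elevation
  $\alpha$ with the projector ray addressing the same elevation:

  $$X(\alpha) = \frac{d_{proj}\,\alpha}{\alpha - \pi r \tan\alpha}
  \begin{pmatrix}1 \\ \tan\alpha\end{pmatrix},
  \qquad \alpha \in (0^\circ, 180^\circ),$$

  rotated about the optical axis to a 3D surface. Export as SVG (profile)
  and binary STL (surface of revolution) for fabrication.
* **Projection** — precomputed pixel maps from equirectangular spherical
  textures to the projector's equidistant azimuthal image, masks, and
  spherical rotations of textures.
* **Distortion evaluation** — a Goldberg-polyhedron GP(3,3) compound-eye
  model (272 faces: 260 equal-area hexagons, 12 pentagons) projected onto
  flat, cylindrical and bowl screens, with per-face area/elongation/width
  distortion metrics.
* **Stimuli** — cylinder gratings, moving edges, dark bars, a graded-edge
  cuboid interior, and seeded binary white noise with frame-accurate trial
  scheduling.
* **Receptive-field mapping** — sliding reverse correlation of binary noise
  against frame-locked responses, spherical recentering of the estimate,
  and kernel statistics (center, FWHM, half-maximum contour area, temporal
  support).
* **Behavior** — wingbeat-envelope quantification, the optomotor
  trace-processing chain, and closed-loop fixation simulation with
  azimuthal probability densities.
* **Synthetic rig** — seeded software stand-ins for all hardware: a
  photodiode, a linear–nonlinear model neuron, a panoramic camera at the
  observer position, and a top-view wingbeat-image generator. Every
  pipeline is testable without any instrument.

See the methods vignette (`vignettes/bowl-screen-methods.Rmd`) for the
models, assumptions, parameter defaults and design decisions.

## Worked example

Design a bowl for a typical compact projector, build the eye model, and
recover a synthetic neuron's receptive field from five minutes of binary
noise:

```r
library(bowlvr)

pm <- projector_model(d_proj = 100)   # throw 1.4, 16:9, 1280 x 720
pm
#> Projector model
#>   distance observer-projector : 100
#>   throw ratio                 : 1.4
#>   aspect ratio                : 1.77778
#>   r = throw * aspect          : 2.48889
#>   resolution                  : 1280 x 720 px

screen_profile(pm)                    # 15-140 deg elevation by default
#> Bowl screen profile: 200 samples, elevation 15..140 deg
#>   x range [-14.28, 27.14], y range [-23.36, -3.826]
# write_profile_svg(), screen_surface(), write_surface_stl() export for
# fabrication

equalize_areas(goldberg_polyhedron(3, 3))
#> Goldberg polyhedron GP(3,3)
#>   faces: 272 (260 hexagons, 12 pentagons); vertices: 540; edges: 810
#>   hexagon solid-angle spread: -0.00% / +0.00% about the mean

grid <- noise_grid(cell = 5, seed = 1)   # 36 x 28 cells, 60 Hz
stim <- binary_noise(grid, 120)          # 2 min of white noise
neuron <- ln_neuron_model(center = c(12, -25), fwhm = 10, noise_sd = 0.05)
k <- reverse_correlate(stim, neuron_respond(stim, neuron, seed = 1), 12)
k
#> Spatiotemporal RF: 13 lags x 28 x 36 (el x az), 60 Hz
#>   peak |k| = 0.1746 at lag 3 (50 ms), az 12.5, el -22.5 deg

rf_stats(recenter_rf(k, out_res = 1, out_az = c(-30, 30),
                     out_el = c(-30, 30)), baseline_lags = 10:12)
#> RF summary: center (1.2, 0.2) deg, FWHM az 10.7 / el 11.5 deg, half-max area 96 deg^2
#>   polarity OFF, peak 0.1233
```

The kernel peaks at 50 ms with OFF polarity (the neuron's negative lobe),
at the cell nearest the true center (12, −25); after recentering, the
recovered FWHM of ~10–11° matches the model's 10° receptive field to
within one 5° noise cell.

A thin command-line wrapper over the same workflows lives at
`inst/cli/bowlvr.R`:

```sh
Rscript inst/cli/bowlvr.R generate-geometry --config cfg.yaml --out out/
```

with commands `generate-geometry`, `build-maps`, `render-stimulus`,
`estimate-rf`, `evaluate-distortion` and `simulate-closed-loop`; every run
writes a `resolved-config.json` sidecar recording parameters and seed.

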