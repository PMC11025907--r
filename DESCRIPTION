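Package: bowlvr
Title: Bowl-Shaped Screen Geometry and Receptive-Field Mapping for Insect
    Visual Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and validating projector-based panoramic
    visual-stimulation arenas for insects. Derives the bowl-shaped screen
    profile that keeps the ratio of projector pixels per ommatidium constant
    across the visual field, exports the profile and the surface of
    revolution for fabrication (SVG, STL), precomputes equidistant-azimuthal
    pixel maps from equirectangular spherical textures, quantifies
    perspective distortion of a Goldberg-polyhedron compound-eye model on
    flat, cylindrical and bowl-shaped screens, synthesizes standard stimuli
    (gratings, edges, bars, binary white noise), estimates spatiotemporal
    receptive fields by sliding reverse correlation with spherical
    recentering, and analyzes open- and closed-loop tethered-flight
    behavior. A fully synthetic rig (photodiode, linear-nonlinear model
    neuron, panoramic camera, wingbeat-image generator) stands in for all
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
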