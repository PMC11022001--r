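Package: aneufit
Title: Inverse Identification of Aneurysm Wall Hyperelastic Constants from
    Luminal Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale inverse-analysis pipeline for estimating in vivo
    Fung-type hyperelastic material constants (a, b) of an aneurysm wall
    from the luminal-volume change produced by a known intraluminal flow
    stimulus. Includes a synthetic phantom generator emulating
    photon-counting CT segmentation masks, image-domain volumetry (rigid
    overlay, aneurysm delimitation, voxel and mesh volume estimators), a
    reduced-order spherical Fung-membrane forward model, a quadratic
    response-surface inverse engine with acquisition-time ambiguity scan,
    and reporting of the resulting wall stress state.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    lhs,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
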