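Package: hemowss
Title: Wall Shear Stress Mapping in Cerebral Arteries from Simulated Blood Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates laminar blood flow in parametric vessel geometries with
    patient-specific resistance outlet boundary conditions, extracts wall shear
    stress (WSS) from the Cauchy stress at the vessel wall, classifies vessel
    walls into anatomical segments, quadrants and curve sides, registers
    results onto a high-resolution MRI-like voxel grid, and computes regional
    WSS ratio statistics together with the agreement and group-comparison
    tests used in vessel-wall imaging studies. Includes a synthetic vessel,
    phantom and ultrasound-panel generator so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    e1071,
    xml2
Config/testthat/edition: 3
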