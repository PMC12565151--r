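Package: dynffr
Title: Dynamic Coronary FFR from Multi-Phase Vessel Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes fractional flow reserve (FFR) from multi-phase
    (4D) coronary geometry. Provides differential geometry of vessel
    centerlines, biharmonic linear-blend-skinning deformation of vessel
    wall meshes, a synthetic generator of temporally consistent 11-phase
    coronary, left-ventricular and aortic-root sequences, a biphasic
    coronary inlet flow model with contrast-based personalization,
    hemodynamically weighted temporal fusion of phase geometries into one
    effective geometry, cardiac functional metrics (stroke volume,
    regurgitation-corrected cardiac output, Bramwell-Hill pressure
    estimation), Windkessel outlet boundary-condition generation, and a
    reduced-order distributed-resistance network solver that yields
    time-averaged pressures and FFR. Mesh and table formats (STL, OBJ,
    legacy VTK, CSV, JSON, YAML) are read and written in plain text.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
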