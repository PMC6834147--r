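Package: EllipsoidLOD
Title: Ellipsoidal Level-of-Detail Abstraction of Molecular Surfaces
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds residue-restricted hierarchical cluster trees over protein
    atoms using a volume-based distance metric, fits a minimum-volume
    enclosing ellipsoid (MVEE) to every cluster, selects distance-dependent
    level-of-detail display lists, and renders the resulting sphere and
    ellipsoid glyphs with a deterministic CPU ray caster including diffuse
    shading, depth-dependent silhouettes and screen-space ambient occlusion.
    Reads standard PDB files and ships a synthetic molecule generator for
    reproducible experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    png
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
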