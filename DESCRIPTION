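Package: qctfea
Title: Phantomless QCT Densitometry and Voxel-Based Finite Element Analysis of Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates voxelwise bone mineral density (BMD) from computed
    tomography Hounsfield units, either through in-scan calibration phantoms
    or through phantomless regression models that combine the Hounsfield
    value with patient physical factors (body circumference, bone
    cross-sectional area). Maps density to elastic modulus with
    site-specific power laws or a linear bone-volume-fraction rule, builds
    voxel-based hexahedral finite element models of vertebra- and
    femur-like geometries, solves the linear elastic problem under
    compression or sideways-fall loading, and compares density estimates
    and strain energy between calibration routes. Includes a synthetic CT
    generator with known ground truth so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
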