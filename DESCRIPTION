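Package: cryoplan
Title: Simulation and Volumetric Validation of Percutaneous Renal Cryoablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans and validates multi-needle percutaneous cryoablation of
    renal tumors. Time-steps a Pennes bioheat equation on a regular voxel
    grid with phase change handled by an apparent-heat-capacity (enthalpy
    spreading) method, blood perfusion attenuated by the local dead-cell
    fraction, and cryoprobes modelled as fixed-temperature cylinders over
    configurable freeze-thaw protocols. A lethal-isotherm cell-death model
    applied to the per-voxel minimum-temperature history yields the
    simulated ablation zone, which is compared against a reference zone
    with volumetric overlap metrics (Dice similarity coefficient, target
    overlap, positive predictive value), a symmetric mean surface distance,
    and ordinal quality ratings. Ellipsoidal phantom generators make every
    component testable without clinical images; masks are read and written
    as NIfTI volumes and a command-line pipeline covers simulate, validate
    and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
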