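Package: neurochron
Title: Brain-Predicted Age and Amyloid PET Quantification for Down Syndrome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kernel Gaussian-process regression of age on voxelwise grey- and
    white-matter volume maps (brain-predicted age and the brain-PAD statistic),
    with 10-fold cross-validation and permutation significance testing;
    basis-function simplified reference tissue model (SRTM) quantification of
    [11C]-PiB nondisplaceable binding potential from dynamic PET time-activity
    curves with voxelwise CSF partial-volume correction; SD-threshold amyloid
    positivity and regional-abnormality classification; and the association
    models linking brain-PAD, amyloid load and cognition in Down syndrome.
    Includes a synthetic cohort generator that emulates the statistical
    structure these analyses assume, so the whole pipeline is testable without
    access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    RNifti,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'simulate.R'
    'features.R'
    'gpr.R'
    'srtm.R'
    'extract.R'
    'amyloid.R'
    'associations.R'
    'io.R'
    'pipeline.R'
    'neurochron-package.R'
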