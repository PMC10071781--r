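Package: petnorm
Title: MRI-Less Spatial Normalization and SUVR Quantification for Amyloid PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Deformable spatial normalization of amyloid PET brain volumes
    without a structural MRI of the same subject, using a cascade of
    encoder-decoder networks that predict dense displacement fields from an
    affine-registered PET image. Training minimizes a local normalized
    cross-correlation loss between warped MR carriers and a T1-like template
    together with a Dice loss on gray-matter segments; at inference only the
    PET volume is required. The package also provides atlas-based regional
    SUVR (standardized uptake value ratio) quantification with composite
    volumes of interest and a cerebellar gray-matter reference,
    amyloid-positivity classification, method-agreement statistics (ordinary
    least squares regression, ICC(3,1), Bland-Altman), a synthetic 3D brain
    phantom generator with known ground-truth deformations, and an
    end-to-end phantom study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
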