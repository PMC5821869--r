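Package: hepaquant
Title: Optical-Density Phenotyping and Surrogate Necroinflammatory Scoring of Liver Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open pipeline for semi-automated scoring of liver-biopsy
    field-of-view (FOV) images. Converts brightfield RGB images to per-stain
    optical-density maps by colour deconvolution (Beer-Lambert), segments
    nuclei, phenotypes cells by marker optical density (IHC DAB) or
    fluorescence intensity (double-label IF), discriminates ductal from
    non-ductal marker-positive cells with a Fisher linear discriminant,
    detects necrosis, steatotic fat, collagen deposition and inflammatory
    foci, and combines cell densities and area fractions inside portal,
    periportal and lobular processing regions into four surrogate
    necroinflammatory measures that are binned and summed into an
    Ishak-Knodell-style composite score. A synthetic-histology generator
    renders 20x-magnification FOVs with complete ground truth so every
    stage is verifiable without patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellSegmentation, Classification, ImmunoOncology, Visualization
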