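Package: rlraug
Title: Local-Rotation Data Augmentation for Biomedical Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reproducible, label-equivariant data augmentation for microscopy
    and biomedical image datasets. Implements random local rotation (rotating
    a randomly placed circular region in place, which avoids the boundary
    fill artefacts of whole-image rotation) and its central special case,
    together with the traditional augmentation operators: flips, whole-image
    rotation under four boundary fill policies, random crop-resize, colour
    jitter, channel isolation, HSL conversion, Gaussian blur, Sobel edges,
    unsharp sharpening, Gaussian / salt-and-pepper / speckle noise and random
    erasing. Includes dataset-level orchestration (replace or append modes,
    class-balanced subsetting), paired image/mask transforms for
    segmentation, synthetic nuclei fixtures with exact ground-truth masks,
    PNG/TIFF input and output, and a JSON-lines manifest enabling bit-exact
    replay of every generated sample.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
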