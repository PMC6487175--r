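Package: avrefine
Title: Segment-Wise Multiloss Refinement of Retinal Artery/Vein
    Classifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Refines per-pixel artery/vein/background classifications of
    retinal fundus vasculature by a segment-wise majority ("multiloss")
    judgment: the vessel mask is skeletonized, cut into junction-free
    skeleton segments, vessel pixels are assigned to their nearest
    segment, and every segment is relabelled to its majority predicted
    class. Includes the mismatch-ratio weighted segment-level loss, the
    five standard semantic-segmentation performance measures (global and
    mean accuracy, mean and weighted IoU, mean boundary F-score), a
    ground-truth label enhancement pipeline that transfers manual
    annotations onto a segmented vessel tree, a percentile-saturation
    contrast stretch, and a seeded synthetic vasculature generator so the
    whole system is testable without fundus images or a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
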