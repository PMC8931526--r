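Package: siamtrack
Title: Model-Free Siamese Template-Matching Tracking for Animal Behavior Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-object, model-free visual tracking for animal behavior
    videos. A template defined by a single first-frame bounding box is matched
    against a search region in every later frame by cross-correlation of
    handcrafted feature maps, with ROI-aligned template features, suppression
    of visually similar distractors, a cosine-window motion prior, anchor-style
    box-shape candidates, and a softmax-based output confidence. Tracking
    failures can be repaired by injected human corrections (which replace the
    template) or, below a confidence threshold, by an exemplar detector trained
    on the tracker's own confident output. Includes the standard overlap-rate
    and pixel-error evaluation criteria, a seeded synthetic-scene generator
    with exact ground truth for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
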