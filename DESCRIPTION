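Package: radclip
Title: Hierarchical Vision-Language Modeling of Multi-Sequence 3D MRI Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrastive vision-language modeling of multi-sequence
    3D MRI studies. Volumes are tokenized with a vector-quantized autoencoder,
    encoded by a two-level hierarchical vision transformer with register
    tokens, and aligned with itemized radiology report text through a joint
    CLIP and patient sequence-discrimination objective. Includes transfer
    heads for multi-label diagnosis, acuity, referral and age prediction,
    retrieval and neighbor-based evaluation metrics, LIME token attribution
    with lesion-overlap scoring, an equalized-opportunity fairness audit
    suite, and a synthetic phantom-study generator so every component is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
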