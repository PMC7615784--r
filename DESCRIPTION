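Package: dlbcnet
Title: Blood Cell Image Classification with GAN Augmentation and
    Randomized Network Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies white blood cell (leukocyte) microscopy images into
    the four common classes (neutrophil, eosinophil, monocyte, lymphocyte)
    with a four-stage pipeline: per-class generative-adversarial augmentation
    of the training images (BCGAN), feature extraction through a frozen
    convolutional trunk with a fine-tuned fully-connected head, three
    pseudo-inverse-trained randomized neural networks (extreme learning
    machine, random vector functional link, Schmidt network), and a
    majority-voting ensemble (ETRN) with an ELM fallback.  Includes one-vs-rest
    confusion counts, macro-averaged multi-class metrics, cross-run
    aggregation, ROC/AUC, synthetic fixture generators for desk-scale testing,
    and tidy accessors for every fitted object.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
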