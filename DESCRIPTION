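Package: bvmanifold
Title: Manifold Detection and Diffusion Pseudo-Time for Vaginal Microbiome
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the progression of vaginal microbial communities
    from healthy Lactobacillus-dominated states toward bacterial vaginosis
    (BV). Builds a k-nearest-neighbor graph over sample compositions, derives
    a diffusion pseudo-time anchored at clinically defined BV root samples
    (positive Amsel's test and Shannon diversity above 3.5), classifies
    samples into community state types by centroid similarity, projects new
    samples onto the fitted manifold by Bray-Curtis nearest neighbor, and
    runs the downstream analyses: ROC curves for BV indicators with a
    shuffled-label null, per-arm sliding-window taxa profiles, and
    longitudinal menstruation and medication dynamics. Includes a synthetic
    cohort generator with a known latent progression parameter so the whole
    pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
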