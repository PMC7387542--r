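Package: mtdyn
Title: Brownian Dynamics of Microtubule Tips with Curved Protofilaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates the mechanics and chemical kinetics of microtubule
    plus-ends whose protofilaments are intrinsically curved. A compiled
    overdamped Langevin (Brownian dynamics) kernel propagates tubulin
    monomers confined to their protofilament planes, interleaved with a
    kinetic Monte-Carlo layer for stochastic GTP-tubulin addition and
    hydrolysis. Tubulin-tubulin contacts are breakable bonds with
    activation-energy barriers, so the model reproduces force generation
    by shortening tips coupled to a Dam1 ring, pushing against obstacles
    by growing tips, and load-accelerated assembly. Includes the staged
    grid-search calibration of interaction parameters against measured
    growth/shortening rates and stall forces, and shape analysis of
    protofilament traces (curl origin, curl length, curvature, tip
    raggedness, persistence length) applicable to both simulated tips and
    electron-cryotomography derived trace files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
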