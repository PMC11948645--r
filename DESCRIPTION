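Package: gradnorm
Title: Normative Modeling of Functional Connectome Gradient Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the development of the cortical functional
    hierarchy with normative models. Builds principal connectivity gradients
    from functional connectomes via diffusion map embedding with Procrustes
    alignment to a group template, fits sinh-arcsinh (SHASH) normative age
    trajectories by penalized maximum likelihood with P-spline smooths,
    scores individuals as centiles of the normative distribution, summarises
    whole-brain hierarchy maturation as the cosine similarity to the
    age-specific normative gradient, quantifies network segregation with the
    participation coefficient, and tests connectome-mediated group
    differences with subject-level bootstrap mediation. Includes a synthetic
    cohort generator with planted developmental ground truth so every stage
    can be validated against a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
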