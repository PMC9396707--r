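Package: epgkit
Title: Electrical Penetration Graph Analysis of Aphid Feeding Behavior and Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing electrical penetration graph (EPG) recordings
    of aphid probing behavior on host plants, and linking behavior to aphid
    performance. Parses time-stamped waveform annotation files into contiguous
    bout sequences, derives the standard suite of probing-behavior variables
    (bout counts and durations, potential-drop rates, latencies, phloem-phase
    composition) with explicit rules for absent and truncated waveforms,
    computes aphid life-table demography (intrinsic rate of increase and
    population doubling time via the Wyatt-White approximation), and provides
    the accompanying inferential toolkit: Kruskal-Wallis and pairwise
    Mann-Whitney tests with compact letter displays, sequential and
    repeated-measures ANOVA, negative-binomial mixed models with
    overdispersion diagnostics, and a from-scratch sparse partial least
    squares discriminant analysis for contrasting host genotype classes.
    Includes a semi-Markov simulator of EPG recordings and companion
    generators for reproduction counts and leaf condensed-tannin assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
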