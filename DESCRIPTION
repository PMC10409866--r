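Package: ribodecode
Title: Kinetic Modelling and Single-Molecule FRET Analysis of Ribosomal
    Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how mRNA modifications such as
    N6-methyladenosine modulate aminoacyl-tRNA selection on the ribosome.
    Represents the branched decoding pathway (initial binding, codon
    recognition, GTP hydrolysis, accommodation, drop-off, classical/hybrid
    tRNA fluctuations) as a continuous-time Markov chain with exact
    stochastic (Gillespie) simulation and analytic solutions (mean
    first-passage times, absorption probabilities, occupancy time courses,
    multi-codon chaining). Generates realistic two-channel single-molecule
    FRET traces from mechanistic trajectories (camera integration,
    channel noise, donor bleed-through, single-step photobleaching) with
    full ground truth, and implements the matching trace-analysis chain:
    bleed-through correction, FRET computation, quality control,
    Gaussian-emission hidden Markov model idealization, transition
    filtering, dwell-time decay fitting with photobleach and
    observation-window correction, Gaussian-sum FRET histogram fitting,
    mechanistic trace classification, and synchronized contour histograms.
    Also fits ensemble stopped-flow/quench-flow time courses with one- or
    two-exponential models and the associated group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
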