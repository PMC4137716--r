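Package: kcm
Title: Kronecker-Product Mechanistic Codon Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic codon substitution models in which the 61 x 61
    generator over sense codons is assembled as the Kronecker product of
    three symmetric 4 x 4 per-position nucleotide exchangeability matrices,
    combined with codon equilibrium frequencies, a selection multiplier
    (omega, the dN/dS ratio) and a binary multi-hit switch that permits or
    forbids instantaneous double and triple nucleotide substitutions within
    a codon.  Provides Felsenstein-pruning log-likelihoods for codon
    alignments on fixed trees (generic over state space, so the same engine
    fits per-position 4-state GTR models), maximum-likelihood fitting of the
    model family (KCM19x, KCM7x, their single-hit restrictions, a neutral
    variant and the M0 baseline), small-sample AICc model comparison, a
    flux-based corrected omega estimator, and a simulation engine (random
    trees, sequence evolution under arbitrary reversible codon generators,
    and perturbation schemes that add double/triple substitution rates to an
    M0 base matrix).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
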