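Package: ardca
Title: Autoregressive Generative Models of Protein Sequence Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits shallow autoregressive generative models (arDCA) to multiple
    sequence alignments of homologous proteins by exact, per-site regularized
    maximum likelihood. The joint sequence probability is factorized into
    soft-max conditional distributions along a chosen positional order
    (entropic by default), which makes training gradient-exact (no MCMC),
    sampling ancestral, and sequence probabilities exactly normalized.
    Includes sequence reweighting, empirical frequency and connected
    correlation statistics, in-silico deep mutational scanning via
    statistical-energy differences, epistasis-based residue-residue contact
    prediction (zero-sum gauge, Frobenius norm, average product correction),
    Monte-Carlo estimation of family entropy and sequence-space size, a
    profile (independent-site) baseline, principal-component projections,
    log-odds subfamily classification, and synthetic ground-truth fixtures
    with brute-force enumeration oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
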