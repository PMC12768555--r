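Package: pluralinfo
Title: Information-Theoretic Analysis of Gender Conditioning in German
    Plural Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how strongly grammatical gender conditions
    plural-class production in German, at the level of individual speakers.
    Implements plug-in information measures (entropy, conditional entropy,
    mutual information, normalized mutual information, Kullback-Leibler
    divergence) over gender-by-plural-class tables; multinomial hypothesis
    simulators for null, lexicon-level, and monosyllable-mediated gender
    conditioning under fixed-gender and self-assigned-gender designs; a
    simulation-calibrated Bayesian Beta regression of normalized mutual
    information on plural-class entropy, fitted by adaptive-Metropolis MCMC
    and used to compute per-participant Bayes factors and hypothesis
    classifications; a synthetic behavioral-data generator emulating novel
    noun ("wug") elicitation cohorts with mixed production strategies; and
    normalized-Levenshtein orthographic neighborhood statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
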