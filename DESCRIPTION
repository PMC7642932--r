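Package: fufs
Title: Fast and Stable Computation of Fu's Fs from Ewens Sampling Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Overflow-safe computation of the Ewens sampling tail probability
    S'(n, m, theta) -- the probability of observing at least m distinct alleles
    among n sequences given scaled diversity theta -- and the derived Fu's Fs
    neutrality statistic. Provides an exact log-space engine built on the
    Stirling-number recurrence (with an exact big-integer oracle for
    validation), a fast single-evaluation asymptotic estimator based on an
    incomplete-beta main term with a saddle-point first-order correction, an
    aligned-FASTA front end that derives n, the allele count m, and the average
    pairwise difference theta-pi, and a validation harness with seeded accuracy
    sweeps. Batch interfaces are tibble-in/tibble-out.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
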