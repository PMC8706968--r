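Package: crisprpair
Title: Paired Guide-Target CRISPR Amplicon Design, Simulation and Indel Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput profiling of Cas12a editing activity with
    genome-integrated, self-cleaving paired crRNA-target libraries. Designs
    PAM-matched guide-target pairs and 142-nt oligonucleotide layouts, simulates
    amplicon sequencing reads with microhomology-mediated and non-homologous
    end-joining repair outcomes plus realistic background noise, calls indels
    against the 42-nt target window with two-round frame filtering and
    control-differential background subtraction, and aggregates per-pair indel
    frequencies into PAM base-preference summaries, repair-pathway spectra and
    nonparametric group comparisons. Includes Poisson multiplicity-of-infection
    conversions for lentiviral titration planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
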