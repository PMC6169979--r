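Package: dhewscan
Title: Selective Sweep and Adaptive Divergence Screens with Matched Genomic Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene population-genetic screens for recent selective sweeps
    and recurrent adaptive protein divergence in population samples of
    coding sequences. Computes site-frequency-spectrum and haplotype
    neutrality statistics (Watterson's theta, Tajima's D, normalized
    Fay and Wu's H, Ewens-Watterson haplotype homozygosity) with p-values
    from coalescent simulations conditioned on the observed number of
    segregating sites, including the DHEW compound test; lineage-polarized
    McDonald-Kreitman tests with the Direction of Selection coefficient;
    and a focal-versus-matched-control comparison-score framework with
    permutation-based rank-against-null percentiles and explicit
    sweep/divergence calling criteria. Includes a coalescent-based
    synthetic-data generator so the whole pipeline can be exercised and
    calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
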