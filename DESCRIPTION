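Package: saltscreen
Title: Salt-Stress Screening of Crop Varieties from Fast Chlorophyll
    Fluorescence, SSR Diversity and Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative salt-performance screening of crop
    variety panels. Extracts JIP-test parameters (F0, FJ, FM, M0, VJ,
    FV/FM and the performance index PIabs) from fast chlorophyll-a
    fluorescence (OJIP) transients; computes relative medium/low-salinity
    values per growth stage, stage-to-stage reduction factors, and the
    salt performance index SPI = log10(A) + n*log10(B) with data-driven
    marker selection; provides one-way ANOVA with Duncan's multiple range
    test and compact letter displays plus correlation matrices; computes
    SSR diversity statistics (allele frequencies, observed
    heterozygosity, gene diversity, PIC), a Shannon-information analysis
    of molecular variance with chi-square G statistics and permutation P
    values, and the Evanno delta-K statistic; calculates ProtParam-style
    protein physicochemical properties (molecular weight, isoelectric
    point, GRAVY, aliphatic and instability indices); quantifies relative
    gene expression by the 2^-ddCt method; and simulates every input
    format with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
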