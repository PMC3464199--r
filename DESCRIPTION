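Package: tetradgc
Title: Meiotic Gene Conversion Analysis from Fluorescent Pollen Tetrads
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring meiotic gene conversion with fluorescent
    tagged lines (FTLs) in Arabidopsis thaliana pollen tetrads. Estimates
    per-locus and pooled conversion frequencies from 3:1 tetrad counts
    (with the doubling adjustment for unscorable 1:3 events), compares
    loci with the G-test of independence, regresses conversion frequency
    on SNP position, classifies conversions as crossover- or
    non-crossover-associated from three-color tetrads, reconciles observed
    frequencies with genome-wide double-strand-break counts to estimate
    conversion tract lengths, and provides a forward simulator of meiotic
    DSB repair (DSBR/SDSA with heteroduplex tracts and mismatch repair)
    that generates synthetic tetrad data with ground-truth event logs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
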