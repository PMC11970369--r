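Package: phytospace
Title: Estimating the Size of the Plant Chemical Space from Mass Spectrometry and Literature Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the size of the phytochemical space from
    tandem mass spectrometry (MS2) data and literature compound-species
    tables. Canonicalizes structures into stereochemistry-free InChIKey
    blocks with Murcko scaffolds and monoisotopic masses, harmonizes
    species names across taxonomic nomenclatures, filters MS2 spectra by
    peak count and adduct, clusters spectra by spectral-entropy similarity
    within precursor ppm windows using connected components, builds
    cumulative unique-structure saturation curves under several annotation
    strategies, and projects total chemical richness with power-law models
    validated on holdout suffixes. Includes a synthetic plant-metabolome
    generator with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
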