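Package: surfannot
Title: Annotation of Cyclic Surfactin Lipopeptides from LC-ESI-MS/MS Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies cyclic surfactin-family lipopeptide homologs from
    centroided LC-ESI-MS/MS peak lists. Detects CH2-spaced homolog series,
    sodium-adduct partners and water-loss peaks in MS1 data; reconstructs
    the acyl-peptide sequence from MS2 spectra by spectrum-graph ladder
    extraction (b-type prefix and y-type suffix ion chains), infers the
    beta-hydroxy fatty-acyl chain length from the lipid anchor mass, and
    classifies annotations against configurable family templates. Also
    implements the companion bioassay statistics (inhibition-zone residual
    rate, minimum inhibitory concentration calling, zone-diameter grading)
    and a synthetic-data generator producing surfactin-like spectra and
    bioassay tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
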