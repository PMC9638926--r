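Package: nucleoidCCF
Title: Modelling Chromosome Fragmentation and DNA Release from the Bacterial Nucleoid
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates double-strand-break placement on a circular bacterial
    chromosome under four mechanistic scenarios (random, scaffold-targeted,
    envelope-targeted, replication-fork collapse), predicts pulsed-field gel
    and origin/terminus probe observables, computes the fraction of DNA
    released from a loop-and-scaffold nucleoid model (by Monte Carlo and by a
    closed form), and inverts observed release fractions into estimates of the
    scaffold attachment density, including a first-order kinetic decomposition
    of ATP-dependent, transcription-driven release. A synthetic-data generator
    emulates gel-quantified release observation tables so the full inference
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
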