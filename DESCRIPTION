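Package: iesim
Title: Simulation and Analysis of Internal Eliminated Sequence Excision
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study programmed DNA elimination in ciliates such as
    Paramecium tetraurelia. Simulates paired germline ("MAC+IES") and somatic
    ("MAC") reference genomes in which short, TA-bounded Internal Eliminated
    Sequences (IESs) are precisely excised during somatic development, together
    with sequencing reads from configurable mixtures of retained, correctly
    excised and erroneously excised molecules. Provides a deterministic
    split-read junction mapper, per-boundary IES retention scores (IRS) with
    Fisher-exact significance calls against a control sample, a taxonomy of
    TA-to-TA excision errors (partial internal/external, internal, external,
    overlapping) with de novo error accounting by parental subtraction, and
    summary analyses of size periodicity, size-peak biases, boundary-shift
    spectra and end-motif composition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
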