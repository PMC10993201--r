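Package: imsOligo
Title: Detection, Deconvolution and Assignment of Peptide Oligomers in
    Ion Mobility Mass Spectrometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing noncovalent peptide oligomers in ion
    mobility mass spectrometry (IM-MS) experiments. Computes elemental
    compositions, masses and isotopic envelopes of capped peptides and
    their n-mers; enumerates candidate oligomer ions and groups them into
    isobaric [kn]^(kz+) families; infers oligomer order and charge from
    observed m/z and isotopologue spacing; extracts ion mobility spectra
    (EIMs) and mobility-gated mass spectra from feature tables; assigns
    precursor oligomer mobilities from the coincidence of fragment-channel
    EIM apexes in quadrupole-selection experiments, with classification of
    residual peaks as interface-fragmentation artifacts; calibrates TIMS
    (inverse reduced mobility) and TWIMS (drift time) axes to collision
    cross sections and compares CCS values across platforms; and simulates
    complete IM-MS datasets with known ground truth, including two-locus
    in-instrument fragmentation, so every analysis step is testable
    without instrument files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
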