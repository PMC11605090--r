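Package: eadlipid
Title: Lipid Structure Annotation from Electron-Activated Dissociation MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A decision-tree engine for in-depth lipid structure annotation
    from electron-activated dissociation (EAD) tandem mass spectra.
    Enumerates candidate structures (sn-, hydroxyl- and double-bond
    positional isomers) within a curated lipid chemical space, generates
    in-silico charge-remote-fragmentation (CRF) spectra with a rule-based
    intensity model, evaluates subclass/chain/position diagnostic ions under
    an instrument noise model, and ranks candidates by a composite
    annotation score combining diagnostic detection with reverse dot
    product spectral fitting. Also provides spectral entropy and modified
    dot product similarity metrics, molecular spectral networking, and
    m/z + collision-cross-section matching of mass spectrometry imaging
    features, plus generators for ground-truthed synthetic spectra and
    imaging phantoms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mzR
Config/testthat/edition: 3
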