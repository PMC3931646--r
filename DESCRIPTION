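Package: cngchan
Title: Electrophysiological and Structural Analysis of Cone CNG Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cyclic nucleotide-gated (CNG) channel
    recordings and structural models. Provides Hill-equation fitting of
    ligand dose-response relations from inside-out patch-clamp sweeps,
    agonist-efficacy and blocker metrics with homomeric/heteromeric patch
    classification, estimation of reversal potentials from averaged voltage
    ramps, inversion of reversal-potential shifts through the
    divalent-extended Goldman-Hodgkin-Katz (Lewis) equation to relative
    Ca2+/Na+ permeabilities with single-ion activity models, charged-residue
    salt-bridge distance mapping on multi-frame coordinate ensembles,
    Tri-Asp sequence-motif scanning, and a synthetic-data generator that
    emulates the corresponding recording protocols with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    bio3d,
    Biostrings,
    igraph,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'bundle.R'
    'bridgemap.R'
    'channelParams.R'
    'cngchan-package.R'
    'constants.R'
    'sweep.R'
    'doseresponse.R'
    'solutions.R'
    'ghk.R'
    'hill.R'
    'motif-fasta.R'
    'motif.R'
    'protocols.R'
    'synthgen.R'
    'pipeline.R'
    'ramps.R'
    'sweep-io.R'
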