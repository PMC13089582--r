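Package: rhodopress
Title: Property-Partitioned Codon Models and Pressure Thermodynamics for
    Rhodopsin Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting physicochemical-property-driven selection in
    protein-coding genes and for quantifying pressure responses of protein
    ensembles. Implements a codon substitution model that splits
    nonsynonymous changes into radical and conservative classes by amino-acid
    compressibility (branch and site mixture variants, with AIC/LRT model
    comparison and a radical/conservative partition sweep), marginal
    ancestral codon reconstruction with a convergence screen for
    compressibility-decreasing substitutions, and trajectory-level
    thermodynamic estimators (isothermal compressibility from volume
    fluctuations, per-residue RMSF, quasiharmonic entropy, and a
    pressure free-energy decomposition). A synthetic-data module generates
    codon alignments evolved under the model and molecular ensembles with
    analytically known observables for estimator validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
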