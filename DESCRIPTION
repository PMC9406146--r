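Package: aggremelt
Title: Aggregation Thermodynamics of Coarse-Grained Peptide Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of peptide association in multi-chain coarse-grained
    (Calpha-trace) replica-exchange ensembles. Computes sequence descriptors
    (GRAVY hydropathy, Henderson-Hasselbalch net charge, simulation box side
    from molar concentration), identifies oligomers from a Calpha contact
    criterion under periodic boundaries, assigns beta/alpha/coil states from
    virtual-bond geometry and a hydrogen-bond proxy, reweights the
    multi-temperature ensemble with binless WHAM to obtain melting profiles
    and heat capacity, extracts melting midpoints and convergence diagnostics,
    and clusters conformations with Ward's method including per-residue RMSF.
    Includes a synthetic replica-exchange generator over an exactly enumerable
    chain-partition Hamiltonian for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
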