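Package: kinn
Title: Kinetically Interpretable Neural Networks for Sequence-Dependent
    Enzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and searches kinetically interpretable neural
    networks (KINNs): sparse sequence-to-rate models whose parameters are,
    by construction, the rate constants of a linear kinetic scheme, with
    steady states computed through a static King-Altman diagram layer.
    Includes exact kinetic machinery (rate matrices, King-Altman diagram
    enumeration, steady states, relaxation dynamics, characteristic
    polynomial identities for the Cas9 cleavage cycle), deterministic
    encodings of gRNA-target alignments, an Arrhenius-rate simulator that
    generates ground-truth sequence-to-cleavage-rate benchmarks, a
    probabilistic model-building genetic algorithm over KINN architectures,
    and a transfer-learning stage that wraps a frozen pretrained KINN with
    a trainable sequence-context backbone to predict binary in vivo
    cleavage outcomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
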