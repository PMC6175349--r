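Package: chirasieve
Title: Screening of Nanoporous Membrane Models for Chiral Separation by
    Molecular Sieving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening membrane-based chiral separation by
    molecular sieving. Builds finite nanoporous graphene and graphdiyne
    pore models with hydrogen passivation and nitrogen rim substitution,
    measures pore diameters, evaluates rigid bimolecular complexes of
    chiral template molecules with a Lennard-Jones plus Coulomb
    interaction model, computes size and energy differences between
    same-chirality and opposite-chirality complexes, performs rigid
    constrained energy scans of molecules propagating through pores with
    cubic-spline interpolation and extrema classification, and locates
    minimum-energy pathways with a nudged elastic band optimizer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
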