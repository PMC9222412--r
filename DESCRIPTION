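Package: gagentropy
Title: Conformational Entropy of Glycosaminoglycan Chains from Glycosidic Torsion Angles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for molecular-dynamics trajectories of
    linear glycosaminoglycan (GAG) chains such as hyaluronan (HA) and
    chondroitin-6-sulfate (CS6). Builds the alternating NG disaccharide-repeat
    chain topology, extracts the glycosidic torsion angles (Phi, Psi) of the
    1->4 and 1->3 linkages from multi-model PDB trajectories or angle tables,
    pools them into Ramachandran-type bivariate histograms, and computes the
    conformational Shannon entropy S = -R0 * sum p_ij log(p_ij) together with
    modal (Phi, Psi) conformations and per-ion summaries over independent
    realizations. A synthetic-data module generates angle time series from von
    Mises mixtures and embeds prescribed torsions into 3D coordinates, so every
    stage is testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
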