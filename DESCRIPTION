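Package: rvimap
Title: Reentry Vulnerability Analysis of Cardiac Electroanatomical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of triangulated electroanatomical maps of the cardiac
    surface: automatic activation (LAT) and repolarization (LRT) annotation of
    unipolar electrograms by the steepest-slope (Wyatt) rules,
    activation-recovery intervals, edge-based spatial gradients,
    triangulation-based conduction velocity with admissibility filtering,
    functional conduction-block area, the reentry vulnerability index (RVI)
    with its 10th-percentile global summary, Bazett QT correction and
    before/after map comparison. Includes a synthetic map and electrogram
    generator (eikonal wavefronts on triangulated meshes, slow-conduction
    patches, repolarization heterogeneity, annotation noise) that provides
    ground truth for every stage, and readers/writers for an open map
    interchange format plus VTK/PLY export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
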