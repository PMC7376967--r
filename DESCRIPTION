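Package: iacsim
Title: Quasi-Static Simulation of Intracranial AC Stimulation Fields and
    Neurogenesis Cell-Count Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling intracranial alternating-current stimulation
    (iACS) in the mouse head and for analysing neurogenesis cell counts.
    Builds a layered voxelized mouse-head phantom (dura, CSF, gray and white
    matter, lateral ventricles with a subventricular-zone shell, hippocampi),
    places epidural screw-electrode montages in stereotaxic coordinates,
    solves the quasi-electrostatic current-flow problem div(sigma grad phi)=0
    with a finite-volume discretization and a conjugate-gradient solver, and
    summarizes the resulting electric field and current density over regions
    of interest, including montage ranking and a lesion-safety check. A
    companion statistics module reconstructs one-way ANOVA, Tukey HSD (with
    an internally implemented studentized-range distribution) and fold
    changes from per-animal counts or from printed group summaries
    (mean, SEM, n), and a synthetic-data module generates hierarchical
    section/view cell-count datasets and toy phantoms with analytic field
    solutions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
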