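Package: mcmflow
Title: Metabolic Connectivity Mapping for Simultaneous PET/MR Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and group-level analysis of learning-induced
    coupling between glucose metabolism and functional connectivity from
    simultaneous PET/MR imaging. Provides functional PET quantification of
    the cerebral metabolic rate of glucose via Patlak graphical analysis,
    arterial spin labeling cerebral blood flow quantification, BOLD
    preprocessing for connectivity (framewise displacement, scrubbing,
    nuisance regression, bandpass filtering), multimodal conjunction of
    task-activation maps, whole-brain metabolic connectivity mapping (MCM),
    repeated-measures group statistics with permutation cluster inference,
    behavioral summaries, and a voxel-removal perturbation analysis. A
    synthetic-study generator with known ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
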