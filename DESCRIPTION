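Package: stimnet
Title: Network Embedding of Brain-Stimulation Sites and Memory Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating the structural and functional network embedding
    of intracranial brain-stimulation sites to stimulation-related episodic
    memory change. Implements ChaCo-style (Change in Connectivity) streamline
    intersection profiling of spherical stimulation masks against a normative
    tractogram, seed-based functional connectivity from task time series,
    list-level free-recall memory-change statistics, parcelwise association
    mapping with max-statistic permutation family-wise error correction,
    Dice-based structure-function congruence over a dual threshold grid with
    Benjamini-Hochberg FDR, and partial least squares path modeling with
    bootstrap moderation and mediation inference. A synthetic-data module
    generates atlases, tractograms, task time series and stimulation cohorts
    with planted effect structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
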