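Package: gazereplay
Title: Sequential Scanpath Replay Analysis for Episodic Memory Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the sequential replay of eye-movement
    scanpaths between the encoding and recall of visual stimuli in
    blank-screen ("looking at nothing") paradigms. Scanpaths are simplified
    into sequences of saccadic vectors, temporally aligned by a shortest
    path through a vector-shape cost matrix, and scored for similarity over
    five spatio-temporal dimensions (fixation position and duration;
    saccade shape, direction and length). Per-trial replay scores are
    derived against a within-participant cross-image baseline, spatial
    reinstatement is summarised over area-of-interest grids, and
    crossed-random-effects mixed models with likelihood-ratio backward
    selection test whether replay predicts memory quality. A synthetic
    experiment generator with known ground truth supports validation of
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
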