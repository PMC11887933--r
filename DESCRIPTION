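Package: uncrowdr
Title: Grouping and Segmentation Model of Visual Uncrowding with Rating Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates vernier-offset discrimination under crowding and
    uncrowding for eight flanker/Pacman stimulus configurations. Stimuli are
    rasterized from declarative geometry in visual degrees; a rate-based
    orientation-channel dynamic produces time-resolved boundary activity;
    collinear (bipole-style) grouping links assemble a boundary graph on which
    top-down selection signals spread, shifting grouped contours into a
    separate segmentation layer; a left/right vernier template decoder reads
    the default layer out into a scalar evidence score. Also provides an exact
    Wilcoxon signed-rank test (full enumeration with midranks, discard or
    Pratt zero handling), Likert rating summaries, a within-person consistency
    metric, and a seeded ordinal rating generator emulating a
    15-participant, 6-condition, 2-side, 2-repetition design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
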