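Package: flydam
Title: Locomotor Activity, Sleep and Circadian Rhythm Analysis for
    Drosophila Activity Monitor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads, validates and writes TriKinetics Drosophila Activity
    Monitor (DAM) system monitor files, converts legacy per-channel files,
    and analyses the resulting beam-crossing count series: automatic
    dead-fly exclusion by a daily activity threshold, locomotor activity
    summaries and profiles with light/dark (LD) and constant-darkness (DD)
    regime splitting, sleep scoring by the five-minute inactivity rule,
    activity and sleep bout statistics, chi-square (Sokolove-Bushell)
    periodogram estimation of the free-running circadian period with
    rhythmicity filtering, and single- or double-plotted actogram matrices.
    Includes a seeded generator of synthetic monitor files with per-fly
    ground truth, so the whole pipeline can be exercised without hardware,
    plus a config-driven analysis runner that exports CSV tables and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
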