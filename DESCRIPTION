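Package: dexeeg
Title: Quantifying Sedative Drug Effects on Neonatal Cortical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bedside-oriented analysis pipeline for quantifying the effect of
    a sedative drug (such as dexmedetomidine) on newborn cortical activity from
    four-channel neonatal EEG. Implements range-EEG (rEEG, per-window
    peak-to-peak amplitude) and an Activation Synchrony Index (ASI, surrogate-
    normalised mutual information between burst envelopes), automated artifact
    detection, long-term and short-term (baseline versus post-drug delta)
    trend designs around a drug-administration timestamp, and the nonparametric
    cohort statistics layer (Spearman, Wilcoxon rank sum, Kruskal-Wallis).
    Includes a synthetic generator of discontinuous neonatal-like EEG with
    known ground truth, and minimal European Data Format (EDF/EDF+) reading
    and writing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
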