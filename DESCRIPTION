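Package: seqtrace
Title: Memory-Trace Models of Stimulus-Sequence Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether animals represent stimulus sequences
    faithfully or as unstructured collections of decaying memory traces.
    Implements a duration-dependent trace model (saturating encoding,
    exponential decay, noisy trace-based choice), schedulers that reproduce
    three behavioural paradigms (delayed matching-to-sample, two-choice
    sequence discrimination with correction trials, and a four-alternative
    matching task with interleaved two-stimulus probe trials), associative
    learning agents that generate behaviour on them, exact binomial and
    Pearson chi-squared tests on choice counts, and maximum-likelihood
    fitting of retention curves and trace-model probe predictions with
    profile confidence intervals and parameter-recovery diagnostics.
    Includes a synthetic-study generator producing complete trial logs with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
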