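Package: tnrtools
Title: Transient Noise Reduction for Hearing-Aid Speech Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reducing brief intense transient sounds (door slams,
    clattering cutlery) in speech, as used in hearing-aid research. Implements
    a recurrent-network (LSTM) estimator of the ideal ratio mask operating on
    gammatone time-frequency features, a multi-channel transient reduction
    (MCTR) comparison algorithm, speech-to-transient-ratio controlled mixing
    with synthetic speech and transient generators, the STOI and NCM intrusive
    intelligibility metrics, and paired-comparison preference-test machinery
    with exact Wilcoxon signed-rank statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
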