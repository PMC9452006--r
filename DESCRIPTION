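Package: mortseq
Title: Neural Generation of Causal Sequences of Death from Hospital
    Discharge Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translating a decedent's last-hospitalization
    diagnosis codes (ICD-9 or ICD-10) into an ordered cause-of-death code
    sequence (underlying cause first) with encoder-decoder sequence models.
    Provides LSTM, bidirectional-RNN and transformer architectures trained
    by teacher forcing on a built-in reverse-mode autodiff engine; greedy
    and beam-search decoding with an optional medical domain-knowledge
    constraint derived from an ACME-style causal decision table; a
    validity-check corpus filter; a 2-gram modified BLEU metric with
    clipped precisions, harmonic weights and a brevity penalty, plus
    entire-sequence, individual-code and underlying-cause accuracies; and
    attention-based identification of death-related diagnosis codes. A
    synthetic mortality-corpus generator with a planted causal graph makes
    the full pipeline testable without access to restricted vital
    statistics data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
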