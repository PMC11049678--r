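Package: tisk
Title: Time-Invariant String Kernel Model of Spoken Word Recognition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for the TISK (time-invariant string kernel)
    interactive-activation model of spoken word recognition, extended with
    positive and negative lexical feedback from words to sublexical N-phone
    nodes. Words are coded as graded ordered open diphones (a string kernel
    over phoneme pairs), so the lexical network needs no time-specific
    duplicated word nodes. Includes phoneme-inventory and lexicon handling,
    a synthetic lexicon generator with controllable competitor structure,
    recognition-time and lexical-competition metrics, and scriptable
    harnesses for five classic simulation paradigms: competitor time course,
    the Ganong effect, retroactive right-context disambiguation, phoneme
    restoration under noise versus silence, and graceful degradation under
    increasing input noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
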