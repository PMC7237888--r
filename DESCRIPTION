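Package: ashm
Title: Clonal Dynamics and Immune Surveillance of Hypersecreting Endocrine Mutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models autoimmune surveillance of hypersecreting mutants (ASHM) in
    endocrine tissues: a clone-competition ODE model of tissue-size feedback
    with cooperative, ratiometric immune killing; invasion-fitness and
    evolutionary-stable-strategy analysis of the killing function; regime
    classification (mutant takeover, functional surveillance, autoimmunity);
    back-of-envelope mutant-burden and cross-organ adenoma-risk calculators; a
    fitness-cost proxy index for secreted factors; and exact CDR3beta matching
    of autoreactive T cell receptors against subject-shared public repertoires,
    with seeded synthetic-data generators for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
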