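Package: tcgsim
Title: Sender-Receiver Agents for the Tacit Communication Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of non-verbal communication in the Tacit Communication
    Game, a two-player cooperative grid game in which a Sender's movement
    trajectory must convey the Receiver's hidden goal location. Provides the
    board geometry and goal-configuration machinery, exhaustive bounded
    enumeration of candidate messages, three recursive Theory-of-Mind Sender
    and Receiver agents (shortest-path, fewest-unique-state, and marked-detour
    message selection with the matching elimination decoders), an
    expectancy-violation Sender that plans step by step from Shannon surprise
    under movement and goal-distance priors with finite-horizon policy-tree
    lookahead and softmax action selection, a Pass-by/Enter-exit/Wiggly message
    classifier, and a seeded session harness that produces message-type
    frequency and decoding-accuracy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
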