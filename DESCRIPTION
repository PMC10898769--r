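Package: amity
Title: Agent-Based Simulation of Friendship and Enmity Formation in Small
    Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates how friendship and enmity networks emerge in small
    closed groups such as school classes. Agents hold a private opinion and
    project a public one; pairwise link weights on an adaptive signed
    network co-evolve with the opinions, with periodic rewiring that
    replaces links turned hostile by fresh acquaintances. A second stage
    turns a finished simulation into directed friend/foe nomination
    (mention) networks under two sociometric survey protocols: a
    fixed-quota protocol in which every respondent names exactly q friends
    and q foes, and a personal-threshold protocol calibrated on an ensemble
    of runs. Summary statistics (mention in-degree distributions,
    reciprocity, clustering contrast) support comparison of simulated and
    empirical mention networks supplied as edge-list CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
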