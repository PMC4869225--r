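Package: agendareach
Title: Agenda-Setting Reach Analysis for Social Media Keyword Streams
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring agenda-setting influence in keyword-tracked
    social media streams. Implements tweet reach metrics (deliveries, retweet
    impressions, total impressions, amplification multipliers), the filter
    cascades used to isolate influential tweets and contributors, account-type
    classification with Cohen's kappa reliability checking, per-type influence
    share tables with rank scaling, source-by-target retweet-interaction
    matrices with network edge export, and max-normalized daily mention-trend
    comparison across channels with spike detection and matching. A seeded
    synthetic cascade generator with known ground truth makes every pipeline
    stage testable without live platform access.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
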