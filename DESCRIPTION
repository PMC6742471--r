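Package: dogcea
Title: Cost-Effectiveness Modelling of Certified Assistance Dogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing certified
    assistance dogs (physical service dogs and diabetes alert dogs) with
    regular companion dogs. A one-year decision tree (suitability tests,
    training, final exam) feeds a nine-year Markov cohort model over five
    health states; discounted costs and quality-adjusted life years are
    accumulated per arm and compared as incremental cost-effectiveness
    ratios with dominance classification. Includes probabilistic
    sensitivity analysis with gamma-distributed costs and beta-distributed
    utility weights, cost-effectiveness acceptability curves, eleven
    built-in deterministic scenario analyses, packaged parameter fixtures,
    and a synthetic-data generator for owner life tables, dog survival
    schedules and individual-level pseudo-study samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
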