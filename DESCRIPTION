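Package: dairysim
Title: Dietary Dairy Substitution and Fortification Scenario Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating the effect of dairy substitution and
    fortification scenarios on the dietary nutrient adequacy of preschool
    children. Computes per-child mean daily nutrient intakes from multi-day
    diet diaries and supplement records, converts dairy items to liquid milk
    equivalents by protein ratio, classifies inadequacy and surplus against
    configurable dietary reference intake (EAR/AI/fiber-density/AMDR) rules,
    and simulates volume-matched substitution and top-up-to-recommendation
    scenarios with soymilk, cow's milk or formulated milk powder. Includes
    SPSS-convention nonparametric statistics (Wilcoxon signed-rank, McNemar,
    Kruskal-Wallis, Mann-Whitney), quartile and percentage reporting
    conventions, table renderers, and a seeded synthetic diet-survey cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
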