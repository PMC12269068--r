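Package: snomcd
Title: Steric NOM-CD Surface Complexation Modelling of Glyphosate-Humic
    Acid Competition on Goethite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tableau-based multicomponent chemical equilibrium solver with
    an extended-Stern three-plane (CD-MUSIC) electrostatic sub-model for
    goethite surfaces, the NOM-CD representation of adsorbed natural
    organic matter as a charged surface component, and its steric
    extension in which a zero-charged component S0 blocks singly
    coordinated surface sites for bulky adsorbates such as glyphosate.
    Includes batch isotherm simulation, synthetic competitive-adsorption
    dataset generation, and least-squares estimation of the maximum
    steric site density from adsorption data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
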