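Package: seglethal
Title: Transmission Genetics Under Gamete Lethality for Rice Linkage Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models transmission ratio distortion caused by gamete lethality in
    rice breeding populations, as arises when the semidwarfing gene d60 and the
    gametic lethal gene gal are combined. Computes surviving-gamete and zygote
    genotype distributions for arbitrary phased parents under two-point
    recombination, performs chi-square segregation tests against theoretical or
    model-derived class ratios, estimates recombination fractions between the
    large-grain locus GW2 and d60 by recessive-class counting and by maximum
    likelihood, and simulates F2 and backcross breeding schemes with marker
    panels and noisy grain-area and culm-length phenotypes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
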