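Package: evophase
Title: Genetic-Algorithm-Enhanced Direct Phasing for Protein Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ab initio recovery of crystallographic phases from diffraction
    amplitudes alone, by a population of independent dual-space electron
    density reconstructions (hybrid input-output solvent feedback, histogram
    matching, solvent flattening) that co-evolve through a genetic algorithm
    with roulette-wheel selection, multi-segment crossover, mutation, elite
    preservation and similarity-based fitness sharing. Includes space-group
    aware origin/enantiomer alignment of density maps, optional rotational
    non-crystallographic symmetry averaging, a synthetic toy-crystal
    generator for fully self-contained testing, and readers/writers for
    structure-factor mmCIF and CCP4/MRC map formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
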