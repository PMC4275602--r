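Package: strwoe
Title: Weight of Evidence for STR Profiles Under Alternative Population
    Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Likelihood-ratio weight-of-evidence calculations for one- and
    two-contributor short tandem repeat (STR) profiles, with coancestry
    (Fst) adjustment of allele probabilities via the Balding-Nichols
    sampling formula and a size-bias count correction for the alleles of
    the queried contributor.  Implements the single-database heuristic
    policy (database of the queried contributor with Fst = 0.03) alongside
    alternative database-assignment policies, simulation of genotypes and
    crime-scene profiles under Hardy-Weinberg and linkage equilibria
    (including Dirichlet-perturbed subpopulation sampling), generation of
    synthetic families of related allele-frequency databases, and a
    simulation study quantifying how often the heuristic policy is
    conservative relative to the alternatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
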