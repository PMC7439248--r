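Package: canonsmi
Title: Rigorous SMILES Canonicalization via Ring and Distance Atom Invariants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses molecular graphs from SMILES and generates a unique
    canonical SMILES for each molecule. Symmetry classes of atoms are
    perceived with local atomic invariants, a prime-product ring invariant
    built from per-bond smallest-ring sizes, and a weighted distance-shell
    invariant, refined by an extended-connectivity algorithm that uses
    powered primes with bond-order exponents to avoid rank leveling and
    swapping. Remaining ties on ring atoms are broken exhaustively and the
    lexicographically minimal depth-first SMILES over all resulting complete
    partitions is selected, so the output is provably independent of the
    input atom ordering. Tetrahedral chirality is carried through parsing,
    class perception and generation. Includes a command-line interface,
    brute-force automorphism-orbit oracles and seeded graph generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
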