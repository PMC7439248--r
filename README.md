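# canonsmi

Rigorous canonical SMILES for molecular graphs, in R.

A chemical database wants one string per compound: if two SMILES spellings of
the same molecule canonicalize to different strings, substructure and
duplicate searches silently fail. Classical extended-connectivity
("Morgan/CANON") canonicalizers are *incomplete*: they assume that atoms with
equal invariant values are symmetry-equivalent, which is false for a family
of highly regular graphs, so their output can depend on the input atom
numbering. `canonsmi` implements a complete two-stage procedure:

1. **Graph-invariant atom partitioning.** Each atom gets a 13-digit local
   invariant vector (degree, atomic number, H count, charge sign, |charge|,
   connectivity, valence, mass, chirality digit), a **prime-product ring
   invariant** (for each bond, the size *s* of the smallest ring through it
   is found by BFS with the bond removed; the atom's invariant is the
   product of the *s*-th primes over its bonds, e.g. 5·5·13 = 325 for two
   3-ring bonds and one 6-ring bond), and a **distance-shell invariant**
   Σ_d count(d)·10^(d−1) where count(d) is the number of atoms at topological
   distance d. Atoms are ranked by these keys and refined by a modified
   CANON iteration: score = prime(rank)^8 · Π_neighbours prime(rank)^e(bond),
   with bond-order exponents e. The exact powered-prime products (computed in
   multi-limb integer arithmetic — never hashed) provably avoid the rank
   leveling/swapping of the original algorithm.
2. **Canonical code by automorphism permutation.** Any class still holding
   two or more ring atoms is split exhaustively (double all ranks, decrement
   one tied atom, re-refine, branch over every member). Each resulting
   complete partition drives a three-pass depth-first SMILES generation
   (tree/chord marking; emission with deterministic ring-closure digits;
   parity correction of `@`/`@@` against the written neighbour order), and
   the bytewise-minimal string is the canonical SMILES — provably identical
   for every relabeling of the input, even when stage 1 under-partitions.

Tetrahedral stereochemistry is carried throughout, including molecules with
only relative (dependent) chirality and no true stereocentres.

## Worked example

```r
library(canonsmi)

canonical_smiles("OCC")$smiles
#> [1] "CCO"

# relative stereochemistry: two traversals, lexicographic minimum wins
canonical_smiles("C[C@H]1CC[C@H](N)CC1")
#> $smiles
#> [1] "C[C@@H]1CC[C@@H](N)CC1"
#> $traversal_count
#> [1] 2
#> $n_classes
#> [1] 6

# cubane: one symmetry class, 48 traversals (= |Aut|), one unique string
canonical_smiles("C12C3C4C1C5C2C3C45")$traversal_count
#> [1] 48

# the invariants behind the ranks
invariant_table(normalize_molecule(parse_smiles("CC1CO1")))
#>   atom      vector13 ring_invariant distance_invariant initial_rank
#> 1    1 1006300440000              1                 21            1
#> 2    2 3006100440000             25                  3            4
#> 3    3 2006200440000             25                 12            2
#> 4    4 2008000220000             25                 12            3
```

The `traversal_count` is the number of complete partitions generated by
tiebreaking; when the perceived classes are exact it equals the order of the
automorphism group of the molecular graph (24 for adamantane, 48 for
cubane). The 13-digit `vector13` reads degree, atomic number (3), hydrogens,
charge sign, |charge|, connectivity, valence, mass (3), chirality.

A command-line interface is installed under `inst/scripts/canonsmi`:

```sh
echo "OCC" | Rscript inst/scripts/canonsmi --traversals
# CCO	1
```

with flags `--classes`, `--traversals`, `--explain` (per-atom invariant
dump), `--strict`, `--power`, `--base`, `--seed`.

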