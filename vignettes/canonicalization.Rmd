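---
title: "Symmetry perception and rigorous SMILES canonicalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry perception and rigorous SMILES canonicalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canonsmi)
```

## The problem

A canonical SMILES is a single string chosen deterministically among all the
SMILES spellings of one molecule, so that string equality is molecule
identity. Producing one requires two logically distinct steps. First,
*graph-invariant atom partitioning*: group atoms into candidate symmetry
classes using label-independent invariants. Second, *canonical code
generation by automorphism permutation*: because no known polynomial
invariant separates non-automorphic atoms on every graph, the candidate
classes must be treated as approximate, every completion of the partition
must be enumerated, and the extremal code selected. Skipping the second step
makes a canonicalizer fail silently on highly regular graphs; `canonsmi`
implements both.

## Atomic invariants

**Local vector (13 digits).** Degree, atomic number (3 digits), attached
hydrogens, charge sign ('1' only for negative), absolute charge,
connectivity (degree + H), valence (bond-order sum + H), mass (3 digits,
'000' if unspecified), chirality digit. The degree leads so that, after
ascending sorting, terminal atoms receive the lowest ranks and are preferred
as traversal roots. All characters are digits, so the string compares like
the concatenated integer.

**Ring invariant.** Every bond is assigned the size of the smallest ring
through it: a BFS from one endpoint to the other in the graph with the bond
deleted gives the shortest alternative path, one edge shorter than the ring.
The atom's ring invariant is the product over its bonds of the *s*-th prime
for ring size *s* (factor 1 for acyclic bonds). By unique factorization the
product is unambiguous — unlike a sum, it cannot collide across different
ring-size multisets: an atom with three 3-ring bonds gets 5³ = 125, one with
two 3-ring bonds and a 6-ring bond gets 5²·13 = 325.

**Distance invariant.** A BFS from each atom counts the atoms in every
distance shell d; the invariant is Σ_d count(d)·base^(d−1) with base 10 by
default, so the decimal digits, read right to left, are the shell counts,
and the number of digits is the NOON (the atom's eccentricity). The
exponent is d−1, anchored by the 24-atom fullerene cage whose two classes
evaluate to 25,763 and 35,663 with NOON 5 under that convention. Shell
counts ≥ 10 produce digit carries; carries weaken but never corrupt the
invariant because the comparison key is the exact integer, and `base` can be
set to the atom count for carry-free behaviour.

**Chirality invariant.** `@`/`@@` symbols are order-dependent, so they are
translated against the symmetry classes computed *without* chirality: digit
0 for no parity or when two neighbours share a class; otherwise the count of
`@` when the written neighbour classes are an even permutation of ascending
order, else 3 minus it. The implicit-H placeholder sits immediately after
the preceding atom in the written order and ranks below every atom class.
After assignment the whole ranking pipeline is re-run once — no fixpoint
iteration, since the achiral classes are already stable.

## Refinement

Initial ranks sort atoms ascending by (13-digit vector, ring invariant,
distance invariant). Refinement then iterates

    score(atom) = prime(rank)^power · Π_neighbours prime(rank_prev(n))^e(bond)

re-ranking the scores ascending to consecutive integers, until the class
count stops growing or equals the atom count. Three numerical decisions
matter:

* **power = 8** by default. A plain product of neighbour primes can level
  two previously distinct ranks (the transposition ambiguity of products in
  small rings); squaring the atom's own prime fixes 3-membered rings but not
  all cases; since chemical degrees never exceed 6, the eighth power is
  always sufficient, and 8 = 2³ costs three squarings. `power` is exposed
  because the hand-worked 2-methyloxirane example (scores 28 / 1470 / 315 /
  525) uses power 2.
* **Bond-order exponents** e(single) = 1, e(aromatic) = 2, e(double) = 3,
  e(triple) = 4. Feeding bond orders into the scores is what separates
  classes in non-aromatic annulenes that an order-blind refinement merges.
  Aromatic bonds have no integer order; the map above preserves the natural
  ordering single < aromatic < double < triple with integers so arithmetic
  stays exact. The map is configurable.
* **Exact arithmetic.** Scores are products of powered primes and grow far
  beyond 2^53; they are computed in multi-limb integer arithmetic (C++
  core). Hashing or floating-point rounding could merge distinct scores,
  which is precisely the bug class the powered primes eliminate, so no
  modular reduction is ever applied. The refiner additionally asserts, every
  iteration, that the new partition refines the previous one, and aborts if
  a merge is ever observed.

Ranking after scoring is global and ascending; this reproduces all worked
examples, and the per-cell comparator variant mentioned in the literature is
deliberately not implemented as a second code path.

## Tiebreaking and generation

If refined classes still contain two or more *ring* atoms, the class with
the maximal rank is selected, and for each member atom in turn all ranks are
doubled, that atom's rank is decremented, the partition re-refined, and the
procedure recursed. Each leaf is a partition whose ring atoms hold unique
ranks. Tiebreaking is restricted to ring atoms: residual ties between
acyclic atoms can only be symmetric subtrees, which emit identical
substrings whichever is visited first (they are resolved by input index for
determinism). Leaves reached along different branch paths may be identical;
they are deduplicated before string generation, while the reported traversal
count keeps the leaf multiplicity — that convention matches the benchmark
counts (16 for the bicyclic cage, 24 for adamantane, 48 for cubane, 28 for
the Petersen G(7,2) skeleton), which equal the automorphism group order
exactly when the perceived classes are exact, and exceed it otherwise.

Each leaf partition drives a three-pass generation: pass 1 walks the graph
depth-first from the rank-1 atom, branching toward lower ranks, and marks
the non-tree (chord) bonds; pass 2 emits atoms, branches, bond symbols and
ring-closure digits (lowest free digit, reused after closure, `%nn` beyond
9, digits at an atom ordered by partner rank); pass 3 compares each chiral
atom's output neighbour order against its written input order and keeps the
parity symbol on an even permutation, inverts it on an odd one. The
comparison is against the *input* order, not the canonical ranks, because
molecules with only relative chirality have all chirality invariants 0 yet
still carry meaningful parities. The canonical SMILES is the bytewise
minimal string over all leaves; for relative-stereo molecules the two
traversals genuinely differ (`C[C@H]1CC[C@H](N)CC1` vs
`C[C@@H]1CC[C@@H](N)CC1`) and the minimum rule picks the latter.

Disconnected inputs are canonicalized per component and joined with `.` in
bytewise-sorted order.

## Supported dialect and valence model

Organic-subset and bracket atoms, isotopes, charges, explicit H counts,
single/double/triple/aromatic bonds, branches, ring closures including
`%nn`, and tetrahedral `@`/`@@`. Directional bonds, wildcards and reaction
notation are rejected with a position-reporting parse error. Implicit
hydrogens follow the default valences B 3, C 4, N 3, O 2, P 3/5, S 2/4/6,
halogens 1. Aromatic systems written in lowercase are trusted and
kekulized (backtracking perfect matching over the atoms that require a
double bond) so that H counts and the valence digit are well defined;
Kekulé-written simple rings of size 5–7 whose atoms are sp²-capable and
whose π count satisfies 4n+2 are perceived as aromatic. This perception is
a deliberately minimal ruleset: fused aromatic systems beyond their
individual smallest rings are not re-perceived, and cis/trans double-bond
stereochemistry is out of scope.

## Validation strategy

The test surface is self-contained: all reference structures are embedded
SMILES (`fixture_corpus()`), and graph families are generated in code —
cycles, theta graphs, prisms, generalized Petersen graphs, seeded
edge-swap-randomized connected k-regular graphs (k ≤ 4, emitted as
all-carbon skeletons so parsing is exercised too), and chains of N
para-linked cyclohexanes with distinct caps, whose automorphism group is
exactly the 2^N ring mirrors. Two brute-force oracles, independent of the
pipeline, provide ground truth on small graphs: exhaustive
automorphism-orbit search and isomorphism testing over label-preserving
vertex maps (practical to ~24 atoms with degree/label pruning).

Property suites assert: label-invariance of every invariant; bit-identical
canonical SMILES over 100 random relabelings of every fixture (relabelings
are produced by the package's own emitter under random rank permutations,
then re-parsed); class count equal to the brute-force orbit count on all
generated graphs up to 10 vertices; the 2^N traversal law for N = 1..4; the
ring-invariant factorization round trip; and that no refinement iteration
ever merges ranks. Problem sizes (graphs ≤ 14 vertices, 100 relabelings per
fixture) were chosen as representative desk-scale checks; the documented
counterexamples are asserted *as* limitations.

## Known limitations

* The invariant stage under-partitions some non-planar regular graphs: the
  generalized Petersen G(7,2) skeleton collapses to one class and a
  24-ring polyether cage with trivial automorphism group to three. The
  exhaustive tiebreaking stage still guarantees a unique canonical string —
  at the cost of extra traversals (28 for G(7,2)).
* Worst-case traversal count is exponential in the number of disjoint
  symmetric ring systems (the 2^N law); this mirrors the complexity of
  graph automorphism partitioning and is intrinsic to completeness.
* Parity symbols on degenerate stereocentres (two constitutionally
  identical substituents) are emitted as written rather than stripped;
  semantically meaningless parities can therefore survive canonicalization.
* Extended stereo (allenes, square-planar and higher), cis/trans double
  bonds, and isotope-driven chirality beyond explicit parity symbols are
  not modelled.
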