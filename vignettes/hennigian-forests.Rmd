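---
title: "Hennigian forests and the Average Consensus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hennigian forests and the Average Consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hennigforest)
```

## The model

`hennigforest` analyses polarized binary data without ever optimizing
character-state changes on a tree. The premise is the symmetry between a
binary character and a rooted branching diagram: with state 0 declared
plesiomorphic a priori, the character `ABCDE/00011` *is* the rooted tree
`ABC(DE)` — its only group is the clade of taxa carrying the apomorphic
state 1. A matrix is therefore a forest of such one-clade trees (a
*Hennigian forest*: every group in every tree is apomorphy-based), and the
phylogeny is estimated from the forest by the Average Consensus supertree
method:

* every edge of every tree is given length one;
* for each taxon pair, the patristic (path-length) distance is averaged
  over the trees in which the pair co-occurs, all trees weighted equally;
* a tree is fitted to the averaged table by least squares, the *score*
  being the minimized sum of squared deviations itself, unnormalized, so
  an exactly additive table scores 0.

The interesting consequence — demonstrated by the bundled `fig2_matrix()`
fixture and asserted by the test-suite — is that a clade may be present in
the fitted tree although *no input tree contains it*: three characters
supporting the conflicting pairs (B,C), (B,D), (C,D) average to a table
that is exactly additive on ((O,A),(B,C,D)), so (B,C,D) is recovered with
score 0 despite the absence of any direct character support. Group support
here is relational, not character-based.

## Forest construction choices

**Three renderings.** Each character is rendered as `additional` (basal
polytomy, `(A,B,C,(D,E))`), `no_poly` (nested below the outgroup,
`(A,(B,C,(D,E)))`, which presumes outgroup polarity and errors if the
character scores the outgroup apomorphic), and `with_poly` (like
`additional`, but uninformative characters become complete polytomies).
Informative characters in the `with_poly` forest use the basal-polytomy
form; the source material specifies only that this file "contains
polytomies", and the basal-polytomy form adds no unsupported group.

**Uninformative characters.** A binary character is uninformative when
fewer than two scored taxa carry either state. All-ones columns are
classified uninformative by the same logic (the "clade" is the entire
taxon set, which no rooted tree can express as a proper group) and are
polytomies in `with_poly`.

**Missing data.** Two readings of `?` are implemented: `prune` (default)
drops the unscored taxa from that character's tree; `expand` emits one
tree per completion of the `?` cells (2^m trees). `prune` is the default
because it keeps one tree per character and matches the practice of
discarding ambiguous-outgroup characters up front in the genomic
recoding; the choice is surfaced in every API and logged in the pipeline
manifest. Under `expand`, completions that come out uninformative drop
out of `additional`/`no_poly` (so the 2^m count is observed in
`with_poly`, where every completion is rendered). A character whose
*outgroup* cell is `?` is allowed in `no_poly` with the outgroup assumed
plesiomorphic — consistent with the polarity declaration that defines the
method.

**Averaging over co-occurrence.** Under `prune`, taxa can be absent from
individual trees; each pair is averaged over the trees containing both,
and a pair co-occurring nowhere is an error naming the pair. Coverage
counts are kept on the table.

## Fitting choices

**Criterion.** Default is unweighted OLS. WLS uses `w_ij = d_ij^(-P')`
computed from the *observed* averaged distances (Fitch–Margoliash-style;
`P' = 7` is the conventional strong weighting), with zero distances under
`P' > 0` an error. BME scores a binary topology by Pauplin's closed form
`sum 2^(1 - t_ij) d_ij`. Branch lengths are obtained by solving the
normal equations of the pair-by-edge path-indicator system; a rooted
binary input is unrooted first, since a degree-2 root makes its two
incident edges indistinguishable on leaf paths (singular system).

**Negative branch lengths.** Default `allow` reports the unconstrained
solution; `clamp_zero` truncates negatives and rescores; and
`constrain_nonneg` runs an active-set nonnegative solve. The printed
reference scores that would pin one convention were not reproducible
offline, so the unconstrained solve — the mathematically plain reading of
"least squares" — stays the default.

**Search.** Exhaustive enumeration of all (2n-5)!! unrooted binary
topologies up to 8 taxa (exact, authoritative for the worked examples);
beyond that an NJ start with NNI hill-climbing. All topologies within
`tie_tolerance = 1e-9` of the optimum are reported, rooted a posteriori
on the outgroup's pendant edge, and summarized by strict consensus.

**NJ / UPGMA.** NJ is the agglomerative alternative the supertree
literature offers and is consistent on additive tables; UPGMA is included
as the phenetic contrast — on additive but non-clock tables it can join a
wrong cherry that NJ and least squares do not (tested explicitly).

## Parsimony verification

The scorer exists to check the pipeline against conventional results, not
to replace a parsimony program. Lengths are computed by Sankoff dynamic
programming with 0/1 costs (Fitch, unordered) or linear costs (Wagner,
ordered); `?` contributes no constraint. Ensemble indices use
`CI = sum(m_c)/L` and `RI = (sum(g_c) - L)/(sum(g_c) - sum(m_c))` with
`m_c` the minimum conceivable steps and `g_c` the steps on the star tree
(for a binary character, `min(#0, #1)` among scored taxa); constants
contribute `m_c = 0`, RI is undefined (NA) when its denominator
vanishes. The search is exhaustive up to 9 taxa and random-addition +
NNI beyond — TBR is deliberately not implemented, as every in-scope
matrix is small. Counts of co-optimal trees are not comparable across
programs (zero-length-branch collapsing differs); only lengths and
indices are asserted.

## Recoders

`dna_presence_absence` emits, per alignment column and per unambiguous
base observed in it, one binary character (1 = has that base, 0 = has a
different unambiguous base, `?` = gap/ambiguity, mirroring
gaps-as-missing parsimony practice). With an outgroup: columns with an
ambiguous outgroup cell are discarded first, and only characters scoring
the outgroup 0 are kept — making state 1 apomorphic by construction.
Characters observed only in the outgroup are generated and then
filtered, which is equivalent to never generating them. The naming
scheme `s<site>=<base>` is this package's convention.

`additive_binary` maps an ordered state k of a character with maximum
state m to k ones followed by m - k zeros, which provably preserves
parsimony length (Wagner on the original equals Fitch on the recoding;
verified by brute force over topologies in the tests).

## Synthetic data: what it emulates, what it does not

The generators state a small, fixed world:

* `random_rooted_tree(n, seed)` — uniform labeled rooted binary
  topologies via sequential random attachment; unit edges.
* `matrix_from_tree` — the perfect (homoplasy-free) binary matrix: one
  character per internal non-root clade. Defaults follow the worked
  examples' scale: the round-trip property is exercised at n = 5-8 over
  20 seeds, sizes at which exhaustive search is exact or NJ+NNI is
  provably consistent (the tables are additive).
* `perturb_matrix(m, rate, seed)` — independent 1-to-0 reversals; rates
  are chosen per test, since the reference examples fix specific reversal
  patterns rather than a rate.
* `homoplasy_free_dna(tree, k, seed)` — k private substitution sites per
  edge; MP length equals the substitution count with CI = RI = 1 by
  construction, and its presence/absence recoding exactly doubles the MP
  length (each substitution toggles two binary characters), halving back
  under outgroup-zero filtering.

What a green test on this world does **not** establish: behaviour under
homoplasy beyond simple reversals, alignment error, rate heterogeneity,
or data at genomic scale (thousands of trees); no substitution model is
simulated. The real-data analyses of the source material are outside
desk scale and are deliberately not reproduced; their qualitative claim
(clade recovery after removing every tree containing it) is covered by
the `fig2_matrix()` property.

## Numerical conventions

* Scores are raw weighted sums of squares; exact fits print as ~1e-30,
  asserted as 0 at 1e-9.
* Co-optimality ties at 1e-9; NJ tie-breaks follow the deterministic
  implementation in `ape::nj`.
* Distance tables are written with 10 significant digits and round-trip
  at 1e-9.
* Degenerate inputs error early with the offending taxon/character/pair
  named: empty forests, never-co-occurring pairs, apomorphic outgroups in
  `no_poly`, all-missing characters, labels containing Newick
  metacharacters (no auto-quoting in the strict dialect).
* All randomness flows from explicit integer seeds; reruns are
  byte-identical.

## Known limitations

* Exhaustive search is factorial; the `exhaustive_limit = 8` default is a
  hard practical ceiling, and the NNI climb beyond it is a local search.
* The `no_poly` forest silently drops characters that conflict with the
  declared polarity when built in bulk (`build_forests`); building the
  single character directly (`character_to_tree`) errors instead, which
  is the contract-checking route.
* WLS weights derive from observed averaged distances, not iteratively
  from fitted ones.
* The parsimony heuristic is adequate for verification at tens of taxa,
  not for serious MP searches.
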