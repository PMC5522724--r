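# hennigforest

Matrix-free cladistics in R: rewrite a binary character matrix as a forest of
rooted trees (a *Hennigian forest*) and estimate the phylogeny from the
forest's Average Consensus distance table — never optimizing character-state
changes on a tree at all.

## The idea

In a polarized binary matrix (state `0` plesiomorphic by prior declaration,
state `1` apomorphic), every character *is* a rooted tree: the character
`ABCDE/00011` is the tree `ABC(DE)`, whose single clade `(D,E)` is exactly the
taxa carrying the apomorphic state. Rewriting each informative character this
way turns the matrix into a forest of "Hennigian" trees — trees in which every
group is supported by an apomorphy. The forest, not the matrix, is then the
subject of analysis:

1. **Forest** (`build_forests`): one tree per informative character, in three
   renderings — complete polytomies for uninformative characters
   (`with_poly`), outgroup-nested `(O,(rest,(clade)))` (`no_poly`), and basal
   polytomy `(rest,(clade))` (`additional`, the default input for analysis).
2. **Average Consensus** (`average_consensus_table`): on each tree every edge
   gets length 1, and for each taxon pair the path length (patristic
   distance) is averaged over the trees in which the pair co-occurs, with
   equal tree weights:
   `d_ij = mean_t  (number of edges between i and j in tree t)`.
3. **Tree estimation** (`search_best_tree`): the supertree minimizing the
   least-squares deviation `S = sum_{i<j} w_ij (d_ij − p_ij)^2` between the
   averaged distances `d_ij` and the tree's implied patristic distances
   `p_ij` (OLS, `w_ij = 1`; WLS, `w_ij = d_ij^(−P')`; alternatively balanced
   minimum evolution via Pauplin's `sum 2^(1−t_ij) d_ij`, NJ, or UPGMA).
   Exhaustive enumeration up to 8 taxa, NJ + NNI hill-climbing beyond.

The striking property this pipeline exhibits — and the package's canonical
fixture demonstrates — is that a clade can be recovered even though **no
single input tree (character) contains it**: relational evidence survives
averaging even when direct character support is absent (e.g. erased by
reversals).

Supporting modules: presence/absence recoding of DNA alignments with
outgroup-zero filtering (`dna_presence_absence`), additive binary recoding of
ordered multistate characters (`additive_binary`), artificial all-zero
outgroups (`add_allzero_outgroup`), a Fitch/Wagner parsimony scorer with
ensemble CI/RI (`tree_length`, `ci_ri`, `mp_search`) for verification, and
seeded generators for tree-derived matrices, reversal perturbations and
homoplasy-free DNA (`matrix_from_tree`, `perturb_matrix`,
`homoplasy_free_dna`).

## Worked example

Five taxa `O, A, B, C, D` (outgroup `O`; `O` and `A` all-plesiomorphic) and
three mutually conflicting characters supporting the pairs `(B,C)`, `(B,D)`,
`(C,D)`:

```r
library(hennigforest)
m <- fig2_matrix()
fb <- build_forests(m)
sapply(fb$additional, ape::write.tree)
#> "(O:1,A:1,D:1,(B:1,C:1):1);" "(O:1,A:1,C:1,(B:1,D:1):1);" "(O:1,A:1,B:1,(C:1,D:1):1);"

tab <- average_consensus_table(fb$additional)
tab$d["O", "A"]; tab$d["B", "C"]
#> 2
#> 2.666667        # = 8/3; every pair except (O,A) averages to 8/3

rep <- run_pipeline(m)
rep
#> Hennigian-forest pipeline
#>   trees in forest : 3
#>   criterion       : ols
#>   best score      : 3.5498741e-30
#>   co-optimal trees: 3
#>   strict consensus: (((D,B,C)1,A)1,O)1;
```

The averaged table is exactly additive on `((O,A),(B,C,D))`, so the three
resolutions of `(B,C,D)` all fit with score 0 and their strict consensus is
`(O,(A,(B,C,D)))` — clade `(B,C,D)` is recovered although none of the three
input trees contains it. Parsimony verification on the same matrix:

```r
mp_search(m)
#> parsimony_result: length=5 CI=0.6 RI=0.3333 (9 minimal trees)
```

## Command line

```sh
Rscript exec/hennig forest matrix.phy --outgroup O       # three forest files
Rscript exec/hennig avcon Additional_matrix.nwk --out tab.phy
Rscript exec/hennig lstree tab.phy --root O --all-ties
Rscript exec/hennig pipeline matrix.phy --outgroup O
Rscript exec/hennig parsimony matrix.phy --search
Rscript exec/hennig simulate --taxa 6 --seed 3 --dna 1 --out sim.phy
```

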