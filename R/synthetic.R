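#' Deterministic synthetic fixtures
#'
#' Generators used by the test-suite and by users wanting controlled
#' inputs: random rooted trees, perfect (tree-derived) binary matrices,
#' reversal perturbations, and homoplasy-free DNA alignments. Everything is
#' reproducible from an integer seed.
#'
#' @name synthetic-fixtures
NULL

# grow a uniformly random rooted binary topology over `labels` by Remy-style
# insertion: each new leaf pairs with a uniformly chosen existing subtree
# (any node, including the root), using the current RNG state
.grow_random_tree <- function(labels) {
  subtrees <- function(t) {
    if (!is.list(t)) return(list(t))
    c(list(t), subtrees(t[[1]]), subtrees(t[[2]]))
  }
  insert_at <- function(t, target, leaf) {
    if (identical(t, target)) return(list(t, leaf))
    if (!is.list(t)) return(t)
    list(insert_at(t[[1]], target, leaf), insert_at(t[[2]], target, leaf))
  }
  tr <- if (stats::runif(1) < 0.5) list(labels[1], labels[2]) else
    list(labels[2], labels[1])
  for (i in seq_along(labels)[-(1:2)]) {
    ss <- subtrees(tr)
    pick <- ss[[sample.int(length(ss), 1)]]
    tr <- insert_at(tr, pick, labels[i])
  }
  ser <- function(t) if (!is.list(t)) t else
    paste0("(", ser(t[[1]]), ",", ser(t[[2]]), ")")
  tree_from_newick(ser(tr))
}

#' Random rooted binary tree
#'
#' Uniform over labeled rooted binary topologies, by sequential random
#' attachment (each new leaf joins a uniformly chosen subtree, including
#' the whole tree, which creates a new root).
#'
#' @param n number of leaves (at least 3).
#' @param seed integer seed.
#' @param labels taxon labels; default `t1..tn`.
#' @return a rooted binary `phylo` with unit edge lengths.
#' @export
random_rooted_tree <- function(n, seed, labels = paste0("t", seq_len(n))) {
  if (n < 3) stop("need at least 3 taxa")
  stopifnot(length(labels) == n)
  set.seed(seed)
  .grow_random_tree(labels)
}

#' Perfect binary matrix of a rooted tree
#'
#' The inverse of matrix representation with parsimony: one binary
#' character per internal non-root clade, scoring membership (1) in the
#' clade. Analysing this matrix through the full pipeline recovers the
#' generating tree with least-squares score 0.
#'
#' @param tree a rooted `phylo`.
#' @param outgroup optional taxon set as the matrix outgroup (it must lie
#'   outside every encoded clade, e.g. a root-adjacent leaf).
#' @return a binary [character_matrix()]; a star tree yields a 0-character
#'   matrix with a warning.
#' @export
matrix_from_tree <- function(tree, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- tree$tip.label
  clades <- .clades_of(tree)[-1]  # drop the root (all taxa)
  if (length(clades) == 0) {
    warning("star tree: no internal clades, empty matrix")
    cells <- matrix(character(0), nrow = length(taxa), ncol = 0)
    rownames(cells) <- taxa
    return(character_matrix(cells, alphabet = "binary", outgroup = outgroup))
  }
  cells <- vapply(clades, function(cl) ifelse(taxa %in% cl, "1", "0"),
                  character(length(taxa)))
  cells <- matrix(cells, nrow = length(taxa),
                  dimnames = list(taxa, paste0("c", seq_along(clades))))
  character_matrix(cells, alphabet = "binary", outgroup = outgroup)
}

#' Perturb a binary matrix with random reversals
#'
#' Each apomorphic cell (state 1) is independently reverted to 0 with the
#' given probability — the minimal model of the reversal-bearing examples:
#' support for a clade is erased from individual characters while sibling
#' structure persists elsewhere in the matrix.
#'
#' @param matrix binary [character_matrix()].
#' @param reversal_rate flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the perturbed matrix; attribute `"flips"` is a data frame
#'   logging the flipped (taxon, character) cells.
#' @export
perturb_matrix <- function(matrix, reversal_rate, seed) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (reversal_rate < 0 || reversal_rate > 1) stop("rate must be in [0,1]")
  set.seed(seed)
  cells <- matrix$cells
  ones <- which(cells == "1", arr.ind = TRUE)
  flip <- if (nrow(ones) > 0) stats::runif(nrow(ones)) < reversal_rate
          else logical(0)
  cells[ones[flip, , drop = FALSE]] <- "0"
  out <- character_matrix(cells, alphabet = matrix$alphabet,
                          outgroup = matrix$outgroup)
  attr(out, "flips") <- data.frame(
    taxon = rownames(cells)[ones[flip, 1]],
    character = ones[flip, 2])
  out
}

#' Homoplasy-free DNA alignment simulated on a tree
#'
#' Assigns each edge of the rooted tree its own private substitution sites:
#' every site changes exactly once on the whole tree, so the matrix has MP
#' length equal to the number of substitutions with CI = RI = 1. When an
#' outgroup leaf is named, edges on the root-to-outgroup path carry no
#' sites, leaving the outgroup with the ancestral base everywhere — the
#' setting in which outgroup-zero filtering of the presence/absence
#' recoding keeps exactly one binary character per site.
#'
#' @param tree rooted `phylo`.
#' @param sites_per_edge sites assigned to each eligible edge (at least 1).
#' @param seed integer seed.
#' @param outgroup optional leaf label whose root path stays
#'   substitution-free.
#' @return a DNA [character_matrix()]; attribute `"n_substitutions"` gives
#'   the total substitution count (= MP length of the matrix).
#' @export
homoplasy_free_dna <- function(tree, sites_per_edge = 1, seed = 1,
                               outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (sites_per_edge < 1) stop("sites_per_edge must be >= 1")
  set.seed(seed)
  taxa <- tree$tip.label
  nt <- length(taxa)
  bases <- c("A", "C", "G", "T")
  skip <- rep(FALSE, nrow(tree$edge))
  if (!is.null(outgroup)) {
    if (!outgroup %in% taxa) stop("outgroup not in tree")
    node <- match(outgroup, taxa)
    while (TRUE) {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0) break
      skip[e] <- TRUE
      node <- tree$edge[e, 1]
    }
  }
  edges <- which(!skip)
  # leaves below each edge
  below <- matrix(FALSE, nt + tree$Nnode, nt)
  for (i in seq_len(nt)) below[i, i] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge)))
    below[po$edge[k, 1], ] <- below[po$edge[k, 1], ] | below[po$edge[k, 2], ]
  cols <- list()
  for (e in edges) {
    members <- below[tree$edge[e, 2], ]
    for (s in seq_len(sites_per_edge)) {
      anc <- sample(bases, 1)
      der <- sample(setdiff(bases, anc), 1)
      cols[[length(cols) + 1L]] <- ifelse(members, der, anc)
    }
  }
  cells <- do.call(cbind, cols)
  rownames(cells) <- taxa
  colnames(cells) <- paste0("s", seq_len(ncol(cells)))
  out <- character_matrix(cells, alphabet = "dna", outgroup = outgroup)
  attr(out, "n_substitutions") <- length(cols)
  out
}

#' The in-text worked-example matrix (three conflicting characters)
#'
#' Five taxa `O, A, B, C, D` with `O` (outgroup) and `A` all-plesiomorphic
#' and three mutually conflicting binary characters supporting the pairs
#' `(B,C)`, `(B,D)` and `(C,D)`. No single character supports the clade
#' `(B,C,D)`, yet the average consensus of the corresponding Hennigian
#' forest recovers it at least-squares score 0 — the package's canonical
#' demonstration fixture.
#'
#' @return a binary [character_matrix()] with outgroup `"O"`.
#' @export
fig2_matrix <- function() {
  cells <- rbind(O = c("0", "0", "0"),
                 A = c("0", "0", "0"),
                 B = c("1", "1", "0"),
                 C = c("1", "0", "1"),
                 D = c("0", "1", "1"))
  colnames(cells) <- c("BC", "BD", "CD")
  character_matrix(cells, alphabet = "binary", outgroup = "O")
}
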