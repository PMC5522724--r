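#' Parsimony length of a matrix on a tree
#'
#' Minimal number of character-state changes, summed over characters:
#' Fitch counting for unordered characters and Wagner (linear-cost Sankoff)
#' counting for ordered ones. `?` (and, for DNA, gaps/ambiguities) carry no
#' constraint. Leaves of the tree not scored in the matrix are treated as
#' all-missing; matrix taxa absent from the tree are an error.
#'
#' @param tree a `phylo` (rooted or not; length is root-invariant).
#' @param matrix a [character_matrix()].
#' @param ordered integer vector of 1-based character indices scored with
#'   linear (ordered) costs; all others are unordered.
#' @return integer total length.
#' @export
tree_length <- function(tree, matrix, ordered = integer(0)) {
  stopifnot(inherits(tree, "phylo"), inherits(matrix, "character_matrix"))
  taxa <- rownames(matrix$cells)
  if (!all(taxa %in% tree$tip.label))
    stop("matrix taxa missing from tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  total <- 0L
  for (j in seq_len(ncol(matrix$cells)))
    total <- total + .char_steps(tree, matrix$cells[, j], taxa,
                                 ordered = j %in% ordered,
                                 alphabet = matrix$alphabet)
  total
}

# state labels observed/possible for one character
.char_states <- function(states, alphabet, ordered) {
  if (alphabet == "dna") return(c("A", "C", "G", "T"))
  obs <- suppressWarnings(as.integer(states[states != "?"]))
  if (length(obs) == 0) return(character(0))
  if (ordered) as.character(0:max(obs)) else as.character(sort(unique(obs)))
}

# Sankoff DP: linear cost if ordered, 0/1 cost otherwise
.char_steps <- function(tree, states, taxa, ordered, alphabet) {
  if (alphabet == "dna") {
    states <- toupper(states)
    states[!states %in% c("A", "C", "G", "T")] <- "?"
  }
  st <- .char_states(states, alphabet, ordered)
  k <- length(st)
  if (k <= 1) return(0L)
  C <- if (ordered) abs(outer(as.integer(st), as.integer(st), "-"))
       else 1 - diag(k)
  nt <- length(tree$tip.label)
  cost <- matrix(Inf, nt + tree$Nnode, k)
  for (i in seq_len(nt)) {
    s <- states[match(tree$tip.label[i], taxa)]
    if (is.na(s) || s == "?") cost[i, ] <- 0
    else cost[i, match(s, st)] <- 0
  }
  po <- ape::reorder.phylo(tree, "postorder")
  parents <- unique(po$edge[, 1])
  init <- setdiff(parents, integer(0))
  cost[init, ] <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    # min over child state of (child cost + transition cost)
    add <- apply(C + rep(cost[ch, ], each = k), 1, min)
    cost[p, ] <- cost[p, ] + add
  }
  root <- po$edge[nrow(po$edge), 1]
  as.integer(round(min(cost[root, ])))
}

# per-character minimum conceivable steps (on the best tree)
.char_min_steps <- function(states, ordered, alphabet) {
  if (alphabet == "dna") {
    states <- toupper(states)
    states[!states %in% c("A", "C", "G", "T")] <- "?"
    obs <- unique(states[states != "?"])
    return(max(length(obs) - 1L, 0L))
  }
  obs <- suppressWarnings(as.integer(states[states != "?"]))
  if (length(obs) == 0) return(0L)
  if (ordered) max(obs) - min(obs) else length(unique(obs)) - 1L
}

# per-character maximum steps over trees = steps on the star tree
.char_max_steps <- function(states, ordered, alphabet) {
  if (alphabet == "dna") {
    states <- toupper(states)
    states[!states %in% c("A", "C", "G", "T")] <- "?"
  }
  obs <- states[states != "?"]
  if (length(obs) == 0) return(0L)
  if (ordered) {
    x <- as.integer(obs)
    a <- stats::median(x)  # linear-cost star centre
    best <- min(sum(abs(x - floor(a))), sum(abs(x - ceiling(a))))
    as.integer(best)
  } else {
    length(obs) - max(table(obs))
  }
}

#' Ensemble consistency and retention indices
#'
#' `CI = sum(m_c) / L` and `RI = (sum(g_c) - L) / (sum(g_c) - sum(m_c))`,
#' where `m_c` is the minimum conceivable steps of character c on any tree
#' and `g_c` its maximum (its steps on the star tree; for a binary
#' character, `min(#0, #1)` among scored taxa). Uninformative characters
#' enter the sums exactly as scored (`m_c = 0` for constants), matching the
#' standard ensemble indices. RI is `NA` when its denominator vanishes.
#'
#' @param matrix a [character_matrix()].
#' @param length tree length from [tree_length()] on the same matrix.
#' @param ordered indices of ordered characters (as in [tree_length()]).
#' @return named numeric vector `c(CI = ..., RI = ...)`.
#' @export
ci_ri <- function(matrix, length, ordered = integer(0)) {
  stopifnot(inherits(matrix, "character_matrix"))
  ms <- gs <- numeric(ncol(matrix$cells))
  for (j in seq_len(ncol(matrix$cells))) {
    ms[j] <- .char_min_steps(matrix$cells[, j], j %in% ordered, matrix$alphabet)
    gs[j] <- .char_max_steps(matrix$cells[, j], j %in% ordered, matrix$alphabet)
  }
  ci <- if (length > 0) sum(ms) / length else NA_real_
  ri <- if (sum(gs) > sum(ms)) (sum(gs) - length) / (sum(gs) - sum(ms))
        else NA_real_
  c(CI = ci, RI = ri)
}

#' Maximum parsimony search
#'
#' Finds minimum-length trees: exhaustively over all unrooted binary
#' topologies for up to `exhaustive_limit` taxa, otherwise by random
#' stepwise addition followed by an NNI hill climb, repeated over
#' `replicates` starts. A verification aid for small matrices, not a
#' general MP engine.
#'
#' @param matrix a [character_matrix()].
#' @param ordered indices of ordered characters.
#' @param exhaustive_limit maximum taxon count for exhaustive enumeration
#'   (default 9).
#' @param replicates random-addition replicates in heuristic mode.
#' @param seed integer seed for the heuristic mode.
#' @return a `parsimony_result`: list with `length`, `CI`, `RI`, and
#'   `trees` (`multiPhylo` of minimal topologies found, unrooted).
#' @export
mp_search <- function(matrix, ordered = integer(0), exhaustive_limit = 9,
                      replicates = 10, seed = 1) {
  stopifnot(inherits(matrix, "character_matrix"))
  taxa <- rownames(matrix$cells)
  n <- length(taxa)
  if (n < 4) stop("need at least 4 taxa")
  if (n <= exhaustive_limit) {
    tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    lens <- vapply(tops, tree_length, 0L, matrix = matrix, ordered = ordered)
    best <- min(lens)
    trees <- tops[lens == best]
  } else {
    set.seed(seed)
    best <- Inf; trees <- list()
    for (r in seq_len(replicates)) {
      cur <- .random_addition_tree(matrix, ordered, taxa)
      len <- tree_length(cur, matrix, ordered)
      repeat {
        nbrs <- phangorn::nni(cur)
        nl <- vapply(nbrs, tree_length, 0L, matrix = matrix, ordered = ordered)
        if (min(nl) < len) { k <- which.min(nl); cur <- nbrs[[k]]; len <- nl[k] }
        else break
      }
      if (len < best) { best <- len; trees <- list(cur) }
      else if (len == best &&
               !any(vapply(trees, function(t) ape::dist.topo(t, cur) == 0,
                           logical(1))))
        trees <- c(trees, list(cur))
    }
  }
  iv <- ci_ri(matrix, best, ordered)
  structure(list(length = as.integer(best), CI = iv[["CI"]], RI = iv[["RI"]],
                 trees = structure(trees, class = "multiPhylo")),
            class = "parsimony_result")
}

# random-order start topology for the heuristic climb
.random_addition_tree <- function(matrix, ordered, taxa) {
  ape::unroot(.grow_random_tree(sample(taxa)))
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("parsimony_result: length=", x$length,
      " CI=", format(x$CI, digits = 4),
      " RI=", format(x$RI, digits = 4),
      " (", length(x$trees), " minimal tree",
      if (length(x$trees) != 1) "s", ")\n", sep = "")
  invisible(x)
}
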