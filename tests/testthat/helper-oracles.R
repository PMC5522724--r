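# Independent oracles and small utilities shared across test files.

# write lines to a tempfile, return path
tmpfile_with <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# numeric (brute-force) weighted least-squares score on a fixed topology:
# minimize sum w (d - p)^2 over edge lengths with BFGS, independent of the
# closed-form normal-equation solve in ols_fit()
brute_force_ls_score <- function(topology, table, power = 0) {
  idx <- which(upper.tri(table$d), arr.ind = TRUE)
  y <- table$d[idx]
  w <- if (power == 0) rep(1, length(y)) else y^(-power)
  ne <- nrow(topology$edge)
  obj <- function(beta) {
    phy <- topology
    phy$edge.length <- beta
    p <- stats::cophenetic(phy)[table$taxa, table$taxa][idx]
    sum(w * (y - p)^2)
  }
  fit <- stats::optim(rep(mean(y) / 2, ne), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  fit$value
}

# Fitch parsimony oracle via phangorn on a binary character_matrix
phangorn_fitch_length <- function(tree, cmat) {
  dat <- phangorn::phyDat(cmat$cells, type = "USER",
                          levels = c("0", "1"), ambiguity = "?")
  phangorn::parsimony(tree, dat, method = "fitch")
}

# exact patristic table of a tree with given edge lengths
additive_table_of <- function(tree) {
  distance_table(stats::cophenetic(tree))
}

# unrooted topological identity
same_topology <- function(a, b) {
  ape::dist.topo(ape::unroot(a), ape::unroot(b)) == 0
}

# random binary matrix (not tree-derived), seeded
random_binary_matrix <- function(ntax, nchar, seed, missing_rate = 0) {
  set.seed(seed)
  cells <- matrix(sample(c("0", "1"), ntax * nchar, replace = TRUE),
                  ntax, nchar)
  if (missing_rate > 0)
    cells[stats::runif(length(cells)) < missing_rate] <- "?"
  rownames(cells) <- paste0("t", seq_len(ntax))
  character_matrix(cells, alphabet = "binary")
}
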