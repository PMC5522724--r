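#' Configuration for distance-based tree fitting
#'
#' @param criterion `"ols"` (unweighted least squares, the default and the
#'   paper-mode criterion), `"wls"` (exponentially weighted least squares,
#'   weights `w_ij = d_ij^(-power)`), or `"bme"` (balanced minimum
#'   evolution, Pauplin's closed-form tree length).
#' @param power the exponent P' of the WLS weights; `0` is unweighted.
#'   The worked weighted analysis uses `power = 7`.
#' @param negbrlen one of `"allow"` (report the unconstrained solution,
#'   default), `"clamp_zero"` (set negative fitted lengths to 0, rescore),
#'   `"constrain_nonneg"` (active-set nonnegative least squares).
#' @param search `"exhaustive"` (all unrooted binary topologies, used when
#'   the taxon count is at most `exhaustive_limit`) or `"nni"` (NJ start
#'   plus nearest-neighbour-interchange hill climb).
#' @param exhaustive_limit maximum taxon count for exhaustive enumeration.
#' @param tie_tolerance score tolerance within which topologies are
#'   reported as co-optimal.
#' @return a `fit_config` list.
#' @export
fit_config <- function(criterion = c("ols", "wls", "bme"),
                       power = 0, negbrlen = c("allow", "clamp_zero",
                                               "constrain_nonneg"),
                       search = c("exhaustive", "nni"),
                       exhaustive_limit = 8, tie_tolerance = 1e-9) {
  criterion <- match.arg(criterion)
  negbrlen <- match.arg(negbrlen)
  search <- match.arg(search)
  if (power < 0) stop("power P' must be >= 0")
  if (exhaustive_limit < 4) stop("exhaustive_limit must be >= 4")
  if (criterion == "wls" && power == 0) criterion <- "ols"
  if (criterion == "ols") power <- 0
  structure(list(criterion = criterion, power = power, negbrlen = negbrlen,
                 search = search, exhaustive_limit = exhaustive_limit,
                 tie_tolerance = tie_tolerance), class = "fit_config")
}

# pair x edge indicator matrix: X[pair, edge] = 1 iff edge lies on the
# leaf-leaf path; pairs ordered as the upper triangle of `taxa` x `taxa`
.path_design <- function(phy, taxa) {
  nt <- length(phy$tip.label)
  perm <- match(taxa, phy$tip.label)
  if (anyNA(perm)) stop("topology leaf set does not match table taxa")
  if (nt != length(taxa)) stop("topology has extra leaves")
  ne <- nrow(phy$edge)
  # leaves below each edge's child
  below <- matrix(FALSE, nt + phy$Nnode, nt)
  for (i in seq_len(nt)) below[i, i] <- TRUE
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge)))
    below[po$edge[k, 1], ] <- below[po$edge[k, 1], ] | below[po$edge[k, 2], ]
  pairs <- which(upper.tri(diag(length(taxa))), arr.ind = TRUE)
  X <- matrix(0, nrow(pairs), ne)
  for (e in seq_len(ne)) {
    inside <- below[phy$edge[e, 2], perm]  # membership in `taxa` order
    X[, e] <- as.numeric(xor(inside[pairs[, 1]], inside[pairs[, 2]]))
  }
  list(X = X, pairs = pairs)
}

.table_vec <- function(table) {
  idx <- which(upper.tri(table$d), arr.ind = TRUE)
  table$d[idx]
}

# active-set nonnegative weighted least squares (small systems only)
.nnls_fit <- function(X, y, w) {
  free <- rep(TRUE, ncol(X))
  beta <- rep(0, ncol(X))
  for (iter in seq_len(ncol(X) + 1)) {
    Xf <- X[, free, drop = FALSE]
    b <- solve(crossprod(Xf, w * Xf), crossprod(Xf, w * y))
    if (all(b >= -1e-12)) { beta[free] <- pmax(b, 0); return(beta) }
    worst <- which(free)[which.min(b)]
    free[worst] <- FALSE
    if (!any(free)) return(beta)
  }
  beta
}

#' Least-squares branch lengths and score on a fixed topology
#'
#' Fits branch lengths minimizing the (optionally weighted) sum of squared
#' deviations between the observed averaged distances and the tree's
#' implied patristic distances, by solving the normal equations of the
#' path-indicator linear system. The minimized sum is the score — no
#' normalization, so an exactly additive table scores 0.
#'
#' @param topology a `phylo` whose leaves are exactly the table's taxa
#'   (rooted or unrooted; the fit treats it as a graph).
#' @param table a `distance_table`.
#' @param config a [fit_config()].
#' @return a `fit_result`: list with `tree` (topology with fitted
#'   `edge.length`), `score`, `criterion`, `power`, `negbrlen`, and `p`
#'   (implied patristic matrix).
#' @export
ols_fit <- function(topology, table, config = fit_config()) {
  stopifnot(inherits(table, "distance_table"))
  # a 2-degree root makes its two incident edges indistinguishable on leaf
  # paths; fit on the unrooted graph (a posteriori rooting adds no length)
  if (ape::is.rooted(topology) && length(topology$tip.label) > 2)
    topology <- ape::unroot(topology)
  des <- .path_design(topology, table$taxa)
  y <- .table_vec(table)
  w <- .pair_weights(y, config)
  A <- crossprod(des$X, w * des$X)
  beta <- tryCatch(solve(A, crossprod(des$X, w * y)),
                   error = function(e) stop("singular least-squares system: ",
                                            conditionMessage(e)))
  beta <- as.numeric(beta)
  if (config$negbrlen == "clamp_zero" && any(beta < 0)) {
    beta <- pmax(beta, 0)
  } else if (config$negbrlen == "constrain_nonneg" && any(beta < 0)) {
    beta <- .nnls_fit(des$X, y, w)
  }
  resid <- y - as.numeric(des$X %*% beta)
  score <- sum(w * resid^2)
  fit <- topology
  fit$edge.length <- beta
  p <- matrix(0, length(table$taxa), length(table$taxa),
              dimnames = list(table$taxa, table$taxa))
  p[des$pairs] <- as.numeric(des$X %*% beta)
  p <- p + t(p)
  structure(list(tree = fit, score = score, criterion = config$criterion,
                 power = config$power, negbrlen = config$negbrlen, p = p),
            class = "fit_result")
}

.pair_weights <- function(y, config) {
  if (config$power == 0) return(rep(1, length(y)))
  if (any(y == 0))
    stop("zero distance with P' > 0: weights d^(-P') undefined")
  y^(-config$power)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: criterion=", x$criterion,
      if (x$criterion == "wls") paste0(" (P'=", x$power, ")"),
      ", score=", format(x$score, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Pauplin's balanced minimum evolution tree length
#'
#' Closed-form BME length of a binary unrooted topology against a distance
#' table: `sum over pairs of 2^(1 - t_ij) d_ij`, with `t_ij` the number of
#' edges on the topological path between leaves i and j.
#'
#' @param topology binary tree (`phylo`); a rooted binary tree is unrooted
#'   first. Non-binary topologies are an error.
#' @param table a `distance_table`.
#' @return the BME length (numeric scalar).
#' @export
bme_length <- function(topology, table) {
  stopifnot(inherits(table, "distance_table"))
  phy <- topology
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  if (!ape::is.binary(phy)) stop("BME length requires a binary topology")
  t_ij <- path_length_matrix(phy, use_lengths = FALSE)
  t_ij <- t_ij[table$taxa, table$taxa]
  lam <- 2^(1 - t_ij)
  sum((lam * table$d)[upper.tri(t_ij)])
}

.score_topology <- function(phy, table, config) {
  if (config$criterion == "bme") bme_length(phy, table)
  else ols_fit(phy, table, config)$score
}

#' Search for the best-fitting tree(s) under a distance criterion
#'
#' Enumerates all unrooted binary topologies when the taxon count is within
#' `config$exhaustive_limit` (there are (2n-5)!! of them), otherwise starts
#' from the NJ tree and hill-climbs over NNI rearrangements. All topologies
#' whose score is within `config$tie_tolerance` of the optimum are
#' returned.
#'
#' @param table a `distance_table` with at least 4 taxa.
#' @param config a [fit_config()].
#' @return list of `fit_result`s (BME results carry OLS branch lengths but
#'   the BME length as `score`), best first.
#' @export
search_best_tree <- function(table, config = fit_config()) {
  stopifnot(inherits(table, "distance_table"))
  n <- length(table$taxa)
  if (n < 4) stop("need at least 4 taxa to search")
  if (config$search == "exhaustive" && n <= config$exhaustive_limit) {
    tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = table$taxa)
    scores <- vapply(tops, .score_topology, 0, table = table, config = config)
  } else {
    cur <- ape::unroot(nj_tree(table))
    cur_s <- .score_topology(cur, table, config)
    repeat {
      nbrs <- phangorn::nni(cur)
      ns <- vapply(nbrs, .score_topology, 0, table = table, config = config)
      if (min(ns) < cur_s - 1e-12) {
        k <- which.min(ns); cur <- nbrs[[k]]; cur_s <- ns[k]
      } else break
    }
    tops <- c(structure(list(cur), class = "multiPhylo"), phangorn::nni(cur))
    scores <- c(cur_s, vapply(tops[-1], .score_topology, 0,
                              table = table, config = config))
  }
  best <- min(scores)
  keep <- which(scores <= best + config$tie_tolerance)
  keep <- keep[order(scores[keep])]
  lapply(keep, function(k) {
    fr <- ols_fit(tops[[k]], table, config)
    if (config$criterion == "bme") fr$score <- scores[k]
    fr
  })
}

#' Neighbor-joining tree from a distance table
#'
#' Saitou-Nei agglomeration (via `ape::nj`); the supertree option of the
#' average consensus. The result is unrooted.
#'
#' @param table a `distance_table` with at least 3 taxa.
#' @return a `phylo`.
#' @export
nj_tree <- function(table) {
  stopifnot(inherits(table, "distance_table"))
  if (length(table$taxa) < 3) stop("NJ needs at least 3 taxa")
  ape::nj(table$d)
}

#' UPGMA phenogram from a distance table
#'
#' Average-linkage clustering; the resulting rooted tree is ultrametric.
#' Shown in the source material as the phenetic contrast: on non-clock
#' (additive but not ultrametric) data UPGMA can recover the wrong
#' topology where NJ and least squares do not.
#'
#' @param table a `distance_table` with at least 2 taxa.
#' @return a rooted `phylo` with branch lengths (heights halved).
#' @export
upgma_tree <- function(table) {
  stopifnot(inherits(table, "distance_table"))
  if (length(table$taxa) < 2) stop("need at least 2 taxa")
  hc <- stats::hclust(stats::as.dist(table$d), method = "average")
  ape::as.phylo(hc)  # as.phylo.hclust already halves merge heights
}

#' Strict consensus of rooted trees
#'
#' Retains exactly the clades present in every input tree.
#'
#' @param trees `multiPhylo` (or list) of rooted trees on identical leaf
#'   sets.
#' @return a rooted `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  trees <- structure(as.list(trees), class = "multiPhylo")
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(sets, identical, logical(1), y = sets[[1]])))
    stop("strict consensus requires identical leaf sets")
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Root an unrooted tree on the pendant edge of the outgroup
#'
#' A posteriori rooting: the root is placed on the outgroup's terminal
#' branch, making the outgroup the sister of everything else.
#'
#' @param tree a `phylo`.
#' @param outgroup a leaf label.
#' @return a rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup %in% tree$tip.label)
    stop("'", outgroup, "' is not a leaf of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
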