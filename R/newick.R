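#' Newick I/O in the paper dialect
#'
#' Trees are `ape::phylo` objects; forests are `ape::multiPhylo` lists with
#' equal (unit) weights and an optional `provenance` attribute recording the
#' source character of each tree. The writing dialect is deliberately
#' strict: unquoted labels, no branch lengths (unit length is implicit),
#' polytomies as multifurcations, one semicolon-terminated tree per line.
#' Labels containing any of the Newick metacharacters `( ) , ; :` or
#' whitespace are rejected rather than auto-quoted.
#'
#' @name newick-io
NULL

.check_newick_labels <- function(labs) {
  bad <- grepl("[(),;:[:space:]]", labs)
  if (any(bad))
    stop("taxon label contains Newick metacharacters: ",
         paste(labs[bad], collapse = ", "))
  invisible(TRUE)
}

.newick_string <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (length(phy$tip.label) < 2)
    stop("refusing to write a tree with fewer than 2 leaves")
  .check_newick_labels(phy$tip.label)
  nt <- length(phy$tip.label)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  rec <- function(node) {
    if (node <= nt) return(phy$tip.label[node])
    ch <- kids[[as.character(node)]]
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")")
  }
  paste0(rec(nt + 1L), ";")
}

#' Write trees as topology-only Newick
#'
#' @param trees a `phylo` or `multiPhylo` (e.g. a forest from
#'   [build_forests()]).
#' @param path output file path; one tree per line.
#' @return the path, invisibly.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- c(structure(list(trees), class = "multiPhylo"))
  if (length(trees) == 0) stop("empty forest: nothing to write")
  writeLines(vapply(trees, .newick_string, ""), path)
  invisible(path)
}

#' Read a Newick tree file into a forest
#'
#' Each non-blank line must hold one valid Newick string. Edges without
#' lengths receive unit length (a branch length of one), the convention
#' under which the average consensus operates.
#'
#' @param path file path.
#' @param unit_lengths if `TRUE` (default) missing branch lengths become 1;
#'   lengths present in the file are preserved.
#' @return a `multiPhylo` forest.
#' @export
read_newick <- function(path, unit_lengths = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no trees in ", path)
  trees <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    phy <- tryCatch(ape::read.tree(text = lines[i]),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy))
      stop("Newick parse error at line ", i, " of ", path)
    if (unit_lengths && is.null(phy$edge.length))
      phy$edge.length <- rep(1, nrow(phy$edge))
    trees[[i]] <- phy
  }
  structure(trees, class = "multiPhylo")
}

#' Construct a rooted tree from nested taxon groups
#'
#' Convenience constructor used throughout: `rooted_tree(c("A","B","C"),
#' list(c("D","E")))` is the basal-polytomy tree `(A,B,C,(D,E));`. Mostly a
#' thin wrapper over Newick text; all edges get unit length.
#'
#' @param newick a Newick string (with or without trailing semicolon).
#' @return a `phylo` with unit edge lengths.
#' @export
tree_from_newick <- function(newick) {
  if (!grepl(";\\s*$", newick)) newick <- paste0(newick, ";")
  phy <- ape::read.tree(text = newick)
  if (is.null(phy)) stop("invalid Newick: ", newick)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

# leaf sets below every internal node, as a list keyed by node id
.clades_of <- function(phy) {
  nt <- length(phy$tip.label)
  nn <- phy$Nnode
  out <- vector("list", nn)
  # postorder accumulation
  po <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", nt + nn)
  for (i in seq_len(nt)) below[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  for (j in seq_len(nn)) out[[j]] <- sort(below[[nt + j]])
  out
}

#' Does a tree contain a clade?
#'
#' Checks whether some node of `tree` has exactly `taxa` as its leaf set.
#' For rooted questions root the tree first (see [root_at_outgroup()]).
#'
#' @param tree a `phylo`.
#' @param taxa character vector of taxon labels.
#' @return logical.
#' @export
has_clade <- function(tree, taxa) {
  want <- sort(unique(as.character(taxa)))
  any(vapply(.clades_of(tree), identical, logical(1), y = want))
}
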