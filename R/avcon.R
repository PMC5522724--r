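#' Path-length (patristic) distance matrix of a tree
#'
#' For every leaf pair, the sum of branch lengths on the unique path between
#' them, the tree being regarded as an unrooted graph (the root is an
#' ordinary vertex of its degree). With `use_lengths = FALSE` every edge
#' counts one — the "branch length of unity" convention of the average
#' consensus.
#'
#' @param tree a `phylo`.
#' @param use_lengths use stored edge lengths (`TRUE`) or unit lengths.
#' @return symmetric numeric matrix with taxon dimnames.
#' @export
path_length_matrix <- function(tree, use_lengths = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!use_lengths || is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  if (any(tree$edge.length < 0)) stop("negative edge length on stored tree")
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Average Consensus distance table of a forest
#'
#' Averages, with equal tree weights, the per-tree path-length matrices of a
#' forest over the trees in which each taxon pair co-occurs. In paper mode
#' (default) all branch lengths are forced to unity regardless of what the
#' input trees carry.
#'
#' @param forest a `multiPhylo` (e.g. from [build_forests()]).
#' @param use_lengths if `TRUE`, respect stored branch lengths instead of
#'   forcing unity.
#' @return a `distance_table`: list with `d` (symmetric averaged matrix,
#'   zero diagonal) and `coverage` (per-pair count of contributing trees).
#' @examples
#' fb <- build_forests(fig2_matrix())
#' tab <- average_consensus_table(fb$additional)
#' tab$d["O", "A"]   # 2
#' tab$d["B", "C"]   # 8/3
#' @export
average_consensus_table <- function(forest, use_lengths = FALSE) {
  if (inherits(forest, "phylo")) forest <- c(structure(list(forest), class = "multiPhylo"))
  if (length(forest) == 0) stop("empty forest")
  taxa <- unique(unlist(lapply(forest, `[[`, "tip.label")))
  n <- length(taxa)
  if (n < 2) stop("fewer than 2 taxa in forest")
  acc <- matrix(0, n, n, dimnames = list(taxa, taxa))
  cov <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (phy in forest) {
    pm <- path_length_matrix(phy, use_lengths = use_lengths)
    idx <- match(rownames(pm), taxa)
    acc[idx, idx] <- acc[idx, idx] + pm
    cov[idx, idx] <- cov[idx, idx] + 1L
  }
  off <- upper.tri(cov)
  if (any(cov[off] == 0)) {
    k <- which(cov == 0 & upper.tri(cov), arr.ind = TRUE)[1, ]
    stop("taxon pair never co-occurs in any tree: ",
         taxa[k[1]], " / ", taxa[k[2]])
  }
  d <- acc
  d[off] <- acc[off] / cov[off]
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  diag(d) <- 0
  diag(cov) <- length(forest)
  structure(list(d = d, coverage = cov, taxa = taxa),
            class = "distance_table")
}

#' @export
print.distance_table <- function(x, ...) {
  cat("distance_table over", length(x$taxa), "taxa\n")
  print(round(x$d, 5))
  invisible(x)
}

#' Build a distance_table directly from a matrix
#'
#' @param d symmetric numeric matrix with taxon dimnames.
#' @param coverage optional coverage matrix (defaults to 1 everywhere).
#' @return a `distance_table`.
#' @export
distance_table <- function(d, coverage = NULL) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) stop("distance matrix needs taxon dimnames")
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("nonzero diagonal")
  if (is.null(coverage))
    coverage <- matrix(1L, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(d = d, coverage = coverage, taxa = rownames(d)),
            class = "distance_table")
}

#' Write / read an averaged distance table
#'
#' `phylip-square`: leading taxon count, then one full row per taxon.
#' `nexus-distances`: a NEXUS `taxa` + `distances` block (triangle = both).
#' At least 9 significant digits are written so tables round-trip.
#'
#' @param table a `distance_table`.
#' @param path file path.
#' @param format `"phylip-square"` or `"nexus-distances"`.
#' @return the path, invisibly.
#' @export
write_distance_table <- function(table, path,
                                 format = c("phylip-square", "nexus-distances")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "distance_table"))
  n <- length(table$taxa)
  if (n == 0) stop("empty distance table")
  fmtrow <- function(i) paste(sprintf("%.10g", table$d[i, ]), collapse = " ")
  con <- file(path, "w"); on.exit(close(con))
  if (format == "phylip-square") {
    writeLines(as.character(n), con)
    for (i in seq_len(n))
      writeLines(paste(table$taxa[i], fmtrow(i)), con)
  } else {
    writeLines(c("#NEXUS",
                 "begin taxa;",
                 paste0("  dimensions ntax=", n, ";"),
                 paste0("  taxlabels ", paste(table$taxa, collapse = " "), ";"),
                 "end;",
                 "begin distances;",
                 "  format triangle=both diagonal labels;",
                 "  matrix"), con)
    for (i in seq_len(n))
      writeLines(paste("   ", table$taxa[i], fmtrow(i)), con)
    writeLines(c("  ;", "end;"), con)
  }
  invisible(path)
}

#' @rdname write_distance_table
#' @export
read_distance_table <- function(path,
                                format = c("phylip-square", "nexus-distances")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  if (format == "phylip-square") {
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(trimws(lines[1]))
    rows <- lapply(lines[1 + seq_len(n)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  } else {
    i0 <- grep("^\\s*matrix\\s*$", lines)
    i1 <- grep("^\\s*;\\s*$", lines)
    i1 <- i1[i1 > i0][1]
    rows <- lapply(lines[(i0 + 1):(i1 - 1)], function(l) strsplit(trimws(l), "\\s+")[[1]])
    n <- length(rows)
  }
  taxa <- vapply(rows, `[`, "", 1)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(taxa, taxa)
  d <- (d + t(d)) / 2  # guard against last-digit asymmetry
  distance_table(d)
}
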