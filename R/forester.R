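#' Rewrite one binary character as Hennigian tree(s)
#'
#' A binary character over taxa `ABCDE` with states `00011` *is* the rooted
#' tree `ABC(DE)`: the clade is exactly the taxa carrying the apomorphic
#' state 1. Three renderings are produced:
#' \describe{
#'   \item{`additional`}{basal-polytomy form `(A,B,C,(D,E))`.}
#'   \item{`no_poly`}{outgroup-nested form `(A,(B,C,(D,E)))` with the
#'     outgroup the sole child of the root beside one ingroup clade. The
#'     character's outgroup state must be 0 (or missing, assumed 0).}
#'   \item{`with_poly`}{like `additional`, but uninformative characters
#'     (fewer than two taxa in either state among scored taxa) are rendered
#'     as one complete polytomy over the scored taxa, e.g. `(A,B,C,D,E)`.}
#' }
#' Missing entries admit two readings: `prune` drops the `?` taxa from this
#' character's tree; `expand` returns one tree per completion of the `?`
#' cells (so `0?011` yields both `A(BC(DE))` and `A(C(BDE))`).
#'
#' @param matrix a binary [character_matrix()].
#' @param char_index 1-based character (column) index.
#' @param mode `"additional"`, `"no_poly"` or `"with_poly"`.
#' @param missing_policy `"prune"` (default) or `"expand"`.
#' @param outgroup outgroup label; defaults to the matrix's outgroup.
#' @return a `multiPhylo` of 0, 1 or `2^m` trees (m = number of `?` cells
#'   under `expand`). Characters that are uninformative are dropped (empty
#'   result) under `additional`/`no_poly` and rendered as polytomies under
#'   `with_poly`.
#' @export
character_to_tree <- function(matrix, char_index,
                              mode = c("additional", "no_poly", "with_poly"),
                              missing_policy = c("prune", "expand"),
                              outgroup = matrix$outgroup) {
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(matrix, "character_matrix"))
  if (matrix$alphabet != "binary")
    stop("character_to_tree needs a binary matrix; recode first")
  if (char_index < 1 || char_index > ncol(matrix$cells))
    stop("char_index ", char_index, " out of range")
  taxa <- rownames(matrix$cells)
  states <- matrix$cells[, char_index]
  if (all(states == "?")) stop("character ", char_index, ": all taxa missing")
  if (mode == "no_poly") {
    if (is.null(outgroup)) stop("no_poly mode requires an outgroup")
    og <- match(outgroup, taxa)
    if (is.na(og)) stop("outgroup '", outgroup, "' not in matrix")
    if (states[og] == "1")
      stop("character ", char_index, " scores outgroup '", outgroup,
           "' with the apomorphic state 1: conflicts with a priori polarity")
    # an ambiguous outgroup is assumed plesiomorphic (state 0)
    if (states[og] == "?") states[og] <- "0"
  }
  miss <- which(states == "?")
  variants <- if (missing_policy == "expand" && length(miss) > 0) {
    # all 2^m completions of the ? cells
    grid <- expand.grid(rep(list(c("0", "1")), length(miss)),
                        stringsAsFactors = FALSE)
    lapply(seq_len(nrow(grid)), function(r) {
      s <- states
      s[miss] <- unlist(grid[r, ], use.names = FALSE)
      list(states = s, taxa = taxa)
    })
  } else {
    keep <- states != "?"
    list(list(states = states[keep], taxa = taxa[keep]))
  }
  out <- list()
  for (v in variants) {
    phy <- .one_character_tree(v$states, v$taxa, mode, outgroup)
    if (!is.null(phy)) out[[length(out) + 1L]] <- phy
  }
  structure(out, class = "multiPhylo")
}

# build a single tree from complete states over taxa; NULL when the
# character is uninformative and mode drops it
.one_character_tree <- function(states, taxa, mode, outgroup) {
  ones <- taxa[states == "1"]
  zeros <- taxa[states == "0"]
  informative <- length(ones) >= 2 && length(zeros) >= 2
  if (!informative) {
    if (mode != "with_poly") return(NULL)
    if (length(taxa) < 2) return(NULL)
    return(tree_from_newick(paste0("(", paste(taxa, collapse = ","), ")")))
  }
  clade <- paste0("(", paste(ones, collapse = ","), ")")
  if (mode == "no_poly") {
    if (!outgroup %in% taxa) return(NULL)  # outgroup pruned as '?'
    rest <- setdiff(zeros, outgroup)
    inner <- if (length(rest) > 0)
      paste0("(", paste(c(rest, clade), collapse = ","), ")") else clade
    return(tree_from_newick(paste0("(", outgroup, ",", inner, ")")))
  }
  tree_from_newick(paste0("(", paste(c(zeros, clade), collapse = ","), ")"))
}

#' Rewrite a binary matrix as its three Hennigian forests
#'
#' Emits the three tree files of the FORESTER run as in-memory forests:
#' `with_poly` (every character, uninformative ones as complete polytomies),
#' `no_poly` (informative characters, outgroup-nested) and `additional`
#' (informative characters, basal polytomy). Characters whose outgroup cell
#' is `?` are allowed in `no_poly` with the outgroup assumed plesiomorphic.
#'
#' @param matrix binary [character_matrix()].
#' @param outgroup outgroup label (default: the matrix's).
#' @param missing_policy `"prune"` or `"expand"`; see [character_to_tree()].
#' @return a `forest_bundle`: list of three `multiPhylo` forests, each
#'   carrying a `provenance` attribute (source character index per tree).
#' @examples
#' m <- fig2_matrix()
#' fb <- build_forests(m)
#' length(fb$additional)  # 3 informative characters -> 3 trees
#' @export
build_forests <- function(matrix, outgroup = matrix$outgroup,
                          missing_policy = c("prune", "expand")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(matrix, "character_matrix"))
  if (is.null(outgroup)) stop("build_forests requires an outgroup")
  if (!outgroup %in% rownames(matrix$cells))
    stop("outgroup '", outgroup, "' not in matrix")
  one <- function(mode) {
    trees <- list(); prov <- integer(0)
    for (j in seq_len(ncol(matrix$cells))) {
      tj <- tryCatch(character_to_tree(matrix, j, mode = mode,
                                       missing_policy = missing_policy,
                                       outgroup = outgroup),
                     error = function(e) {
                       if (mode == "no_poly") structure(list(), class = "multiPhylo")
                       else stop(e)
                     })
      if (length(tj) > 0) {
        trees <- c(trees, unclass(tj))
        prov <- c(prov, rep(j, length(tj)))
      }
    }
    structure(trees, class = "multiPhylo", provenance = prov)
  }
  bundle <- list(with_poly = one("with_poly"),
                 no_poly = one("no_poly"),
                 additional = one("additional"))
  if (length(bundle$additional) == 0)
    warning("no informative characters: no_poly/additional forests are empty")
  structure(bundle, class = "forest_bundle")
}

#' @export
print.forest_bundle <- function(x, ...) {
  cat("forest_bundle: with_poly=", length(x$with_poly),
      " no_poly=", length(x$no_poly),
      " additional=", length(x$additional), " trees\n", sep = "")
  invisible(x)
}

#' Write the three FORESTER tree files
#'
#' @param bundle a `forest_bundle` from [build_forests()].
#' @param dir output directory.
#' @param stem base file name; files are `With_poly_<stem>.nwk` etc.
#' @return named character vector of the three paths, invisibly.
#' @export
write_forest_bundle <- function(bundle, dir = ".", stem = "forest") {
  stopifnot(inherits(bundle, "forest_bundle"))
  paths <- c(with_poly = file.path(dir, paste0("With_poly_", stem, ".nwk")),
             no_poly = file.path(dir, paste0("No_poly_", stem, ".nwk")),
             additional = file.path(dir, paste0("Additional_", stem, ".nwk")))
  for (k in names(paths))
    if (length(bundle[[k]]) > 0) write_newick(bundle[[k]], paths[k])
  invisible(paths)
}

#' Rewrite a three-taxon-statement matrix as minimal trees ("seedlings")
#'
#' Each column must score exactly three taxa — one `0` and two `1` — all
#' others `?`. The minimal relationship `A(BC)/011` is rewritten as the
#' rooted triplet `(A,(B,C))`.
#'
#' @param matrix binary [character_matrix()] of 3TS columns.
#' @return a `multiPhylo` of rooted triplets, one per column.
#' @export
minimal_trees_from_3ts <- function(matrix) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (matrix$alphabet != "binary") stop("3TS matrices are binary")
  taxa <- rownames(matrix$cells)
  trees <- vector("list", ncol(matrix$cells))
  for (j in seq_len(ncol(matrix$cells))) {
    states <- matrix$cells[, j]
    zeros <- taxa[states == "0"]; ones <- taxa[states == "1"]
    if (length(zeros) != 1 || length(ones) != 2)
      stop("column ", j, " is not a three-taxon statement ",
           "(need one 0 and two 1 among scored taxa; got ",
           length(zeros), " zeros, ", length(ones), " ones)")
    trees[[j]] <- tree_from_newick(
      paste0("(", zeros, ",(", ones[1], ",", ones[2], "))"))
  }
  structure(trees, class = "multiPhylo",
            provenance = seq_len(ncol(matrix$cells)))
}
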