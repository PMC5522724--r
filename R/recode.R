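#' Presence/absence recoding of a DNA alignment
#'
#' The simplest binary representation of an aligned nucleotide matrix: for
#' each alignment column and each unambiguous base observed in it, one
#' binary character scores presence (1) of that base, absence (0, a
#' different unambiguous base) or missing (`?`, a gap or ambiguity code).
#' When an outgroup is supplied, (i) columns where the outgroup cell is
#' ambiguous (not `A`/`C`/`G`/`T`) are discarded before recoding, and
#' (ii) only characters in which the outgroup scores 0 are kept, so that
#' state 1 is apomorphic relative to the outgroup. Character names encode
#' site and base as `s<site>=<base>`.
#'
#' @param alignment a [character_matrix()] with alphabet `"dna"`.
#' @param outgroup outgroup label; `NULL` gives the unfiltered (full)
#'   presence/absence recoding with no column discarded.
#' @return a binary [character_matrix()] (outgroup carried over).
#' @export
dna_presence_absence <- function(alignment, outgroup = alignment$outgroup) {
  stopifnot(inherits(alignment, "character_matrix"))
  if (alignment$alphabet != "dna") stop("alignment must have alphabet 'dna'")
  taxa <- rownames(alignment$cells)
  if (!is.null(outgroup) && !outgroup %in% taxa)
    stop("outgroup '", outgroup, "' not in alignment")
  A <- toupper(alignment$cells)
  bases <- c("A", "C", "G", "T")
  cols <- list(); nms <- character(0)
  for (site in seq_len(ncol(A))) {
    col <- A[, site]
    if (!is.null(outgroup) && !(col[match(outgroup, taxa)] %in% bases))
      next  # ambiguous outgroup: column discarded before recoding
    obs <- intersect(bases, unique(col))
    for (b in obs) {
      v <- ifelse(col == b, "1", ifelse(col %in% bases, "0", "?"))
      if (!is.null(outgroup) && v[match(outgroup, taxa)] != "0")
        next  # keep only outgroup-zero characters
      cols[[length(cols) + 1L]] <- v
      nms <- c(nms, paste0("s", site, "=", b))
    }
  }
  cells <- if (length(cols)) do.call(cbind, cols) else
    matrix(character(0), nrow = length(taxa), ncol = 0)
  colnames(cells) <- nms
  character_matrix(cells, taxa = taxa, alphabet = "binary",
                   outgroup = outgroup)
}

#' Additive binary recoding of ordered multistate characters
#'
#' An ordered character with maximum state m becomes m binary columns:
#' state k maps to k ones followed by m - k zeros, so each step along the
#' ordered scale toggles exactly one derived column and Wagner (ordered)
#' parsimony length is preserved under Fitch scoring of the recoding.
#' `?` maps to `?` in every derived column. Characters not listed in
#' `ordered_chars` must already be binary and pass through unchanged.
#'
#' @param matrix a [character_matrix()] with alphabet `"multistate"` (or
#'   `"binary"`).
#' @param ordered_chars integer vector of 1-based column indices to recode;
#'   default: every column with a state above 1.
#' @return a binary [character_matrix()]; derived columns are named
#'   `<orig>_<level>`.
#' @export
additive_binary <- function(matrix, ordered_chars = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  cells <- matrix$cells
  if (!all(cells == "?" | grepl("^[0-9]$", cells)))
    stop("non-integer state in matrix; additive coding needs integer states")
  maxs <- apply(cells, 2, function(s) {
    s <- s[s != "?"]
    if (length(s) == 0) 0L else max(as.integer(s))
  })
  if (is.null(ordered_chars)) ordered_chars <- which(maxs > 1L)
  bad <- setdiff(which(maxs > 1L), ordered_chars)
  if (length(bad) > 0)
    stop("character(s) ", paste(bad, collapse = ", "),
         " have states above 1 but are not listed as ordered")
  cols <- list(); nms <- character(0)
  orig <- colnames(cells)
  for (j in seq_len(ncol(cells))) {
    if (!(j %in% ordered_chars) || maxs[j] <= 1L) {
      cols[[length(cols) + 1L]] <- cells[, j]
      nms <- c(nms, orig[j])
      next
    }
    m <- maxs[j]
    for (lev in seq_len(m)) {
      s <- cells[, j]
      v <- ifelse(s == "?", "?", ifelse(as.integer(ifelse(s == "?", 0, s)) >= lev, "1", "0"))
      cols[[length(cols) + 1L]] <- v
      nms <- c(nms, paste0(orig[j], "_", lev))
    }
  }
  cells2 <- do.call(cbind, cols)
  colnames(cells2) <- nms
  character_matrix(cells2, taxa = rownames(cells), alphabet = "binary",
                   outgroup = matrix$outgroup)
}

#' Append an artificial all-zero outgroup
#'
#' Adds a hypothetical all-plesiomorphic taxon as the last row and declares
#' it the outgroup, the standard device for rooting a matrix that has no
#' natural outgroup.
#'
#' @param matrix a binary [character_matrix()].
#' @param name label for the new taxon.
#' @return the augmented [character_matrix()] with `outgroup = name`.
#' @export
add_allzero_outgroup <- function(matrix, name = "ROOT") {
  stopifnot(inherits(matrix, "character_matrix"))
  if (name %in% rownames(matrix$cells))
    stop("taxon '", name, "' already present")
  cells <- rbind(matrix$cells, rep("0", ncol(matrix$cells)))
  rownames(cells) <- c(rownames(matrix$cells), name)
  character_matrix(cells, alphabet = matrix$alphabet, outgroup = name)
}
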