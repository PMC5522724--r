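#' Character matrices for matrix-free cladistics
#'
#' A `character_matrix` is a taxa-by-characters table of single-symbol states
#' over one of three alphabets: `"binary"` (`0`/`1`, `0` plesiomorphic by
#' prior declaration), `"multistate"` (ordered integer states `0`, `1`, ...)
#' or `"dna"` (IUPAC nucleotides; anything outside `A`,`C`,`G`,`T` is treated
#' as ambiguous). `?` marks missing data in every alphabet. An optional
#' outgroup taxon carries the a priori polarity: its states are assumed
#' plesiomorphic, and it is used to root fitted trees.
#'
#' @param cells character matrix of single-character states; rownames are
#'   taxon labels unless `taxa` is given.
#' @param taxa character vector of unique, non-empty taxon labels.
#' @param alphabet one of `"binary"`, `"multistate"`, `"dna"`.
#' @param outgroup optional taxon label; must name a row. The convention of
#'   placing the outgroup last in the file is honoured as a default by
#'   [read_matrix()] when no outgroup is given.
#' @return an object of class `character_matrix`: a list with elements
#'   `cells` (character matrix), `alphabet`, and `outgroup`.
#' @seealso [read_matrix()], [write_matrix()], [build_forests()]
#' @export
character_matrix <- function(cells,
                             taxa = rownames(cells),
                             alphabet = c("binary", "multistate", "dna"),
                             outgroup = NULL) {
  alphabet <- match.arg(alphabet)
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (is.null(taxa)) stop("taxon labels are required (rownames or `taxa`)")
  taxa <- as.character(taxa)
  if (length(taxa) != nrow(cells))
    stop("length of `taxa` (", length(taxa), ") != number of rows (",
         nrow(cells), ")")
  if (anyDuplicated(taxa)) stop("duplicate taxon labels: ",
                                paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  if (any(!nzchar(taxa))) stop("empty taxon label")
  rownames(cells) <- taxa
  if (is.null(colnames(cells)) && ncol(cells) > 0)
    colnames(cells) <- paste0("c", seq_len(ncol(cells)))
  bad <- which(!.state_ok(cells, alphabet), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("illegal state '", cells[bad[1, 1], bad[1, 2]], "' for alphabet '",
         alphabet, "' at taxon '", taxa[bad[1, 1]], "', character ",
         bad[1, 2])
  if (!is.null(outgroup)) {
    if (!outgroup %in% taxa)
      stop("outgroup '", outgroup, "' is not a taxon of the matrix")
  }
  structure(list(cells = cells, alphabet = alphabet, outgroup = outgroup),
            class = "character_matrix")
}

.state_ok <- function(cells, alphabet) {
  ok <- switch(alphabet,
    binary = cells %in% c("0", "1", "?"),
    multistate = cells == "?" | grepl("^[0-9]$", cells),
    dna = toupper(cells) %in% c("A", "C", "G", "T", "U", "R", "Y", "S",
                                "W", "K", "M", "B", "D", "H", "V", "N",
                                "-", "?"))
  matrix(ok, nrow = nrow(cells), ncol = ncol(cells))
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("character_matrix: ", nrow(x$cells), " taxa x ", ncol(x$cells),
      " characters (", x$alphabet, ")\n", sep = "")
  if (!is.null(x$outgroup)) cat("outgroup:", x$outgroup, "\n")
  n <- min(nrow(x$cells), 10L)
  for (i in seq_len(n))
    cat(format(rownames(x$cells)[i], width = 12), " ",
        paste(x$cells[i, seq_len(min(ncol(x$cells), 60L))], collapse = ""),
        "\n", sep = "")
  if (nrow(x$cells) > n) cat("... (", nrow(x$cells) - n, " more)\n", sep = "")
  invisible(x)
}

#' @export
dim.character_matrix <- function(x) dim(x$cells)

#' Number of taxa / characters
#' @param x a [character_matrix()].
#' @return integer count.
#' @export
n_taxa <- function(x) nrow(x$cells)

#' @rdname n_taxa
#' @export
n_char <- function(x) ncol(x$cells)

#' Taxon labels of a matrix
#' @param x a [character_matrix()].
#' @return character vector.
#' @export
taxa_labels <- function(x) rownames(x$cells)

#' Read a relaxed non-interleaved PHYLIP character matrix
#'
#' The dialect: a header line `ntax nchar`, then one taxon per line, the
#' label first (no whitespace inside labels), followed by the states either
#' whitespace-separated, contiguous, or any mixture. Blank lines are
#' ignored.
#'
#' @param path file path.
#' @param alphabet alphabet tag, see [character_matrix()].
#' @param outgroup optional taxon label. Default `"last"` follows the
#'   convention that the pre-defined outgroup is the last taxon of the file;
#'   use `NULL` for no outgroup or give a label explicitly.
#' @return a [character_matrix()].
#' @export
read_matrix <- function(path, alphabet = c("binary", "multistate", "dna"),
                        outgroup = "last") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty matrix file: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr) || any(hdr < 0))
    stop("parse error at line 1: expected header 'ntax nchar', got '",
         lines[1], "'")
  ntax <- hdr[1]; nch <- hdr[2]
  body <- lines[-1]
  if (length(body) != ntax)
    stop("dimension mismatch: header declares ", ntax, " taxa but file has ",
         length(body), " taxon lines")
  labs <- character(ntax)
  cells <- matrix("", nrow = ntax, ncol = nch)
  for (i in seq_len(ntax)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    labs[i] <- tok[1]
    states <- strsplit(paste(tok[-1], collapse = ""), "")[[1]]
    if (length(states) != nch)
      stop("parse error at taxon '", labs[i], "' (line ", i + 1, "): ",
           length(states), " states, expected ", nch)
    if (nch > 0) cells[i, ] <- states
  }
  if (identical(outgroup, "last")) outgroup <- if (ntax > 0) labs[ntax] else NULL
  character_matrix(cells, taxa = labs, alphabet = alphabet,
                   outgroup = outgroup)
}

#' Write a character matrix in relaxed PHYLIP format
#'
#' @param x a [character_matrix()].
#' @param path output file path.
#' @param sep separator between label and states (default two spaces);
#'   states are written contiguously.
#' @return the path, invisibly.
#' @export
write_matrix <- function(x, path, sep = "  ") {
  stopifnot(inherits(x, "character_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(x$cells), ncol(x$cells)), con)
  for (i in seq_len(nrow(x$cells)))
    writeLines(paste0(rownames(x$cells)[i], sep,
                      paste(x$cells[i, ], collapse = "")), con)
  invisible(path)
}

# informativeness of one binary column: >=2 taxa in each state among scored
.binary_split <- function(states) {
  scored <- states %in% c("0", "1")
  list(ones = which(states == "1"), zeros = which(states == "0"),
       missing = which(states == "?"), scored = which(scored))
}

#' Classify a binary character as parsimony-informative
#'
#' A binary character is informative when at least two scored taxa carry the
#' apomorphic state 1 and at least two carry state 0; otherwise it collapses
#' to a polytomy in tree form.
#'
#' @param states character vector of `"0"`/`"1"`/`"?"` states.
#' @return logical.
#' @export
is_informative <- function(states) {
  s <- .binary_split(states)
  length(s$ones) >= 2 && length(s$zeros) >= 2
}
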