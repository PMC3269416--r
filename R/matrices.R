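#' Read an NCBI-style substitution matrix
#'
#' Parses the whitespace-delimited text format used for NCBI scoring
#' matrices (`#` comment lines, one header row of residue symbols, one
#' labelled row per symbol).
#'
#' @param path Path to the matrix file.
#' @return A symmetric integer matrix with residue one-letter codes as
#'   dimnames. A column/row named `X` (or `*`) acts as the wildcard for
#'   non-standard residues.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("substitution matrix file not found: ", path, call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, comment.char = "#",
                                   check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("matrix file is not square with matching row/column labels: ",
         path, call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (!isSymmetric(unname(m))) {
    stop("substitution matrix is not symmetric: ", path, call. = FALSE)
  }
  m
}

#' BLOSUM62 substitution matrix
#'
#' The standard NCBI BLOSUM62 matrix (half-bit units) shipped with the
#' package, including the B/Z ambiguity codes and the X wildcard row.
#'
#' @return Integer matrix, see [read_score_matrix()].
#' @export
blosum62 <- function() {
  if (is.null(.homsite_cache$blosum62)) {
    path <- system.file("extdata", "BLOSUM62.txt", package = "homsite",
                        mustWork = TRUE)
    .homsite_cache$blosum62 <- read_score_matrix(path)
  }
  .homsite_cache$blosum62
}

.homsite_cache <- new.env(parent = emptyenv())

#' Look up substitution scores for residue pairs
#'
#' Vectorised lookup with wildcard fallback: residues absent from the
#' matrix score through the `X` row when present, else 0.
#'
#' @param a,b Character vectors of one-letter residue codes.
#' @param H Substitution matrix.
#' @return Integer vector of scores.
#' @keywords internal
score_pairs <- function(a, b, H) {
  syms <- rownames(H)
  map_sym <- function(x) {
    out <- ifelse(x %in% syms, x, if ("X" %in% syms) "X" else NA_character_)
    out
  }
  a2 <- map_sym(a)
  b2 <- map_sym(b)
  s <- integer(length(a))
  known <- !is.na(a2) & !is.na(b2)
  s[known] <- H[cbind(a2[known], b2[known])]
  s
}
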