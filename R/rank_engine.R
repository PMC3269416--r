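as_row <- function(x) {
  if (is.character(x) && length(x) == 1) strsplit(x, "")[[1]] else
    as.character(x)
}

#' Classify a cluster as conserved or singleton
#'
#' Members are reduced greedily for redundancy: ordered by descending
#' defined length then id, a member is redundant when it is at least
#' `redundancy_identity` identical (over shared aligned columns) to an
#' already retained representative. A cluster with more than one
#' representative is `"conserved"`; otherwise it is a `"singleton"` --
#' a one-off observation with no independent support.
#'
#' @param members Named list (or character vector) of member sequences:
#'   strings, or character vectors where `NA`/`-` marks an unaligned
#'   column (rows must then share the column space).
#' @param redundancy_identity Identity threshold, default 0.90.
#' @return List with `label` (`"conserved"`/`"singleton"`),
#'   `n_nonredundant` and `representatives` (indices into `members`).
#' @export
classify_cluster <- function(members, redundancy_identity = 0.90) {
  stopifnot(length(members) >= 1)
  rows <- lapply(members, as_row)
  rows <- lapply(rows, function(r) { r[r == "-"] <- NA; r })
  ids <- names(members)
  if (is.null(ids)) ids <- as.character(seq_along(rows))
  deflen <- vapply(rows, function(r) sum(!is.na(r)), 0L)
  ord <- order(-deflen, ids)
  reps <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (r in reps) {
      both <- !is.na(rows[[i]]) & !is.na(rows[[r]])
      ident <- if (!any(both)) 0 else
        mean(rows[[i]][both] == rows[[r]][both])
      if (ident >= redundancy_identity) { redundant <- TRUE; break }
    }
    if (!redundant) reps <- c(reps, i)
  }
  list(label = if (length(reps) > 1) "conserved" else "singleton",
       n_nonredundant = length(reps), representatives = sort(reps))
}

#' Henikoff-Henikoff position-based sequence weights
#'
#' In each column, a residue type occurring in `m` sequences out of `k`
#' distinct types contributes `1/(k*m)` to each sequence carrying it
#' (gaps count as a 21st type); sequence weights are the column sums,
#' normalized to sum 1. Divergent sequences receive larger weights.
#'
#' @param rows Character matrix (sequences x columns), or list of
#'   equal-length strings/character vectors; `-` marks gaps.
#' @return Numeric vector of weights summing to 1.
#' @export
henikoff_weights <- function(rows) {
  m <- rows_to_matrix(rows)
  w <- numeric(nrow(m))
  for (p in seq_len(ncol(m))) {
    col <- m[, p]
    tab <- table(col)
    k <- length(tab)
    w <- w + 1 / (k * as.numeric(tab[col]))
  }
  w / sum(w)
}

rows_to_matrix <- function(rows) {
  if (is.matrix(rows)) return(rows)
  rl <- lapply(rows, as_row)
  len <- unique(lengths(rl))
  if (length(len) != 1) stop("alignment rows differ in length", call. = FALSE)
  do.call(rbind, rl)
}

#' Weighted Shannon conservation of a cluster alignment
#'
#' Per column, the entropy `h = -sum p log2 p` of the weighted residue
#' frequencies over the 21-symbol alphabet (20 residues + gap); the
#' conservation score is the mean over columns of `log2(21) - h`, so
#' fully invariant alignments score `log2(21)` and larger means more
#' conserved.
#'
#' @param rows Alignment rows (see [henikoff_weights()]).
#' @param weights Sequence weights; default Henikoff weights of `rows`.
#' @return Mean per-column negentropy (double).
#' @export
conservation_score <- function(rows, weights = NULL) {
  m <- rows_to_matrix(rows)
  if (is.null(weights)) weights <- henikoff_weights(m)
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  neg <- apply(m, 2, function(col) {
    p <- tapply(weights, col, sum)
    p <- p[p > 0]
    log2(21) - (-sum(p * log2(p)))
  })
  mean(neg)
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a PSSM from a cluster alignment (profile average method)
#'
#' `M(p, b) = sum_a f_w(p, a) * H(a, b)` with `f_w` the weighted
#' residue frequencies at column p -- every column is a convex
#' combination of substitution-matrix rows, which carries the matrix's
#' implicit pseudo-counts. Gap mass is renormalized over residues;
#' all-gap columns are dropped.
#'
#' @param rows Alignment rows.
#' @param weights Sequence weights; default Henikoff weights.
#' @param H Substitution matrix, default [blosum62()].
#' @return Matrix (kept columns x 20 residues) with attribute `"kept"`
#'   giving the retained column indices.
#' @export
build_pssm <- function(rows, weights = NULL, H = blosum62()) {
  m <- rows_to_matrix(rows)
  if (is.null(weights)) weights <- henikoff_weights(m)
  keep <- which(apply(m, 2, function(col) any(col != "-" & !is.na(col))))
  if (length(keep) == 0) {
    stop("empty profile: all alignment columns are gaps", call. = FALSE)
  }
  Hs <- H[.AA20, .AA20]
  wild <- if ("X" %in% rownames(H)) H["X", .AA20] else rep(0L, 20)
  pssm <- matrix(0, length(keep), 20, dimnames = list(NULL, .AA20))
  for (ci in seq_along(keep)) {
    col <- m[, keep[ci]]
    res <- !is.na(col) & col != "-"
    f <- tapply(weights[res], col[res], sum)
    f <- f / sum(f)
    for (a in names(f)) {
      row_a <- if (a %in% .AA20) Hs[a, ] else wild
      pssm[ci, ] <- pssm[ci, ] + f[[a]] * row_a
    }
  }
  attr(pssm, "kept") <- keep
  pssm
}

#' Score the query row against a cluster PSSM
#'
#' Sum over non-gap query columns of the PSSM score of the query
#' residue at that column.
#'
#' @param pssm A [build_pssm()] matrix.
#' @param query_row Character vector (or string) over the PSSM's kept
#'   columns; `-` marks query positions without a residue.
#' @return The sequence-PSSM score (double).
#' @export
score_query <- function(pssm, query_row) {
  q <- as_row(query_row)
  if (length(q) != nrow(pssm)) {
    stop("query row length ", length(q), " does not match PSSM columns ",
         nrow(pssm), call. = FALSE)
  }
  use <- which(q != "-" & !is.na(q))
  if (length(use) == 0) return(0)
  ci <- match(q[use], colnames(pssm))
  sum(pssm[cbind(use[!is.na(ci)], ci[!is.na(ci)])])
}

#' Gapped alignment of a cluster's mapped sites
#'
#' Columns are the union of the member sites' query positions; each row
#' shows the member's residues where its site covers the column and `-`
#' elsewhere; the query row shows the query's own residues.
#'
#' @param sites List of `MappedSite`s in one cluster.
#' @param query_seq Query chain sequence (string).
#' @return A `ClusterAlignment`: list with `columns` (0-based query
#'   indices), `rows` (character matrix), `query_row`, `weights`
#'   (Henikoff), `site_ids`.
#' @export
cluster_alignment <- function(sites, query_seq) {
  cols <- sort(unique(unlist(lapply(sites, `[[`, "query_idx"))))
  rows <- t(vapply(sites, function(s) {
    out <- rep("-", length(cols))
    out[match(s$query_idx, cols)] <- s$res
    out
  }, character(length(cols))))
  qa <- strsplit(query_seq, "")[[1]]
  structure(list(columns = cols, rows = rows,
                 query_row = qa[cols + 1],
                 weights = henikoff_weights(rows),
                 site_ids = vapply(sites, `[[`, "", "site_id")),
            class = "ClusterAlignment")
}

#' Rank binding-site clusters
#'
#' Each raw component (conservation, mean contact number, query-PSSM
#' score, mean alignment identity) is standardized to a Z-score across
#' the conserved clusters (`Z = 0` when fewer than two conserved
#' clusters or zero spread), and clusters are ordered by the weighted
#' Z-score sum (descending), then size (descending), then id.
#' Singletons carry no score and always rank below every conserved
#' cluster, ordered by size then id.
#'
#' @param components Data frame with columns `cluster_id`, `label`,
#'   `n_members`, `n_nonredundant`, `conserv`, `contact`, `pssm`,
#'   `pcnt` (singleton rows may hold `NA` components).
#' @param weights Non-negative weights for (conserv, contact, pssm,
#'   pcnt); default all 1.
#' @return The data frame with added `z_conserv`, `z_contact`,
#'   `z_pssm`, `z_pcnt`, `combined`, `rank`, sorted by rank.
#' @export
rank_clusters <- function(components, weights = c(1, 1, 1, 1)) {
  stopifnot(length(weights) == 4, all(weights >= 0))
  comp_names <- c("conserv", "contact", "pssm", "pcnt")
  df <- components
  cons <- df$label == "conserved"
  for (nm in comp_names) {
    z <- rep(NA_real_, nrow(df))
    if (sum(cons) >= 2) {
      x <- df[[nm]][cons]
      s <- stats::sd(x)
      z[cons] <- if (is.na(s) || s == 0) 0 else (x - mean(x)) / s
    } else if (sum(cons) == 1) {
      z[cons] <- 0
    }
    df[[paste0("z_", nm)]] <- z
  }
  zmat <- as.matrix(df[, paste0("z_", comp_names)])
  df$combined <- as.numeric(zmat %*% weights)
  df$combined[!cons] <- NA_real_
  ord_cons <- which(cons)[order(-df$combined[cons], -df$n_members[cons],
                                df$cluster_id[cons])]
  ord_sing <- which(!cons)[order(-df$n_members[!cons],
                                 df$cluster_id[!cons])]
  df <- df[c(ord_cons, ord_sing), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
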