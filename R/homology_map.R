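#' Construct and validate an alignment map
#'
#' An `AlignmentMap` is a colinear residue-level correspondence between
#' a neighbour chain and the query chain: 0-based sequence-index pairs,
#' strictly increasing on both sides, plus the two sequences and the
#' fraction of identical aligned columns.
#'
#' @param neighbor_id,query_id Character vectors `c(structure_id,
#'   chain_id)`.
#' @param pairs Two-column integer matrix of (neighbor index, query
#'   index), 0-based.
#' @param neighbor_seq,query_seq One-letter sequences of the two
#'   chains.
#' @return An `AlignmentMap`.
#' @export
alignment_map <- function(neighbor_id, query_id, pairs,
                          neighbor_seq, query_seq) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("neighbor", "query")))
  if (nrow(pairs) > 0) {
    if (any(pairs < 0)) stop("alignment indices must be >= 0", call. = FALSE)
    if (max(pairs[, 1]) >= nchar(neighbor_seq)) {
      stop("alignment index ", max(pairs[, 1]), " out of range for ",
           "neighbor chain of length ", nchar(neighbor_seq), call. = FALSE)
    }
    if (max(pairs[, 2]) >= nchar(query_seq)) {
      stop("alignment index ", max(pairs[, 2]), " out of range for ",
           "query chain of length ", nchar(query_seq), call. = FALSE)
    }
    if (any(duplicated(pairs[, 1])) || any(duplicated(pairs[, 2])) ||
        is.unsorted(pairs[, 1], strictly = TRUE) ||
        is.unsorted(pairs[, 2], strictly = TRUE)) {
      stop("alignment pairs must be strictly increasing on both sides ",
           "(colinear, no crossings)", call. = FALSE)
    }
  }
  na <- strsplit(neighbor_seq, "")[[1]]
  qa <- strsplit(query_seq, "")[[1]]
  ident <- if (nrow(pairs) == 0) 0 else
    mean(na[pairs[, 1] + 1] == qa[pairs[, 2] + 1])
  structure(list(neighbor_id = neighbor_id, query_id = query_id,
                 pairs = pairs, neighbor_seq = neighbor_seq,
                 query_seq = query_seq, identity_fraction = ident),
            class = "AlignmentMap")
}

#' Load pairwise alignments from a file
#'
#' Two dialects are accepted: (i) a TSV with columns
#' `neighbor_structure, neighbor_chain, query_structure, query_chain,
#' pairs` where `pairs` is `"i:j;i:j;..."` (0-based indices into
#' [chain_sequence_map()] order), and (ii) aligned FASTA with two
#' records per block (neighbor first, query second), headers
#' `>structure_id:chain_id`, gaps as `-`.
#'
#' @param path Alignment file.
#' @param models Named list of `StructureModel`s (names =
#'   structure ids) used to validate indices and fetch sequences; must
#'   include the query and every neighbour referenced.
#' @param format `"auto"` (TSV if the first non-empty line is not a
#'   FASTA header), `"tsv"` or `"fasta"`.
#' @return List of `AlignmentMap`s in file order.
#' @export
load_alignments <- function(path, models, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    format <- if (startsWith(first, ">")) "fasta" else "tsv"
  }
  get_seq <- function(sid, chain) {
    m <- models[[sid]]
    if (is.null(m)) stop("alignment references unknown structure '", sid,
                         "'", call. = FALSE)
    chain_sequence_map(m, chain)$sequence
  }
  if (format == "tsv") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("neighbor_structure", "neighbor_chain", "query_structure",
              "query_chain", "pairs")
    if (!all(need %in% names(df))) {
      stop("alignment TSV must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    out <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
      r <- df[i, ]
      toks <- strsplit(strsplit(r$pairs, ";", fixed = TRUE)[[1]], ":",
                       fixed = TRUE)
      pm <- matrix(as.integer(unlist(toks)), ncol = 2, byrow = TRUE)
      out[[i]] <- alignment_map(
        c(r$neighbor_structure, r$neighbor_chain),
        c(r$query_structure, r$query_chain), pm,
        get_seq(r$neighbor_structure, r$neighbor_chain),
        get_seq(r$query_structure, r$query_chain))
    }
    return(out)
  }
  # aligned-FASTA pairs
  heads <- grep("^>", lines)
  if (length(heads) %% 2 != 0) {
    stop("aligned-FASTA alignment file must contain record pairs",
         call. = FALSE)
  }
  read_rec <- function(h) {
    stop_at <- c(heads[heads > h], length(lines) + 1)[1] - 1
    id <- strsplit(sub("^>\\s*", "", lines[h]), ":", fixed = TRUE)[[1]]
    list(id = id,
         seq = gsub("\\s", "", paste(lines[seq(h + 1, stop_at)],
                                     collapse = "")))
  }
  out <- list()
  for (b in seq(1, length(heads), by = 2)) {
    n <- read_rec(heads[b]); q <- read_rec(heads[b + 1])
    if (nchar(n$seq) != nchar(q$seq)) {
      stop("aligned-FASTA records differ in length for ",
           lines[heads[b]], call. = FALSE)
    }
    nc <- strsplit(n$seq, "")[[1]]; qc <- strsplit(q$seq, "")[[1]]
    ni <- cumsum(nc != "-") - 1L
    qi <- cumsum(qc != "-") - 1L
    both <- nc != "-" & qc != "-"
    out[[length(out) + 1]] <- alignment_map(
      n$id, q$id, cbind(ni[both], qi[both]),
      get_seq(n$id[1], n$id[2]), get_seq(q$id[1], q$id[2]))
  }
  out
}

#' Global sequence alignment fallback
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gaps, used when
#' no precomputed alignment is supplied for a neighbour. A gap of
#' length L costs `gap_open + L * gap_extend` (both negative).
#' Traceback tie-break is deterministic: diagonal, then up (gap in the
#' query), then left.
#'
#' @param neighbor_seq,query_seq Non-empty one-letter sequences.
#' @param H Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Affine gap parameters (default -11/-1).
#' @param neighbor_id,query_id Optional `c(structure, chain)` labels.
#' @return An `AlignmentMap` with attribute `"score"` (the optimal
#'   global alignment score).
#' @export
align_fallback <- function(neighbor_seq, query_seq, H = blosum62(),
                           gap_open = -11, gap_extend = -1,
                           neighbor_id = c("neighbor", "A"),
                           query_id = c("query", "A")) {
  if (!nzchar(neighbor_seq) || !nzchar(query_seq)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  a <- strsplit(neighbor_seq, "")[[1]]
  b <- strsplit(query_seq, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Iy[1, j + 1] <- gap_open + j * gap_extend
  sub <- matrix(score_pairs(rep(a, times = m), rep(b, each = n), H), n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sub[i, j]
      Ix[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                              Ix[i, j + 1] + gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                              Iy[i + 1, j] + gap_extend)
    }
  }
  # traceback, preferring diagonal (M), then up (Ix), then left (Iy)
  scores <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which(scores == max(scores))[1]
  i <- n; j <- m
  pi <- integer(0); pj <- integer(0)
  while (i > 0 || j > 0) {
    if (state == 1) {
      pi <- c(i - 1L, pi); pj <- c(j - 1L, pj)
      prev <- M[i + 1, j + 1] - sub[i, j]
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- which(abs(cand - prev) < 1e-6)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      state <- if (abs(Ix[i + 1, j + 1] -
                       (M[i, j + 1] + gap_open + gap_extend)) < 1e-6) 1 else 2
      i <- i - 1
    } else {
      state <- if (abs(Iy[i + 1, j + 1] -
                       (M[i + 1, j] + gap_open + gap_extend)) < 1e-6) 1 else 3
      j <- j - 1
    }
    if (i == 0 && j == 0) break
    if (i == 0 && state != 3) state <- 3
    if (j == 0 && state != 2) state <- 2
  }
  am <- alignment_map(neighbor_id, query_id, cbind(pi, pj),
                      neighbor_seq, query_seq)
  attr(am, "score") <- max(scores)
  am
}

#' Filter structure neighbours by sequence identity
#'
#' Keeps alignments whose identity over aligned columns is at least
#' `min_identity`. Redundant (even 100% identical) neighbours are
#' deliberately kept: the same protein bound to different partners is
#' informative.
#'
#' @param alignments List of `AlignmentMap`s.
#' @param min_identity Fraction in 0..1, default 0.30.
#' @return Filtered list; excluded maps are reported in attribute
#'   `"excluded"` as a data frame of ids and identities.
#' @export
filter_neighbors <- function(alignments, min_identity = 0.30) {
  keep <- vapply(alignments, function(a) {
    a$identity_fraction >= min_identity
  }, logical(1))
  out <- alignments[keep]
  dropped <- alignments[!keep]
  attr(out, "excluded") <- data.frame(
    neighbor = vapply(dropped, function(a)
      paste(a$neighbor_id, collapse = ":"), ""),
    identity = vapply(dropped, `[[`, 0, "identity_fraction"),
    reason = if (length(dropped)) sprintf("identity below %.2f threshold",
                                          min_identity) else character(0),
    stringsAsFactors = FALSE)
  out
}

#' Compose two alignments through the shared query
#'
#' Given maps A->query and B->query, returns the A->B correspondence:
#' (i, k) is present iff A's i and B's k align to the same query
#' position. Composition through the query (rather than a direct A-B
#' alignment) keeps only query-relevant columns.
#'
#' @param a_map,b_map `AlignmentMap`s onto the same query chain.
#' @return An `AlignmentMap` from A's chain onto B's chain.
#' @export
compose_alignment <- function(a_map, b_map) {
  if (!identical(a_map$query_id, b_map$query_id)) {
    stop("cannot compose alignments with different query chains: ",
         paste(a_map$query_id, collapse = ":"), " vs ",
         paste(b_map$query_id, collapse = ":"), call. = FALSE)
  }
  common <- intersect(a_map$pairs[, 2], b_map$pairs[, 2])
  ai <- a_map$pairs[match(common, a_map$pairs[, 2]), 1]
  bi <- b_map$pairs[match(common, b_map$pairs[, 2]), 1]
  ord <- order(ai)
  alignment_map(a_map$neighbor_id, b_map$neighbor_id,
                cbind(ai[ord], bi[ord]),
                a_map$neighbor_seq, b_map$neighbor_seq)
}

#' Project a neighbour binding site onto the query
#'
#' Maps the site's residues through the neighbour-to-query alignment;
#' the site is rejected (returns `NULL`) when fewer than `min_aligned`
#' of its residues have a query image.
#'
#' @param site A `BindingSite` on the neighbour chain of `aln`.
#' @param aln `AlignmentMap` from the neighbour chain to the query.
#' @param neighbor_model,query_model The two `StructureModel`s.
#' @param min_aligned Minimum aligned fraction, default 0.75.
#' @return A `MappedSite` (list with `site_id`, `member_id`,
#'   `partner_family`, `query_idx` 0-based, `query_residue_keys`, `res`
#'   = neighbour residues at the mapped positions, `aligned_fraction`,
#'   `pcnt` = full-alignment identity, `total_contacts`, `profile` =
#'   neighbour residue per query position over the whole alignment), or
#'   a `RejectedSite` (list with `reason`) when the aligned fraction
#'   falls below the threshold.
#' @export
map_site_to_query <- function(site, aln, neighbor_model, query_model,
                              min_aligned = 0.75) {
  nmap <- chain_sequence_map(neighbor_model, aln$neighbor_id[2])
  qmap <- chain_sequence_map(query_model, aln$query_id[2])
  idx <- match(site$residue_keys, nmap$keys) - 1L
  if (anyNA(idx)) {
    stop("binding site residue(s) not found on neighbor chain ",
         paste(aln$neighbor_id, collapse = ":"), ": ",
         paste(site$residue_keys[is.na(idx)], collapse = ","),
         call. = FALSE)
  }
  hit <- match(idx, aln$pairs[, 1])
  qidx <- aln$pairs[hit[!is.na(hit)], 2]
  frac <- length(qidx) / length(idx)
  if (frac < min_aligned) {
    return(structure(list(reason = sprintf(
      "aligned fraction %.3f below %.2f", frac, min_aligned)),
      class = "RejectedSite"))
  }
  ord <- order(qidx)
  qidx <- qidx[ord]
  naa <- strsplit(aln$neighbor_seq, "")[[1]]
  site_res <- naa[idx[!is.na(hit)] + 1][ord]
  profile <- rep(NA_character_, nchar(aln$query_seq))
  profile[aln$pairs[, 2] + 1] <- naa[aln$pairs[, 1] + 1]
  structure(list(
    site_id = paste0(paste(aln$neighbor_id, collapse = ":"), "|",
                     site$owner_domain, ">", site$partner_domain),
    member_id = paste(aln$neighbor_id, collapse = ":"),
    query_id = paste(aln$query_id, collapse = ":"),
    partner_family = site$partner_family,
    query_idx = qidx,
    query_residue_keys = qmap$keys[qidx + 1],
    res = site_res,
    aligned_fraction = frac,
    pcnt = aln$identity_fraction,
    total_contacts = site$total_contacts,
    profile = profile), class = "MappedSite")
}
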