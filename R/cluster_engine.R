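#' Binding-site similarity scoring parameters
#'
#' @param H Substitution matrix (default [blosum62()]).
#' @param position_bonus Bonus added at every aligned (non-gap) column;
#'   rewards positional equivalence even between dissimilar residues.
#'   Default +1.
#' @param gap_penalty Score of a column where either site lacks the
#'   query position. Default -4.
#' @param lambda,K Statistical parameters converting raw scores to bit
#'   scores; defaults are the ungapped BLOSUM62 values (0.3176 nats,
#'   0.134).
#' @return A `ScoringParams` list.
#' @export
scoring_params <- function(H = blosum62(), position_bonus = 1L,
                           gap_penalty = -4L, lambda = 0.3176, K = 0.134) {
  stopifnot(lambda > 0, K > 0, K < 1, isSymmetric(unname(H)))
  structure(list(H = H, position_bonus = as.integer(position_bonus),
                 gap_penalty = as.integer(gap_penalty),
                 lambda = lambda, K = K), class = "ScoringParams")
}

#' Build the gapped pairwise alignment of two mapped binding sites
#'
#' Columns are the union of the two sites' query positions in query
#' order; a site contributes its residue where it covers the position
#' and a gap (`-`) otherwise. `delta` is 1 at columns where both sides
#' have a residue, 0 otherwise; no column is gapped on both sides.
#'
#' @param site_a,site_b `MappedSite`s on the same query chain.
#' @return An `AlignedSitePair`: list with `columns` (0-based query
#'   indices), `a`, `b` (character vectors with `-` gaps), `delta`.
#' @export
build_site_pair <- function(site_a, site_b) {
  if (!identical(site_a$query_id, site_b$query_id)) {
    stop("sites are mapped onto different queries: ",
         site_a$query_id, " vs ", site_b$query_id, call. = FALSE)
  }
  cols <- sort(union(site_a$query_idx, site_b$query_idx))
  pick <- function(site) {
    out <- rep("-", length(cols))
    hit <- match(site$query_idx, cols)
    out[hit] <- site$res
    out
  }
  a <- pick(site_a); b <- pick(site_b)
  structure(list(columns = cols, a = a, b = b,
                 delta = as.integer(a != "-" & b != "-")),
            class = "AlignedSitePair")
}

#' Raw similarity score of an aligned site pair
#'
#' Sum over columns of `delta * (H(a, b) + position_bonus) +
#' (1 - delta) * gap_penalty`: aligned columns score their substitution
#' value plus the position bonus, gapped columns score the gap penalty
#' instead.
#'
#' @param pair An `AlignedSitePair`.
#' @param params A [scoring_params()] object.
#' @return Integer raw score.
#' @export
raw_similarity <- function(pair, params = scoring_params()) {
  d <- pair$delta
  s <- integer(length(d))
  if (any(d == 1)) {
    s[d == 1] <- score_pairs(pair$a[d == 1], pair$b[d == 1], params$H) +
      params$position_bonus
  }
  s[d == 0] <- params$gap_penalty
  sum(s)
}

#' Convert a raw similarity score to a bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`.
#'
#' @param raw Raw score (integer).
#' @param params A [scoring_params()] object.
#' @return Bit score (double).
#' @export
to_bits <- function(raw, params = scoring_params()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

self_bits <- function(site, params) {
  raw <- sum(score_pairs(site$res, site$res, params$H) +
               params$position_bonus)
  to_bits(raw, params)
}

#' Normalized similarity between two mapped binding sites
#'
#' The pair bit score divided by the larger of the two self bit scores
#' (each site aligned to itself, no gaps), so that identical sites
#' score exactly 1 and scores from different interface alignments are
#' comparable.
#'
#' @inheritParams build_site_pair
#' @param params A [scoring_params()] object.
#' @return `S_norm` in (-Inf, 1].
#' @export
normalized_similarity <- function(site_a, site_b,
                                  params = scoring_params()) {
  denom <- max(self_bits(site_a, params), self_bits(site_b, params))
  if (denom <= 0) {
    stop("degenerate site: non-positive self bit score", call. = FALSE)
  }
  to_bits(raw_similarity(build_site_pair(site_a, site_b), params),
          params) / denom
}

#' Pairwise normalized-similarity matrix over mapped sites
#'
#' @param sites List of `MappedSite`s on one query.
#' @param params A [scoring_params()] object.
#' @return A `SimilarityMatrix`: list with `site_ids`, symmetric `S`
#'   with unit diagonal, and `N`.
#' @export
similarity_matrix <- function(sites, params = scoring_params()) {
  n <- length(sites)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        S[i, j] <- S[j, i] <- normalized_similarity(sites[[i]], sites[[j]],
                                                    params)
      }
    }
  }
  ids <- vapply(sites, `[[`, "", "site_id")
  dimnames(S) <- list(ids, ids)
  structure(list(site_ids = ids, S = S, N = n), class = "SimilarityMatrix")
}

#' Complete-linkage clustering of binding sites
#'
#' Hierarchical clustering where the distance between two clusters is
#' the maximum distance between their members (`stats::hclust`,
#' `method = "complete"`), on `d = 1 - S_norm`.
#'
#' @param dist_matrix Symmetric distance matrix with zero diagonal.
#' @return A `homsite_dendrogram`: list with the `hclust` object (or
#'   `NULL` for N = 1), `n`, `heights` and `labels`.
#' @export
complete_linkage <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (!isSymmetric(unname(dist_matrix), tol = 1e-9) ||
      any(abs(diag(dist_matrix)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  n <- nrow(dist_matrix)
  if (n == 1) {
    return(structure(list(hc = NULL, n = 1L, heights = numeric(0),
                          labels = rownames(dist_matrix)),
                     class = "homsite_dendrogram"))
  }
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "complete")
  structure(list(hc = hc, n = n, heights = hc$height,
                 labels = rownames(dist_matrix)),
            class = "homsite_dendrogram")
}

partition_f <- function(assign, S, temperature) {
  n <- length(assign)
  f <- 0
  for (cl in unique(assign)) {
    members <- which(assign == cl)
    k <- length(members)
    sbar <- if (k == 1) 1 else {
      sub <- S[members, members, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }
    p <- k / n
    f <- f + p * sbar + temperature * p * log(p)
  }
  f
}

#' Select the dendrogram cut with a pseudo-free-energy functional
#'
#' Every distinct cut of the complete-linkage dendrogram (1..N
#' clusters) is scored with
#' `F = sum_C (|C|/N) * sbar_C + T * sum_C (|C|/N) * ln(|C|/N)`, where
#' `sbar_C` is the mean pairwise normalized similarity within cluster C
#' (1 for singletons): the first term favours tight clusters, the
#' second (entropy-like, always <= 0) penalises fragmenting the
#' description. The cut maximising F wins; ties go to fewer clusters.
#'
#' @param dend A [complete_linkage()] result.
#' @param sim A [similarity_matrix()] result over the same sites.
#' @param temperature Balance constant T, default 0.05.
#' @return A `ClusterPartition`: list with `clusters` (list of integer
#'   member-index vectors), `assignment`, `site_ids`, `N`, `cutoff`,
#'   `temperature`, `F`.
#' @export
select_partition <- function(dend, sim, temperature = 0.05) {
  n <- sim$N
  if (n == 1) {
    return(structure(list(clusters = list(1L), assignment = 1L,
                          site_ids = sim$site_ids, N = 1L, cutoff = 0,
                          temperature = temperature, F = 1),
                     class = "ClusterPartition"))
  }
  best <- NULL
  heights <- sort(dend$heights)
  for (k in seq_len(n)) {
    assign <- stats::cutree(dend$hc, k = k)
    f <- partition_f(assign, sim$S, temperature)
    # iterate k upward and require strict improvement: ties keep fewer
    # clusters
    if (is.null(best) || f > best$F + 1e-12) {
      cutoff <- if (k == n) 0 else heights[n - k]
      best <- list(assign = assign, F = f, k = k, cutoff = cutoff)
    }
  }
  clusters <- lapply(sort(unique(best$assign)),
                     function(cl) which(best$assign == cl))
  structure(list(clusters = clusters, assignment = unname(best$assign),
                 site_ids = sim$site_ids, N = as.integer(n),
                 cutoff = best$cutoff, temperature = temperature,
                 F = best$F), class = "ClusterPartition")
}
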