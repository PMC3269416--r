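#' Run configuration for the inference pipeline
#'
#' Bundles every tunable threshold of the method with its default:
#' contact radius 4 Angstrom / 5 contacting residues, 30% minimum
#' neighbour identity, 75% minimum aligned site fraction, BLOSUM62
#' scoring with +1 position bonus and -4 gap penalty, clustering
#' temperature 0.05, 90% redundancy identity, unit ranking weights.
#'
#' @param contact [contact_params()].
#' @param min_identity Neighbour identity threshold (default 0.30).
#' @param min_aligned Site aligned-fraction threshold (default 0.75).
#' @param scoring [scoring_params()].
#' @param temperature Cluster-selection temperature (default 0.05).
#' @param redundancy_identity Conserved/singleton threshold (default
#'   0.90).
#' @param weights Ranking weights for (conserv, contact, pssm, pcnt).
#' @param query_chain Query chain id (`NULL` = first chain).
#' @return A `RunConfig` list.
#' @export
run_config <- function(contact = contact_params(), min_identity = 0.30,
                       min_aligned = 0.75, scoring = scoring_params(),
                       temperature = 0.05, redundancy_identity = 0.90,
                       weights = c(1, 1, 1, 1), query_chain = NULL) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_aligned >= 0, min_aligned <= 1,
            temperature >= 0, redundancy_identity > 0,
            redundancy_identity <= 1, length(weights) == 4)
  structure(list(contact = contact, min_identity = min_identity,
                 min_aligned = min_aligned, scoring = scoring,
                 temperature = temperature,
                 redundancy_identity = redundancy_identity,
                 weights = weights, query_chain = query_chain),
            class = "RunConfig")
}

#' Infer binding sites on a query from homologous complexes
#'
#' Full pipeline: read structures, load (or compute) alignments, filter
#' neighbours by identity, extract every domain-domain interface in
#' every neighbour, project sites onto the query (aligned-fraction
#' filter), score pairwise site similarity, cluster by complete linkage
#' with the pseudo-free-energy cut, classify conserved vs singleton and
#' rank. The query's own observed interfaces, if any, enter as
#' neighbours at identity 1.
#'
#' @param query_path Query structure file (PDB/mmCIF).
#' @param neighbor_paths Character vector of neighbour structure files.
#' @param alignments Alignment file path (TSV or aligned-FASTA; see
#'   [load_alignments()]), or `NULL` to compute global-alignment
#'   fallbacks for every neighbour chain.
#' @param domains Domain TSV path or `NULL` (whole chains).
#' @param config A [run_config()].
#' @return An `AnnotationReport`: list with `query_id`, `status`,
#'   `ranking` (data frame), `clusters` (list: site ids per cluster),
#'   `sites` (the mapped sites), `partition`, `provenance`, `log`,
#'   `config`.
#' @export
run_inference <- function(query_path, neighbor_paths, alignments = NULL,
                          domains = NULL, config = run_config()) {
  query <- read_structure(query_path)
  qchain <- if (is.null(config$query_chain)) names(query$chains)[1]
            else config$query_chain
  qmap <- chain_sequence_map(query, qchain)
  neighbors <- list()
  for (p in neighbor_paths) {
    m <- read_structure(p)
    neighbors[[m$structure_id]] <- m
  }
  models <- neighbors
  models[[query$structure_id]] <- query
  log_lines <- character(0)

  alns <- if (is.null(alignments)) {
    out <- list()
    for (m in neighbors) {
      for (ch in names(m$chains)) {
        out[[length(out) + 1]] <- align_fallback(
          chain_sequence_map(m, ch)$sequence, qmap$sequence,
          H = config$scoring$H,
          neighbor_id = c(m$structure_id, ch),
          query_id = c(query$structure_id, qchain))
      }
    }
    out
  } else {
    load_alignments(alignments, models)
  }
  # the query's own observed interfaces ride on an identity self-map
  self_map <- alignment_map(
    c(query$structure_id, qchain), c(query$structure_id, qchain),
    cbind(seq_len(nchar(qmap$sequence)) - 1L,
          seq_len(nchar(qmap$sequence)) - 1L),
    qmap$sequence, qmap$sequence)
  alns[[length(alns) + 1]] <- self_map

  kept <- filter_neighbors(alns, config$min_identity)
  excl <- attr(kept, "excluded")
  if (nrow(excl)) {
    log_lines <- c(log_lines, sprintf("filtered neighbor %s: %s",
                                      excl$neighbor, excl$reason))
  }
  aln_index <- stats::setNames(
    kept, vapply(kept, function(a) paste(a$neighbor_id, collapse = ":"), ""))

  empty_report <- function(status) {
    structure(list(query_id = paste0(query$structure_id, ":", qchain),
                   status = status,
                   ranking = NULL, clusters = list(), sites = list(),
                   partition = NULL,
                   provenance = data.frame(
                     neighbor = character(), identity = numeric(),
                     stringsAsFactors = FALSE),
                   log = log_lines, config = config),
              class = "AnnotationReport")
  }
  n_nonself <- sum(vapply(kept, function(a)
    !identical(a$neighbor_id, a$query_id), logical(1)))

  sites <- list()
  for (m in c(neighbors, list(query))) {
    doms <- apply_domains(m, domains)
    if (length(doms) < 2) next
    ints <- enumerate_interactions(m, doms, config$contact)
    for (ia in ints) {
      for (side in c("site_a", "site_b")) {
        st <- ia[[side]]
        key <- paste(m$structure_id, st$owner_chain, sep = ":")
        aln <- aln_index[[key]]
        if (is.null(aln)) {
          log_lines <- c(log_lines, sprintf(
            "site %s>%s on %s: no retained alignment for owner chain",
            st$owner_domain, st$partner_domain, key))
          next
        }
        ms <- map_site_to_query(st, aln, m, query, config$min_aligned)
        if (inherits(ms, "RejectedSite")) {
          log_lines <- c(log_lines, sprintf(
            "site %s>%s on %s rejected: %s", st$owner_domain,
            st$partner_domain, key, ms$reason))
          next
        }
        sites[[length(sites) + 1]] <- ms
      }
    }
  }
  if (length(sites) == 0) {
    status <- if (length(neighbors) == 0) "no neighbor library supplied"
      else if (n_nonself == 0) "no homologous complexes above threshold"
      else "no mappable binding sites"
    return(empty_report(status))
  }

  sim <- similarity_matrix(sites, config$scoring)
  dend <- complete_linkage(1 - sim$S)
  part <- select_partition(dend, sim, config$temperature)

  comp_rows <- list()
  cluster_sites <- list()
  for (ci in seq_along(part$clusters)) {
    idx <- part$clusters[[ci]]
    csites <- sites[idx]
    cluster_sites[[ci]] <- vapply(csites, `[[`, "", "site_id")
    profiles <- lapply(csites, `[[`, "profile")
    names(profiles) <- vapply(csites, `[[`, "", "member_id")
    cls <- classify_cluster(profiles, config$redundancy_identity)
    caln <- cluster_alignment(csites, qmap$sequence)
    pssm <- build_pssm(caln$rows, caln$weights, config$scoring$H)
    qrow <- caln$query_row[attr(pssm, "kept")]
    keys <- qmap$keys[caln$columns + 1]
    comp_rows[[ci]] <- data.frame(
      cluster_id = sprintf("C%02d", ci), label = cls$label,
      n_members = length(csites), n_nonredundant = cls$n_nonredundant,
      conserv = conservation_score(caln$rows, caln$weights),
      contact = mean(vapply(csites, `[[`, 0, "total_contacts")),
      pssm = score_query(pssm, qrow),
      pcnt = mean(vapply(csites, `[[`, 0, "pcnt")),
      partner_family = paste(sort(unique(vapply(
        csites, `[[`, "", "partner_family"))), collapse = ","),
      query_site_residues = paste(keys, collapse = ","),
      stringsAsFactors = FALSE)
  }
  comps <- do.call(rbind, comp_rows)
  ranking <- rank_clusters(comps, config$weights)
  names(cluster_sites) <- comps$cluster_id

  structure(list(
    query_id = paste0(query$structure_id, ":", qchain),
    status = "ok",
    ranking = ranking,
    clusters = cluster_sites,
    sites = sites,
    partition = part,
    provenance = data.frame(
      neighbor = vapply(kept, function(a)
        paste(a$neighbor_id, collapse = ":"), ""),
      identity = vapply(kept, `[[`, 0, "identity_fraction"),
      stringsAsFactors = FALSE),
    log = log_lines,
    config = config), class = "AnnotationReport")
}

#' @export
print.AnnotationReport <- function(x, ...) {
  cat("AnnotationReport for", x$query_id, "- status:", x$status, "\n")
  if (!is.null(x$ranking)) {
    cols <- c("rank", "cluster_id", "label", "n_members",
              "n_nonredundant", "combined", "query_site_residues")
    print(x$ranking[, cols], digits = 4)
  }
  invisible(x)
}

#' Overlap fraction between predicted and reference residue sets
#'
#' `|predicted intersect reference| / |predicted|`; the prediction is a
#' true positive when strictly more than half of its residues fall in
#' the reference set. A symmetric Jaccard variant is available.
#'
#' @param predicted,reference Character vectors of residue keys in the
#'   same key space.
#' @param denominator `"predicted"` (default) or `"jaccard"`.
#' @return List with `fraction` and `tp`.
#' @export
overlap_fraction <- function(predicted, reference,
                             denominator = c("predicted", "jaccard")) {
  denominator <- match.arg(denominator)
  if (length(predicted) == 0) {
    stop("overlap fraction undefined for an empty predicted set",
         call. = FALSE)
  }
  inter <- length(intersect(predicted, reference))
  frac <- if (denominator == "predicted") inter / length(predicted)
          else inter / length(union(predicted, reference))
  list(fraction = frac, tp = frac > 0.5)
}

report_cluster_keys <- function(report) {
  lapply(seq_len(nrow(report$ranking)), function(i)
    strsplit(report$ranking$query_site_residues[i], ",", fixed = TRUE)[[1]])
}

#' Evaluate a run against reference binding sites
#'
#' Scores the report's clusters against labelled truth at the
#' interaction level (each predicted cluster is a true positive when it
#' overlaps a reference site by more than half of its residues) and at
#' the residue level (set arithmetic over residue keys), in two
#' variants: all clusters, and conserved clusters only.
#'
#' @param report An `AnnotationReport`.
#' @param reference_sites List of residue-key vectors: the true
#'   (biological) binding sites on the query.
#' @param negative_sites List of residue-key vectors for known
#'   non-biological (e.g. crystal-packing) sites; may be empty.
#' @param query_keys All residue keys of the query chain (for
#'   residue-level true negatives).
#' @return Nested list `$interaction` / `$residue`, each with
#'   `$all_clusters` and `$conserved_only` holding `sensitivity`,
#'   `specificity`, `precision` (and the underlying counts).
#' @export
evaluate_run <- function(report, reference_sites, negative_sites = list(),
                         query_keys) {
  stopifnot(inherits(report, "AnnotationReport"))
  if (is.null(report$ranking)) {
    stop("cannot evaluate an empty report (status: ", report$status, ")",
         call. = FALSE)
  }
  pred_all <- report_cluster_keys(report)
  labels <- report$ranking$label
  variants <- list(all_clusters = seq_along(pred_all),
                   conserved_only = which(labels == "conserved"))
  ref_union <- unique(unlist(reference_sites))
  out <- list(interaction = list(), residue = list())
  for (v in names(variants)) {
    preds <- pred_all[variants[[v]]]
    # interaction level
    hit_ref <- vapply(reference_sites, function(ref)
      any(vapply(preds, function(p)
        overlap_fraction(p, ref)$tp, logical(1))), logical(1))
    cl_tp <- vapply(preds, function(p)
      any(vapply(reference_sites, function(ref)
        overlap_fraction(p, ref)$tp, logical(1))), logical(1))
    neg_hit <- vapply(negative_sites, function(ng)
      any(vapply(preds, function(p)
        overlap_fraction(p, ng)$tp, logical(1))), logical(1))
    TPi <- sum(hit_ref); FNi <- sum(!hit_ref)
    FPi <- sum(!cl_tp); TNi <- sum(!neg_hit)
    out$interaction[[v]] <- list(
      TP = TPi, FN = FNi, FP = FPi, TN = TNi,
      sensitivity = TPi / (TPi + FNi),
      specificity = if (FPi + TNi > 0) 1 - FPi / (FPi + TNi) else NA_real_,
      precision = if (sum(cl_tp) + FPi > 0)
        sum(cl_tp) / (sum(cl_tp) + FPi) else NA_real_)
    # residue level
    pred_union <- unique(unlist(preds))
    TP <- length(intersect(pred_union, ref_union))
    FP <- length(setdiff(pred_union, ref_union))
    FN <- length(setdiff(ref_union, pred_union))
    TN <- length(setdiff(query_keys, union(pred_union, ref_union)))
    out$residue[[v]] <- list(
      TP = TP, FP = FP, FN = FN, TN = TN,
      sensitivity = TP / (TP + FN),
      specificity = 1 - FP / (FP + TN),
      precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_)
  }
  out
}

#' Write the report files of a run
#'
#' Emits `ranking.tsv` (the ranking table), `clusters.tsv` (cluster
#' membership), `provenance.tsv` (retained neighbours and identities)
#' and `run.log`. Output is deterministic: identical inputs and config
#' produce byte-identical files.
#'
#' @param report An `AnnotationReport`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, path) {
    con <- file(path, "wb")
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    close(con)
  }
  if (!is.null(report$ranking)) {
    rk <- report$ranking
    for (nm in c("conserv", "contact", "pssm", "pcnt", "z_conserv",
                 "z_contact", "z_pssm", "z_pcnt", "combined")) {
      rk[[nm]] <- sprintf("%.6f", rk[[nm]])
    }
    wt(rk[, c("rank", "cluster_id", "label", "n_members",
              "n_nonredundant", "z_conserv", "z_contact", "z_pssm",
              "z_pcnt", "combined", "query_site_residues",
              "partner_family")], file.path(dir, "ranking.tsv"))
    mem <- do.call(rbind, lapply(names(report$clusters), function(cid)
      data.frame(cluster_id = cid, site_id = report$clusters[[cid]],
                 stringsAsFactors = FALSE)))
    wt(mem, file.path(dir, "clusters.tsv"))
  }
  prov <- report$provenance
  prov$identity <- sprintf("%.6f", prov$identity)
  wt(prov, file.path(dir, "provenance.tsv"))
  con <- file(file.path(dir, "run.log"), "wb")
  writeLines(c(paste("query:", report$query_id),
               paste("status:", report$status), report$log), con)
  close(con)
  invisible(dir)
}
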