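#' Contact detection parameters
#'
#' @param radius Heavy-atom distance cutoff in Angstrom (inclusive
#'   boundary). Default 4.0.
#' @param min_residues Minimum number of contacting residues on at
#'   least one side for a domain pair to count as an interaction.
#'   Default 5.
#' @param contact_count Whether `total_contacts` counts contacting
#'   residue pairs (`"residue"`, default) or atom pairs (`"atom"`).
#' @return A `ContactParams` list.
#' @export
contact_params <- function(radius = 4.0, min_residues = 5L,
                           contact_count = c("residue", "atom")) {
  stopifnot(radius > 0, min_residues >= 1)
  structure(list(radius = radius, min_residues = as.integer(min_residues),
                 contact_count = match.arg(contact_count)),
            class = "ContactParams")
}

domain_atoms <- function(domain, model) {
  model$atoms[model$atoms$chain == domain$chain_id &
              model$atoms$key %in% domain$residue_keys, , drop = FALSE]
}

#' Residue-level contacts between two domains
#'
#' A residue pair (one residue from each domain) is in contact when the
#' minimum over their heavy-atom pairs of the Euclidean distance is at
#' or below the contact radius.
#'
#' @param domain_a,domain_b `DomainInstance`s with disjoint residue
#'   sets (they may share a chain).
#' @param model The `StructureModel` holding both domains.
#' @param params A [contact_params()] object.
#' @return Data frame with columns `key_a`, `key_b` (residue keys),
#'   `n_atom_pairs` (atom pairs within the radius for that residue
#'   pair), deduplicated and ordered by (`key_a`, `key_b`).
#' @export
residue_contacts <- function(domain_a, domain_b, model,
                             params = contact_params()) {
  if (domain_a$chain_id == domain_b$chain_id &&
      length(intersect(domain_a$residue_keys, domain_b$residue_keys)) > 0) {
    stop("invalid domain pair: residue sets overlap (",
         domain_a$domain_id, ", ", domain_b$domain_id, ")", call. = FALSE)
  }
  at_a <- domain_atoms(domain_a, model)
  at_b <- domain_atoms(domain_b, model)
  empty <- data.frame(key_a = character(), key_b = character(),
                      n_atom_pairs = integer(), stringsAsFactors = FALSE)
  if (nrow(at_a) == 0 || nrow(at_b) == 0) return(empty)
  xa <- as.matrix(at_a[, c("x", "y", "z")])
  xb <- as.matrix(at_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rep(1, nrow(xb))) +
    outer(rep(1, nrow(xa)), rowSums(xb^2)) - 2 * tcrossprod(xa, xb)
  hit <- which(d2 <= params$radius^2 + 1e-9, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  pairs <- data.frame(key_a = at_a$key[hit[, 1]], key_b = at_b$key[hit[, 2]],
                      stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n_atom_pairs = rep(1L, nrow(pairs))),
                          by = pairs, FUN = sum)
  ord_a <- match(agg$key_a, domain_a$residue_keys)
  ord_b <- match(agg$key_b, domain_b$residue_keys)
  agg <- agg[order(ord_a, ord_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Extract an interaction (pair of binding sites) between two domains
#'
#' An interaction exists when at least one side has at least
#' `min_residues` distinct contacting residues. Both binding sites are
#' populated from the full contact list.
#'
#' @inheritParams residue_contacts
#' @return An `InteractionPair` (list with `site_a`, `site_b`, `homo`)
#'   or `NULL` when the threshold is not met. Each site is a
#'   `BindingSite`: `owner_domain`, `partner_domain`, `owner_chain`,
#'   `partner_family`, `residue_keys`, `contacts_per_residue`,
#'   `total_contacts`.
#' @export
extract_interaction <- function(domain_a, domain_b, model,
                                params = contact_params()) {
  cts <- residue_contacts(domain_a, domain_b, model, params)
  if (nrow(cts) == 0) return(NULL)
  keys_a <- unique(cts$key_a)
  keys_b <- unique(cts$key_b)
  if (length(keys_a) < params$min_residues &&
      length(keys_b) < params$min_residues) return(NULL)
  total <- if (params$contact_count == "atom") sum(cts$n_atom_pairs)
           else nrow(cts)
  mk_site <- function(owner, partner, keys, ckeys) {
    keys <- keys[order(match(keys, owner$residue_keys))]
    cpr <- table(factor(ckeys, levels = keys))
    structure(list(
      owner_domain = owner$domain_id, partner_domain = partner$domain_id,
      owner_chain = owner$chain_id, partner_family = partner$family_id,
      residue_keys = keys,
      contacts_per_residue = stats::setNames(as.integer(cpr), keys),
      total_contacts = total), class = "BindingSite")
  }
  structure(list(
    site_a = mk_site(domain_a, domain_b, keys_a, cts$key_a),
    site_b = mk_site(domain_b, domain_a, keys_b, cts$key_b),
    homo = identical(domain_a$family_id, domain_b$family_id)),
    class = "InteractionPair")
}

#' Enumerate all domain-domain interactions in a model
#'
#' Tests every unordered domain pair (inter- and intra-chain).
#'
#' @param model A `StructureModel`.
#' @param domains List of `DomainInstance`s (see [apply_domains()]).
#' @param params A [contact_params()] object.
#' @return List of `InteractionPair`s ordered by
#'   (`domain_id_a`, `domain_id_b`).
#' @export
enumerate_interactions <- function(model, domains,
                                   params = contact_params()) {
  if (length(domains) < 2) {
    stop("need at least 2 domains to enumerate interactions", call. = FALSE)
  }
  ids <- vapply(domains, `[[`, "", "domain_id")
  domains <- domains[order(ids)]
  out <- list()
  n <- length(domains)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ia <- extract_interaction(domains[[i]], domains[[j]], model, params)
      if (!is.null(ia)) out[[length(out) + 1]] <- ia
    }
  }
  out
}

#' Write an interaction report TSV
#'
#' @param interactions List of `InteractionPair`s.
#' @param structure_id Structure identifier for the report rows.
#' @param path Output TSV path.
#' @return The report data frame, invisibly (also written to `path` if
#'   given).
#' @export
interaction_report <- function(interactions, structure_id, path = NULL) {
  rows <- lapply(interactions, function(ia) {
    data.frame(
      structure_id = structure_id,
      domain_a = ia$site_a$owner_domain, domain_b = ia$site_b$owner_domain,
      homo = ia$homo,
      n_residues_a = length(ia$site_a$residue_keys),
      n_residues_b = length(ia$site_b$residue_keys),
      total_contacts = ia$site_a$total_contacts,
      residues_a = paste(ia$site_a$residue_keys, collapse = ","),
      residues_b = paste(ia$site_b$residue_keys, collapse = ","),
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(), domain_a = character(),
               domain_b = character(), homo = logical(),
               n_residues_a = integer(), n_residues_b = integer(),
               total_contacts = integer(), residues_a = character(),
               residues_b = character(), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(df)
}
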