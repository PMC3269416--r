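#' Specification of a synthetic homolog family
#'
#' Describes a family of toy dimer complexes sharing planted binding
#' modes. Members descend from a common random ancestor, mutated
#' i.i.d. per site at `mutation_rate`, except at planted interface
#' columns which mutate at `mutation_rate / 4` (binding sites are the
#' conserved part the method relies on). Member `j` exhibits binding
#' mode `((j - 1) mod n_modes) + 1`. Geometry is a 2-pseudo-atom
#' (CA/CB) straight-chain layout: partner atoms of planted interface
#' residues sit within 3.5 Angstrom, every other inter-chain residue
#' pair is at least 6 Angstrom apart.
#'
#' @param n_members Number of family members (dimers). Default 8.
#' @param chain_length Residues per chain. Default 60.
#' @param binding_modes List of 0-based residue-index vectors. Default
#'   two modes: indices 10..17 (8 residues) and 35..43 (9 residues).
#' @param mutation_rate Per-site substitution probability in (0, 1).
#'   Default 0.1.
#' @param iface_rate_ratio Ratio of the mutation rate applied at
#'   planted interface columns to `mutation_rate`. Default 0: planted
#'   interfaces are strictly conserved across the family, emulating the
#'   binding-site conservation among close homologs that the inference
#'   method assumes. At the toy site sizes generated here (8-9
#'   residues), even a single interface substitution shifts the
#'   normalized site similarity by more than the clustering temperature
#'   tolerates, so a non-zero ratio produces families whose planted
#'   modes are no longer guaranteed to cluster as single modes.
#' @param seed Integer RNG seed; all outputs are a deterministic
#'   function of it.
#' @param decoy_packing Add one extra member carrying a one-off
#'   crystal-packing-like interface. Default `FALSE`.
#' @param decoy_residues 0-based indices of the decoy interface,
#'   disjoint from all modes. Default 48..53.
#' @return A `FamilySpec` list.
#' @export
family_spec <- function(n_members = 8L, chain_length = 60L,
                        binding_modes = list(10:17, 35:43),
                        mutation_rate = 0.1, iface_rate_ratio = 0,
                        seed = 1L, decoy_packing = FALSE,
                        decoy_residues = 48:53) {
  stopifnot(n_members >= 1, chain_length >= 10,
            mutation_rate >= 0, mutation_rate < 1,
            iface_rate_ratio >= 0, iface_rate_ratio <= 1)
  for (m in binding_modes) {
    if (any(m < 0) || any(m >= chain_length)) {
      stop("binding modes must be subsets of [0, chain_length)",
           call. = FALSE)
    }
  }
  structure(list(n_members = as.integer(n_members),
                 chain_length = as.integer(chain_length),
                 binding_modes = lapply(binding_modes, as.integer),
                 mutation_rate = mutation_rate,
                 iface_rate_ratio = iface_rate_ratio,
                 seed = as.integer(seed),
                 decoy_packing = isTRUE(decoy_packing),
                 decoy_residues = as.integer(decoy_residues)),
            class = "FamilySpec")
}

mutate_seq <- function(anc, rates) {
  hit <- stats::runif(length(anc)) < rates
  if (any(hit)) {
    anc[hit] <- vapply(anc[hit], function(a)
      sample(setdiff(.AA20, a), 1), "")
  }
  anc
}

# draw a member sequence, redrawing (bounded) until it is non-redundant
# (< 90% identity) to every previously drawn member, so that the
# family's expected "conserved" cluster labels hold by construction
draw_member <- function(anc, rates, prior, max_tries = 100L) {
  if (max(rates) == 0) return(mutate_seq(anc, rates))
  for (t in seq_len(max_tries)) {
    s <- mutate_seq(anc, rates)
    if (all(vapply(prior, function(p) mean(s == p) < 0.90, logical(1)))) {
      return(s)
    }
  }
  stop("could not draw a non-redundant member sequence in ", max_tries,
       " attempts; increase chain_length or mutation_rate", call. = FALSE)
}

# chain layouts: (y, z) offsets for CA/CB, per residue, with interface
# residues pulling CB towards the partner
chain_atoms <- function(chain_id, seq_chars, layout, iface = integer(0)) {
  L <- length(seq_chars)
  i0 <- seq_len(L) - 1
  cb_y <- rep(layout$cb[1], L); cb_z <- rep(layout$cb[2], L)
  if (length(iface)) {
    cb_y[iface + 1] <- layout$cb_iface[1]
    cb_z[iface + 1] <- layout$cb_iface[2]
  }
  resid3 <- bio3d::aa123(seq_chars)
  data.frame(
    chain = chain_id,
    resno = rep(i0 + 1L, each = 2),
    insert = "",
    resid = rep(resid3, each = 2),
    elety = rep(c("CA", "CB"), L),
    element = "C",
    x = rep(6 * i0, each = 2),
    y = as.vector(rbind(rep(layout$ca[1], L), cb_y)),
    z = as.vector(rbind(rep(layout$ca[2], L), cb_z)),
    o = 1,
    stringsAsFactors = FALSE)
}

.LAYOUT_A <- list(ca = c(0, 0), cb = c(1.5, 0), cb_iface = c(1.5, 0))
.LAYOUT_B <- list(ca = c(12, 0), cb = c(10.5, 0), cb_iface = c(4.3, 0))
.LAYOUT_C <- list(ca = c(0, 12), cb = c(0, 10.5), cb_iface = c(0, 2.8))

#' Generate a synthetic homolog family with planted binding modes
#'
#' Writes one PDB per member (homodimers, chains A/B), a monomeric
#' query structure carrying the ancestral sequence, the alignment TSV
#' (identity correspondences member chain -> query), a domain TSV
#' assigning all family chains to one family, and a truth table. With
#' `decoy_packing`, an extra trimer member is added whose chain C
#' touches chain A at `decoy_residues` (see [generate_decoy()]). Every
#' emitted structure is read back and checked against its own truth
#' table with default contact parameters.
#'
#' @param spec A [family_spec()].
#' @param dir Output directory (created if needed).
#' @return A `FixtureTruth` list: `spec`, `dir`, `query` (path),
#'   `members` (data frame: structure_id, path, mode, sequence),
#'   `alignment_file`, `domain_file`, `truth_file`,
#'   `mode_keys` (list of query residue-key vectors per mode),
#'   `decoy_keys` (query residue keys of the decoy interface or
#'   `NULL`), `site_truth` (data frame: structure_id, chain_id,
#'   mode_id, residue_keys).
#' @export
generate_family <- function(spec, dir = tempfile("family")) {
  stopifnot(inherits(spec, "FamilySpec"))
  if (spec$decoy_packing) check_decoy_disjoint(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  L <- spec$chain_length
  iface_union <- sort(unique(unlist(spec$binding_modes)))
  rates <- rep(spec$mutation_rate, L)
  rates[iface_union + 1] <- spec$mutation_rate * spec$iface_rate_ratio
  anc <- sample(.AA20, L, replace = TRUE)
  drawn <- list()

  n_modes <- length(spec$binding_modes)
  members <- data.frame(structure_id = character(), path = character(),
                        mode = integer(), sequence = character(),
                        stringsAsFactors = FALSE)
  site_truth <- list()
  aln_rows <- list()
  dom_rows <- list()

  query_path <- file.path(dir, "query.pdb")
  write_structure_pdb(chain_atoms("A", anc, .LAYOUT_A), query_path)
  dom_rows[[1]] <- data.frame(structure_id = "query", chain_id = "A",
                              domain_id = "A", family_id = "FAM",
                              ranges = paste0("1-", L),
                              stringsAsFactors = FALSE)

  emit_member <- function(sid, seqs, mode_idx, chains, iface_sets) {
    at <- do.call(rbind, lapply(seq_along(chains), function(ci)
      chain_atoms(chains[ci], seqs[[ci]],
                  list(A = .LAYOUT_A, B = .LAYOUT_B, C = .LAYOUT_C)[[chains[ci]]],
                  iface_sets[[ci]])))
    path <- file.path(dir, paste0(sid, ".pdb"))
    write_structure_pdb(at, path)
    path
  }

  for (j in seq_len(spec$n_members)) {
    sid <- sprintf("member%02d", j)
    mode_idx <- ((j - 1) %% n_modes) + 1
    mode <- spec$binding_modes[[mode_idx]]
    mseq <- draw_member(anc, rates, drawn)
    drawn[[length(drawn) + 1]] <- mseq
    path <- emit_member(sid, list(mseq, mseq), mode_idx, c("A", "B"),
                        list(mode, mode))
    members <- rbind(members, data.frame(
      structure_id = sid, path = path, mode = mode_idx,
      sequence = paste(mseq, collapse = ""), stringsAsFactors = FALSE))
    for (ch in c("A", "B")) {
      site_truth[[length(site_truth) + 1]] <- data.frame(
        structure_id = sid, chain_id = ch, mode_id = mode_idx,
        residue_keys = paste(residue_key(ch, mode + 1L), collapse = ","),
        stringsAsFactors = FALSE)
      aln_rows[[length(aln_rows) + 1]] <- data.frame(
        neighbor_structure = sid, neighbor_chain = ch,
        query_structure = "query", query_chain = "A",
        pairs = paste(sprintf("%d:%d", 0:(L - 1), 0:(L - 1)),
                      collapse = ";"), stringsAsFactors = FALSE)
      dom_rows[[length(dom_rows) + 1]] <- data.frame(
        structure_id = sid, chain_id = ch, domain_id = ch,
        family_id = "FAM", ranges = paste0("1-", L),
        stringsAsFactors = FALSE)
    }
  }

  decoy_keys <- NULL
  if (spec$decoy_packing) {
    dec <- generate_decoy(spec, ancestor = anc, rates = rates,
                          prior = drawn)
    sid <- dec$structure_id
    path <- emit_member(sid, dec$sequences, 1L, c("A", "B", "C"),
                        list(spec$binding_modes[[1]],
                             spec$binding_modes[[1]],
                             spec$decoy_residues))
    members <- rbind(members, data.frame(
      structure_id = sid, path = path, mode = 1L,
      sequence = paste(dec$sequences[[1]], collapse = ""),
      stringsAsFactors = FALSE))
    for (ch in c("A", "B")) {
      site_truth[[length(site_truth) + 1]] <- data.frame(
        structure_id = sid, chain_id = ch, mode_id = 1L,
        residue_keys = paste(residue_key(ch, spec$binding_modes[[1]] + 1L),
                             collapse = ","), stringsAsFactors = FALSE)
      aln_rows[[length(aln_rows) + 1]] <- data.frame(
        neighbor_structure = sid, neighbor_chain = ch,
        query_structure = "query", query_chain = "A",
        pairs = paste(sprintf("%d:%d", 0:(L - 1), 0:(L - 1)),
                      collapse = ";"), stringsAsFactors = FALSE)
      dom_rows[[length(dom_rows) + 1]] <- data.frame(
        structure_id = sid, chain_id = ch, domain_id = ch,
        family_id = "FAM", ranges = paste0("1-", L),
        stringsAsFactors = FALSE)
    }
    # decoy interface on chain A (and its mirror on C); chain C is a
    # lattice mate with no alignment record, so only the A-side site maps
    site_truth[[length(site_truth) + 1]] <- data.frame(
      structure_id = sid, chain_id = "A", mode_id = NA_integer_,
      residue_keys = paste(residue_key("A", spec$decoy_residues + 1L),
                           collapse = ","), stringsAsFactors = FALSE)
    dom_rows[[length(dom_rows) + 1]] <- data.frame(
      structure_id = sid, chain_id = "C", domain_id = "C",
      family_id = "PACK", ranges = paste0("1-", L),
      stringsAsFactors = FALSE)
    decoy_keys <- residue_key("A", spec$decoy_residues + 1L)
  }

  aln_df <- do.call(rbind, aln_rows)
  dom_df <- do.call(rbind, dom_rows)
  truth_df <- do.call(rbind, site_truth)
  aln_file <- file.path(dir, "alignments.tsv")
  dom_file <- file.path(dir, "domains.tsv")
  truth_file <- file.path(dir, "truth.tsv")
  for (w in list(list(aln_df, aln_file), list(dom_df, dom_file),
                 list(truth_df, truth_file))) {
    con <- file(w[[2]], "wb")
    utils::write.table(w[[1]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    close(con)
  }

  truth <- structure(list(
    spec = spec, dir = dir, query = query_path, members = members,
    alignment_file = aln_file, domain_file = dom_file,
    truth_file = truth_file,
    mode_keys = lapply(spec$binding_modes, function(m)
      residue_key("A", m + 1L)),
    decoy_keys = decoy_keys, site_truth = truth_df),
    class = "FixtureTruth")
  verify_family(truth)
  truth
}

check_decoy_disjoint <- function(spec) {
  if (length(intersect(spec$decoy_residues,
                       unlist(spec$binding_modes))) > 0) {
    stop("decoy interface residues must be disjoint from all planted ",
         "binding modes", call. = FALSE)
  }
  if (any(spec$decoy_residues < 0) ||
      any(spec$decoy_residues >= spec$chain_length)) {
    stop("decoy residues outside the chain", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate the crystal-packing-like decoy member
#'
#' Produces the extra family member carrying a one-off interface:
#' chains A/B exhibit binding mode 1, chain C contacts chain A at
#' `decoy_residues`, which must be disjoint from every planted mode.
#' The decoy interface therefore appears in exactly one member of the
#' family, emulating a lattice contact.
#'
#' @param spec A [family_spec()] with `decoy_packing = TRUE`.
#' @param ancestor,rates,prior Internal: ancestor sequence, per-site
#'   mutation rates and previously drawn member sequences (derived from
#'   `spec$seed + 1` when omitted).
#' @return List with `structure_id` (`"decoy"`) and `sequences` (list
#'   of A/B/C character vectors).
#' @export
generate_decoy <- function(spec, ancestor = NULL, rates = NULL,
                           prior = list()) {
  if (!spec$decoy_packing) {
    stop("decoy_packing is not set in this family spec", call. = FALSE)
  }
  check_decoy_disjoint(spec)
  if (is.null(ancestor)) {
    set.seed(spec$seed + 1L)
    ancestor <- sample(.AA20, spec$chain_length, replace = TRUE)
    rates <- rep(spec$mutation_rate, spec$chain_length)
    rates[sort(unique(unlist(spec$binding_modes))) + 1] <-
      spec$mutation_rate * spec$iface_rate_ratio
  }
  mseq <- draw_member(ancestor, rates, prior)
  cseq <- mutate_seq(ancestor, rates)
  list(structure_id = "decoy", sequences = list(mseq, mseq, cseq))
}

verify_family <- function(truth) {
  params <- contact_params()
  for (i in seq_len(nrow(truth$members))) {
    sid <- truth$members$structure_id[i]
    model <- read_structure(truth$members$path[i])
    domains <- apply_domains(model, truth$domain_file)
    ints <- enumerate_interactions(model, domains, params)
    got <- list()
    for (ia in ints) {
      got[[paste0(ia$site_a$owner_chain)]] <-
        c(got[[paste0(ia$site_a$owner_chain)]], list(ia$site_a$residue_keys))
      got[[paste0(ia$site_b$owner_chain)]] <-
        c(got[[paste0(ia$site_b$owner_chain)]], list(ia$site_b$residue_keys))
    }
    want <- truth$site_truth[truth$site_truth$structure_id == sid, ]
    for (r in seq_len(nrow(want))) {
      keys <- strsplit(want$residue_keys[r], ",", fixed = TRUE)[[1]]
      hits <- got[[want$chain_id[r]]]
      ok <- any(vapply(hits, function(h) identical(sort(h), sort(keys)),
                       logical(1)))
      if (!ok) {
        stop("fixture self-check failed: planted site not recovered on ",
             sid, " chain ", want$chain_id[r], call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}
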