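#' @importFrom stats hclust cutree as.dist sd
#' @importFrom utils read.table write.table
NULL

.WATER <- c("HOH", "DOD", "WAT", "H2O")

#' Canonical residue key
#'
#' Residues are identified everywhere by author numbering: chain id,
#' author sequence number and insertion code (blank if none), joined as
#' `"chain:resnoins"`, e.g. `"A:100"` or `"A:100A"`.
#'
#' @param chain,resno,insert Vectors of chain ids, author residue
#'   numbers and insertion codes (`""` or `NA` for none).
#' @return Character vector of keys.
#' @export
residue_key <- function(chain, resno, insert = "") {
  ins <- ifelse(is.na(insert) | insert == " ", "", insert)
  paste0(chain, ":", resno, ins)
}

one_letter <- function(resid) {
  aa <- suppressWarnings(bio3d::aa321(resid))
  aa[is.na(aa) | !aa %in% LETTERS] <- "X"
  aa
}

derive_element <- function(elesy, elety) {
  el <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  miss <- is.na(el)
  if (any(miss)) {
    guess <- sub("^[0-9]+", "", elety[miss])
    el[miss] <- toupper(substr(guess, 1, 1))
  }
  el
}

#' Read a protein structure into a StructureModel
#'
#' Parses a PDB or mmCIF file (via \pkg{bio3d}) into a uniform model of
#' protein chains, residues keyed by author numbering + insertion code,
#' and heavy-atom coordinates. Waters and hydrogens/deuteriums are
#' dropped; alternate locations are resolved to the highest-occupancy
#' conformer (ties: first in file); only the first model of multi-model
#' files is kept.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"` (by extension), `"pdb"`, `"mmcif"`.
#' @return A `StructureModel`: list with `structure_id`, `source_format`,
#'   `atoms` (data frame: chain, resno, insert, resid, aa, elety,
#'   element, x, y, z, o, key) and `chains` (named list, each with
#'   `chain_id`, `keys`, `resno`, `insert`, `aa`, `sequence`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- withCallingHandlers(
    tryCatch(
      if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                           rm.alt = FALSE, verbose = FALSE)
      else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
      error = function(e) stop("failed to parse ", format, " file '", path,
                               "': ", conditionMessage(e), call. = FALSE)
    ),
    warning = function(w) {
      # bio3d warns about absent optional records and its own cif-reader
      # maturity; neither affects the atom table we consume
      if (grepl("helix/sheet|beta version", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("empty model: no atom records in ", path, call. = FALSE)
  }
  at$insert[is.na(at$insert)] <- ""
  at <- at[!(at$resid %in% .WATER), , drop = FALSE]
  at$element <- derive_element(at$elesy, at$elety)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) > 0) {
    # altloc: highest occupancy wins, ties go to the first conformer in file
    at$o[is.na(at$o)] <- 1
    orig <- seq_len(nrow(at))
    grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(grp, -at$o, orig)
    keep <- ord[!duplicated(grp[ord])]
    at <- at[sort(keep), , drop = FALSE]
  }
  # a residue is protein if it is an ATOM record of an amino acid, or any
  # record carrying a CA atom (covers modified residues filed as HETATM)
  if (nrow(at) > 0) {
    rid <- paste(at$chain, at$resno, at$insert, sep = "\r")
    has_ca <- rid %in% rid[at$elety == "CA"]
    is_aa <- !is.na(suppressWarnings(bio3d::aa321(at$resid))) &
      suppressWarnings(bio3d::aa321(at$resid)) != "X"
    keep <- has_ca | (at$type == "ATOM" & is_aa)
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("empty model: no protein chains in ", path, call. = FALSE)

  atoms <- data.frame(
    chain = at$chain, resno = as.integer(at$resno), insert = at$insert,
    resid = at$resid, aa = one_letter(at$resid), elety = at$elety,
    element = at$element, x = at$x, y = at$y, z = at$z,
    o = at$o, stringsAsFactors = FALSE
  )
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$insert)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    stop("non-finite coordinates at atom record(s): ",
         paste(which(bad)[1:min(3, sum(bad))], collapse = ", "), call. = FALSE)
  }

  chains <- list()
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    first <- !duplicated(sub$key)
    chains[[ch]] <- list(
      chain_id = ch,
      keys = sub$key[first],
      resno = sub$resno[first],
      insert = sub$insert[first],
      aa = sub$aa[first],
      sequence = paste(sub$aa[first], collapse = "")
    )
  }
  structure(list(
    structure_id = sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                       ignore.case = TRUE),
    source_format = if (format == "mmcif") "mmcif" else "pdb",
    atoms = atoms,
    chains = chains
  ), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel", x$structure_id, sprintf("(%s)", x$source_format), "\n")
  for (ch in x$chains) {
    cat(sprintf("  chain %s: %d residues\n", ch$chain_id, length(ch$keys)))
  }
  invisible(x)
}

parse_ranges <- function(ranges) {
  parts <- strsplit(ranges, ",", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    bounds <- as.integer(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
    if (length(bounds) == 1) bounds <- c(bounds, bounds)
    seq.int(bounds[1], bounds[2])
  })
  unique(unlist(out))
}

#' Attach domain boundaries to a model
#'
#' With no annotations, every chain becomes one whole-chain domain whose
#' `family_id` is its chain id. Otherwise a TSV (or data frame) with
#' columns `structure_id, chain_id, domain_id, family_id, ranges`
#' (ranges like `"5-120,130-200"`, author numbering, inclusive) carves
#' out domains; residues outside any annotated range belong to no
#' domain.
#'
#' @param model A `StructureModel`.
#' @param annotations `NULL`, a TSV path, or a data frame.
#' @return List of `DomainInstance`: lists with `domain_id`,
#'   `family_id`, `chain_id`, `residue_keys`.
#' @export
apply_domains <- function(model, annotations = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  if (is.null(annotations)) {
    return(lapply(model$chains, function(ch) {
      structure(list(domain_id = ch$chain_id, family_id = ch$chain_id,
                     chain_id = ch$chain_id, residue_keys = ch$keys),
                class = "DomainInstance")
    }))
  }
  ann <- if (is.character(annotations)) {
    utils::read.table(annotations, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, colClasses = "character")
  } else as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("structure_id", "chain_id", "domain_id", "family_id", "ranges")
  if (!all(need %in% names(ann))) {
    stop("domain annotation must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ann <- ann[ann$structure_id == model$structure_id, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ann))) {
    row <- ann[i, ]
    ch <- model$chains[[row$chain_id]]
    if (is.null(ch)) {
      stop("domain annotation row ", i, " (domain '", row$domain_id,
           "') references chain '", row$chain_id,
           "' absent from structure ", model$structure_id, call. = FALSE)
    }
    resnos <- parse_ranges(row$ranges)
    sel <- ch$resno %in% resnos
    if (!any(sel)) {
      stop("domain annotation row ", i, " (domain '", row$domain_id,
           "') selects no residues on chain ", row$chain_id, call. = FALSE)
    }
    out[[row$domain_id]] <- structure(
      list(domain_id = row$domain_id, family_id = row$family_id,
           chain_id = row$chain_id, residue_keys = ch$keys[sel]),
      class = "DomainInstance")
  }
  out
}

#' Chain sequence and index-to-residue map
#'
#' @param model A `StructureModel`.
#' @param chain_id Chain identifier.
#' @return List with `sequence` (one-letter string, unknown residues as
#'   `X`) and `keys`: character vector such that 0-based sequence index
#'   `i` corresponds to `keys[i + 1]`.
#' @export
chain_sequence_map <- function(model, chain_id) {
  ch <- model$chains[[chain_id]]
  if (is.null(ch)) {
    stop("unknown chain '", chain_id, "' in structure ",
         model$structure_id, call. = FALSE)
  }
  list(sequence = ch$sequence, keys = ch$keys)
}

#' Write a minimal PDB file
#'
#' Fixed-column ATOM records for a model's heavy atoms (author
#' numbering, insertion codes and element symbols preserved).
#'
#' @param model A `StructureModel` or an atom data frame with columns
#'   `chain, resno, insert, resid, elety, element, x, y, z, o`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  at <- if (inherits(model, "StructureModel")) model$atoms else model
  con <- file(path, "wb")
  on.exit(close(con))
  lines <- character(nrow(at) + 1)
  for (i in seq_len(nrow(at))) {
    name <- at$elety[i]
    name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    lines[i] <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i %% 100000, name_fmt, at$resid[i], at$chain[i], at$resno[i],
      ifelse(at$insert[i] == "", " ", at$insert[i]),
      at$x[i], at$y[i], at$z[i],
      if (is.null(at$o)) 1 else at$o[i], 0, at$element[i])
  }
  lines[nrow(at) + 1] <- "END"
  writeLines(lines, con)
  invisible(path)
}

#' Write a minimal mmCIF file
#'
#' A single `atom_site` loop equivalent to [write_structure_pdb()].
#'
#' @inheritParams write_structure_pdb
#' @return `path`, invisibly.
#' @export
write_structure_cif <- function(model, path) {
  at <- if (inherits(model, "StructureModel")) model$atoms else model
  sid <- if (inherits(model, "StructureModel")) model$structure_id else "toy"
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    paste0("data_", sid),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1",
    seq_len(nrow(at)), at$element, at$elety, at$resid, at$chain, at$resno,
    ifelse(at$insert == "", "?", at$insert), at$x, at$y, at$z,
    if (is.null(at$o)) rep(1, nrow(at)) else at$o, 0,
    at$resno, at$resid, at$chain, at$elety)
  writeLines(c(header, rows, "#"), con)
  invisible(path)
}
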