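line_model <- function(sid, seqs, dir = tempdir()) {
  rows <- list()
  for (ci in seq_along(seqs)) {
    s <- strsplit(seqs[[ci]], "")[[1]]
    rows[[ci]] <- toy_atoms(LETTERS[ci], seq_along(s), "CA",
                            6 * (seq_along(s) - 1), 10 * (ci - 1), 0,
                            resid = bio3d::aa123(s))
  }
  path <- file.path(dir, paste0(sid, ".pdb"))
  write_structure_pdb(do.call(rbind, rows), path)
  read_structure(path)
}

test_that("both alignment dialects load to identical validated maps", {
  qm <- line_model("qry", list("ACDEFGHIKL"))
  nm <- line_model("nbr", list("ACDFGHIKL"))  # E deleted
  models <- list(qry = qm, nbr = nm)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "neighbor_structure\tneighbor_chain\tquery_structure\tquery_chain\tpairs",
    paste0("nbr\tA\tqry\tA\t",
           "0:0;1:1;2:2;3:5;4:6;5:7;6:8;7:9")), tsv)
  a_tsv <- load_alignments(tsv, models)[[1]]
  expect_s3_class(a_tsv, "AlignmentMap")
  expect_equal(nrow(a_tsv$pairs), 8)

  # identity self-alignment
  self_tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "neighbor_structure\tneighbor_chain\tquery_structure\tquery_chain\tpairs",
    paste0("qry\tA\tqry\tA\t",
           paste(sprintf("%d:%d", 0:9, 0:9), collapse = ";"))), self_tsv)
  self <- load_alignments(self_tsv, models)[[1]]
  expect_equal(self$identity_fraction, 1.0)
  expect_equal(self$pairs[, 1], self$pairs[, 2])

  # FASTA dialect of an equivalent alignment
  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">nbr:A", "ACD-FGHIKL",
               ">qry:A", "ACDEFGHIKL"), fa2)
  a_fa <- load_alignments(fa2, models)[[1]]
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "neighbor_structure\tneighbor_chain\tquery_structure\tquery_chain\tpairs",
    "nbr\tA\tqry\tA\t0:0;1:1;2:2;3:4;4:5;5:6;6:7;7:8;8:9"), tsv2)
  a_tsv2 <- load_alignments(tsv2, models)[[1]]
  expect_equal(a_fa$pairs, a_tsv2$pairs)
  expect_equal(a_fa$identity_fraction, a_tsv2$identity_fraction)

  # validation: out-of-range index and crossings
  expect_error(alignment_map(c("nbr", "A"), c("qry", "A"),
                             cbind(500, 0), nm$chains$A$sequence,
                             qm$chains$A$sequence), "out of range")
  expect_error(alignment_map(c("nbr", "A"), c("qry", "A"),
                             cbind(c(0, 1), c(3, 2)),
                             nm$chains$A$sequence,
                             qm$chains$A$sequence), "colinear")
})

test_that("fallback global alignment is optimal and deterministic", {
  H <- blosum62()
  id <- align_fallback("ACDEFG", "ACDEFG")
  expect_equal(id$pairs[, 1], id$pairs[, 2])
  expect_equal(id$identity_fraction, 1.0)

  # spec'd small case plus random short pairs vs exhaustive enumeration
  set.seed(42)
  cases <- c(list(c("ACDE", "ACE")), lapply(1:15, function(i) {
    c(paste(sample(AA20, sample(2:4, 1), replace = TRUE), collapse = ""),
      paste(sample(AA20, sample(2:4, 1), replace = TRUE), collapse = ""))
  }))
  for (cs in cases) {
    got <- attr(align_fallback(cs[1], cs[2], H), "score")
    want <- exhaustive_align_score(cs[1], cs[2], H)
    expect_equal(got, want, info = paste(cs, collapse = " vs "))
  }
  expect_error(align_fallback("", "ACD"), "non-empty")
})

test_that("neighbour filtering applies the identity threshold and keeps redundancy", {
  mk_aln <- function(ident, id = "n") {
    # seq of length 10 with `ident` fraction matching
    q <- strsplit("AAAAAAAAAA", "")[[1]]
    n <- q
    nmut <- round((1 - ident) * 10)
    if (nmut > 0) n[seq_len(nmut)] <- "C"
    alignment_map(c(id, "A"), c("q", "A"),
                  cbind(0:9, 0:9), paste(n, collapse = ""),
                  paste(q, collapse = ""))
  }
  alns <- list(mk_aln(0.2, "low"), mk_aln(0.3, "edge"),
               mk_aln(1.0, "dup1"), mk_aln(1.0, "dup2"))
  kept <- filter_neighbors(alns)
  ids <- vapply(kept, function(a) a$neighbor_id[1], "")
  expect_equal(ids, c("edge", "dup1", "dup2"))  # 0.30 kept, duplicates kept
  expect_equal(attr(kept, "excluded")$neighbor, "low:A")
  expect_length(filter_neighbors(list()), 0)
  # at threshold 0 the filter is the identity function
  expect_length(filter_neighbors(alns, 0), 4)
})

test_that("alignment composition matches a join oracle and is associative", {
  set.seed(7)
  seqs <- replicate(4, paste(sample(AA20, 30, replace = TRUE),
                             collapse = ""))
  for (rep in 1:25) {
    pa <- random_colinear_pairs(30, 30)
    pb <- random_colinear_pairs(30, 30)
    a <- alignment_map(c("a", "A"), c("q", "A"), pa, seqs[1], seqs[2])
    b <- alignment_map(c("b", "A"), c("q", "A"), pb, seqs[3], seqs[2])
    ab <- compose_alignment(a, b)
    # nested-loop join oracle over index pairs
    want <- list()
    for (i in seq_len(nrow(pa))) {
      for (j in seq_len(nrow(pb))) {
        if (pa[i, 2] == pb[j, 2]) {
          want[[length(want) + 1]] <- c(pa[i, 1], pb[j, 1])
        }
      }
    }
    want <- if (length(want)) do.call(rbind, want) else
      matrix(integer(0), 0, 2)
    expect_equal(unname(ab$pairs), want[order(want[, 1]), , drop = FALSE])
  }

  # identity element
  q <- alignment_map(c("q", "A"), c("q", "A"), cbind(0:29, 0:29),
                     seqs[2], seqs[2])
  a <- alignment_map(c("a", "A"), c("q", "A"),
                     random_colinear_pairs(30, 30, 12), seqs[1], seqs[2])
  expect_equal(unname(compose_alignment(a, q)$pairs), unname(a$pairs))

  # mismatched queries refuse to compose
  b2 <- alignment_map(c("b", "A"), c("other", "A"),
                      cbind(0:4, 0:4), seqs[3], seqs[4])
  expect_error(compose_alignment(a, b2), "different query")
})

test_that("site projection applies the 75% aligned-fraction rule", {
  qm <- line_model("qry2", list(paste(rep("A", 20), collapse = "")))
  nm <- line_model("nbr2", list(paste(rep("A", 20), collapse = "")))
  site <- structure(list(
    owner_domain = "A", partner_domain = "B", owner_chain = "A",
    partner_family = "F", residue_keys = residue_key("A", 1:8),
    contacts_per_residue = stats::setNames(rep(1L, 8),
                                           residue_key("A", 1:8)),
    total_contacts = 8L), class = "BindingSite")

  # only 5 of 8 site residues aligned: 0.625 < 0.75, rejected
  part <- alignment_map(c("nbr2", "A"), c("qry2", "A"),
                        cbind(c(0:4, 10:14), c(0:4, 10:14)),
                        nm$chains$A$sequence, qm$chains$A$sequence)
  ms <- map_site_to_query(site, part, nm, qm)
  expect_s3_class(ms, "RejectedSite")
  expect_match(ms$reason, "0.625")

  # identity alignment: all residues mapped, fraction 1
  full <- alignment_map(c("nbr2", "A"), c("qry2", "A"),
                        cbind(0:19, 0:19),
                        nm$chains$A$sequence, qm$chains$A$sequence)
  ms2 <- map_site_to_query(site, full, nm, qm)
  expect_equal(ms2$aligned_fraction, 1.0)
  expect_equal(ms2$query_residue_keys, residue_key("A", 1:8))

  # known gap pattern: residues 0..7, alignment drops 2 of them and
  # shifts the rest by +2
  gap <- alignment_map(c("nbr2", "A"), c("qry2", "A"),
                       cbind(c(0, 1, 2, 3, 4, 5), c(2, 3, 4, 5, 6, 7)),
                       nm$chains$A$sequence, qm$chains$A$sequence)
  ms3 <- map_site_to_query(site, gap, nm, qm)
  expect_equal(ms3$aligned_fraction, 6 / 8)
  expect_equal(ms3$query_residue_keys, residue_key("A", 3:8))

  # site residue missing from the neighbour chain
  bad_site <- site
  bad_site$residue_keys <- c(site$residue_keys, "A:999")
  expect_error(map_site_to_query(bad_site, full, nm, qm), "not found")
})
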