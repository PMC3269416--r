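test_that("redundancy reduction separates conserved clusters from singletons", {
  expect_equal(classify_cluster(list(a = "ACDEFGHIKLMNPQRSTVWY"))$label,
               "singleton")
  base <- "ACDEFGHIKLMNPQRSTVWY"
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    v[seq_len(k)] <- "G"
    paste(v, collapse = "")
  }
  # 19/20 = 95% identity: redundant pair, singleton
  expect_equal(classify_cluster(list(a = base, b = mut(base, 1)))$label,
               "singleton")
  # 17/20 = 85% identity: two representatives, conserved
  cl <- classify_cluster(list(a = base, b = mut(base, 3)))
  expect_equal(cl$label, "conserved")
  expect_equal(cl$n_nonredundant, 2)
  # exactly at the 90% threshold counts as redundant (>= rule)
  expect_equal(classify_cluster(list(a = base, b = mut(base, 2)))$label,
               "singleton")
})

test_that("Henikoff position-based weights match the hand computation", {
  # identical rows share weight equally
  expect_equal(henikoff_weights(c("ACD", "ACD", "ACD")), rep(1 / 3, 3))
  expect_equal(henikoff_weights("AC"), 1.0)

  # {"AA","AA","AC"}: col 1 gives 1/3 each; col 2 gives 1/4, 1/4, 1/2
  w <- henikoff_weights(c("AA", "AA", "AC"))
  raw <- c(1 / 3 + 1 / 4, 1 / 3 + 1 / 4, 1 / 3 + 1 / 2)
  expect_equal(w, raw / sum(raw))
  expect_gt(w[3], w[1])  # divergent row carries the largest weight

  set.seed(31)
  for (rep in 1:20) {
    rows <- replicate(sample(2:6, 1),
                      paste(sample(c(AA20, "-"), 12, replace = TRUE),
                            collapse = ""))
    w <- henikoff_weights(rows)
    expect_true(all(w > 0))
    expect_equal(sum(w), 1)
  }
})

test_that("conservation is weighted negentropy over the 21-letter alphabet", {
  # invariant alignment: entropy 0, conservation log2(21)
  expect_equal(conservation_score(c("ACDE", "ACDE", "ACDE")), log2(21))

  # one column of 20 equally weighted distinct residues: h = log2 20
  expect_equal(conservation_score(matrix(AA20, ncol = 1),
                                  weights = rep(1 / 20, 20)),
               log2(21) - log2(20))

  # adding an identical copy of a row never decreases conservation
  set.seed(37)
  for (rep in 1:20) {
    rows <- replicate(3, paste(sample(c(AA20, "-"), 10, replace = TRUE),
                               collapse = ""))
    expect_gte(conservation_score(c(rows, rows[1])) + 1e-12,
               conservation_score(rows))
    # weighted-entropy value matches the direct oracle
    w <- henikoff_weights(rows)
    expect_equal(conservation_score(rows, w),
                 weighted_entropy_oracle(rows, w))
  }
})

test_that("PSSM columns are convex combinations of substitution rows", {
  H <- blosum62()
  p1 <- build_pssm("A", weights = 1)
  expect_equal(unname(p1[1, ]), unname(H["A", AA20]))

  p2 <- build_pssm(c("A", "C"), weights = c(0.5, 0.5))
  expect_equal(unname(p2[1, ]),
               unname(0.5 * H["A", AA20] + 0.5 * H["C", AA20]))

  set.seed(41)
  for (rep in 1:15) {
    rows <- replicate(sample(2:5, 1),
                      paste(sample(c(AA20, "-"), 8, replace = TRUE),
                            collapse = ""))
    w <- henikoff_weights(rows)
    got <- build_pssm(rows, w, H)
    want <- pssm_oracle(rows, w, H)
    expect_equal(unname(got), unname(want), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_error(build_pssm(c("--", "--")), "all alignment columns are gaps")
})

test_that("query-PSSM scoring sums matrix entries over non-gap columns", {
  H <- blosum62()
  seqv <- c("A", "W", "C", "H")
  p <- build_pssm(paste(seqv, collapse = ""), weights = 1)
  # single member scored against itself: sum of diagonal entries
  expect_equal(score_query(p, seqv), sum(H[cbind(seqv, seqv)]))
  expect_equal(score_query(p, rep("-", 4)), 0)
  expect_error(score_query(p, c("A", "A")), "does not match")

  set.seed(43)
  for (rep in 1:15) {
    rows <- replicate(3, paste(sample(AA20, 8, replace = TRUE),
                               collapse = ""))
    w <- henikoff_weights(rows)
    p <- build_pssm(rows, w, H)
    q <- sample(c(AA20, "-"), 8, replace = TRUE)
    oracle <- pssm_oracle(rows, w, H)
    want <- sum(vapply(which(q != "-"), function(i) oracle[i, q[i]], 0))
    expect_equal(score_query(p, q), want)
  }
})

mk_components <- function(labels, conserv, contact, pssm, pcnt,
                          n_members = NULL) {
  n <- length(labels)
  data.frame(cluster_id = sprintf("C%02d", seq_len(n)), label = labels,
             n_members = if (is.null(n_members)) rep(2, n) else n_members,
             n_nonredundant = ifelse(labels == "conserved", 2, 1),
             conserv = conserv, contact = contact, pssm = pssm,
             pcnt = pcnt, stringsAsFactors = FALSE)
}

test_that("cluster ranking standardizes components and sinks singletons", {
  # singleton never outranks a conserved cluster
  df <- mk_components(c("singleton", "conserved"),
                      c(NA, 1), c(NA, 1), c(NA, 1), c(NA, 1))
  rk <- rank_clusters(df)
  expect_equal(rk$label, c("conserved", "singleton"))
  expect_equal(rk$combined[1], 0)  # single conserved cluster: Z = 0
  expect_true(is.na(rk$combined[2]))

  # identical components: Z = 0, order falls back to size then id
  df2 <- mk_components(rep("conserved", 2), c(1, 1), c(2, 2), c(3, 3),
                       c(0.5, 0.5), n_members = c(3, 5))
  rk2 <- rank_clusters(df2)
  expect_equal(rk2$combined, c(0, 0))
  expect_equal(rk2$cluster_id, c("C02", "C01"))

  # three conserved clusters vs a spreadsheet-style Z computation
  conserv <- c(4.0, 2.0, 3.0); contact <- c(10, 30, 20)
  pssm <- c(5, 15, 40); pcnt <- c(0.9, 0.5, 0.7)
  df3 <- mk_components(rep("conserved", 3), conserv, contact, pssm, pcnt)
  z <- function(x) (x - mean(x)) / stats::sd(x)
  want <- z(conserv) + z(contact) + z(pssm) + z(pcnt)
  rk3 <- rank_clusters(df3)
  expect_equal(rk3$combined, sort(want, decreasing = TRUE))
  expect_equal(rk3$rank, 1:3)

  # Z-score invariance under affine rescaling of a raw component
  df4 <- df3
  df4$contact <- 100 * df3$contact + 7
  rk4 <- rank_clusters(df4)
  expect_equal(rk4$cluster_id, rk3$cluster_id)
  expect_equal(rk4$combined, rk3$combined)

  # randomized fixtures: singletons always occupy the bottom ranks
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    labels <- sample(c("conserved", "singleton"), n, replace = TRUE)
    dfr <- mk_components(labels, stats::runif(n), stats::runif(n),
                         stats::runif(n), stats::runif(n),
                         n_members = sample(1:10, n, replace = TRUE))
    rkr <- rank_clusters(dfr)
    lab <- rkr$label
    if (any(lab == "conserved") && any(lab == "singleton")) {
      expect_lt(max(which(lab == "conserved")),
                min(which(lab == "singleton")))
    }
  }
})
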