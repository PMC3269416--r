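# Independent oracles and small in-code fixture builders shared by the
# test files. Oracles deliberately use naive algorithms (nested loops,
# exhaustive enumeration) so they stay independent of the package's
# implementation paths.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# ---- structure fixtures -------------------------------------------------

toy_atoms <- function(chain, resno, elety, x, y, z, resid = "ALA",
                      insert = "", o = 1) {
  data.frame(chain = chain, resno = as.integer(resno), insert = insert,
             resid = resid, elety = elety, element = "C",
             x = x, y = y, z = z, o = o, stringsAsFactors = FALSE)
}

write_toy_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  homsite::write_structure_pdb(atoms, path)
  path
}

# random multi-chain toy structure: `nres` residues per chain, 1-3 atoms
# per residue, coordinates in a box scaled so some contacts occur
random_toy_model <- function(nchain = 2, nres = 10, box = 12) {
  rows <- list()
  for (ci in seq_len(nchain)) {
    ch <- LETTERS[ci]
    for (ri in seq_len(nres)) {
      natom <- sample(1:3, 1)
      for (ai in seq_len(natom)) {
        rows[[length(rows) + 1]] <- toy_atoms(
          ch, ri, c("CA", "CB", "CG")[ai],
          round(stats::runif(1, 0, box), 3),
          round(stats::runif(1, 0, box), 3),
          round(stats::runif(1, 0, box), 3),
          resid = sample(c("ALA", "GLY", "SER", "LEU"), 1))
      }
    }
  }
  at <- do.call(rbind, rows)
  homsite::read_structure(write_toy_pdb(at))
}

# ---- contact oracle -----------------------------------------------------

# brute-force all-atom-pairs contact oracle (nested loops over residues)
brute_contacts <- function(domain_a, domain_b, model, radius = 4.0) {
  at <- model$atoms
  out <- list()
  for (ka in domain_a$residue_keys) {
    aa <- at[at$chain == domain_a$chain_id & at$key == ka, , drop = FALSE]
    for (kb in domain_b$residue_keys) {
      ab <- at[at$chain == domain_b$chain_id & at$key == kb, , drop = FALSE]
      found <- 0L
      for (i in seq_len(nrow(aa))) {
        for (j in seq_len(nrow(ab))) {
          d <- sqrt((aa$x[i] - ab$x[j])^2 + (aa$y[i] - ab$y[j])^2 +
                      (aa$z[i] - ab$z[j])^2)
          if (d <= radius) found <- found + 1L
        }
      }
      if (found > 0) {
        out[[length(out) + 1]] <- data.frame(
          key_a = ka, key_b = kb, n_atom_pairs = found,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(key_a = character(), key_b = character(),
                      n_atom_pairs = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(match(df$key_a, domain_a$residue_keys),
           match(df$key_b, domain_b$residue_keys)), , drop = FALSE]
}

# ---- mapped-site fixtures and scoring oracle ----------------------------

# a minimal mapped-site stand-in accepted by the cluster engine
mk_site <- function(idx, res, id = "s", query_id = "q:A",
                    total_contacts = length(idx), pcnt = 1) {
  list(site_id = id, member_id = id, query_id = query_id,
       query_idx = as.integer(idx), res = res,
       total_contacts = total_contacts, pcnt = pcnt)
}

random_site <- function(nq = 40, nmin = 3, nmax = 12, id = "s") {
  n <- sample(nmin:nmax, 1)
  idx <- sort(sample(0:(nq - 1), n))
  mk_site(idx, sample(AA20, n, replace = TRUE), id = id)
}

# per-column summation oracle for the raw similarity score
raw_score_oracle <- function(pair, H, omega = 1, gap = -4) {
  total <- 0
  for (i in seq_along(pair$a)) {
    a <- pair$a[i]; b <- pair$b[i]
    if (a == "-" || b == "-") total <- total + gap
    else {
      h <- if (a %in% rownames(H) && b %in% rownames(H)) H[a, b]
           else H["X", if (b %in% rownames(H)) b else "X"]
      total <- total + h + omega
    }
  }
  total
}

# ---- alignment oracles --------------------------------------------------

# exhaustive global-alignment oracle: enumerates every monotone
# alignment path and scores it under the affine scheme where a gap run
# of length L costs open + L * extend
exhaustive_align_score <- function(a, b, H, open = -11, extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, score + H[av[i], bv[j]], "m")
    }
    if (i <= length(av)) {
      pen <- if (state == "x") extend else open + extend
      rec(i + 1, j, score + pen, "x")
    }
    if (j <= length(bv)) {
      pen <- if (state == "y") extend else open + extend
      rec(i, j + 1, score + pen, "y")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# random strictly-colinear alignment map between chains of length la, lb
random_colinear_pairs <- function(la, lb, n = NULL) {
  k <- if (is.null(n)) sample(0:min(la, lb), 1) else n
  cbind(sort(sample(0:(la - 1), k)), sort(sample(0:(lb - 1), k)))
}

# ---- clustering oracles -------------------------------------------------

# naive quadratic complete-linkage: returns merge heights in order
naive_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# independent evaluation of the partition functional
f_oracle <- function(assign, S, temperature) {
  n <- length(assign)
  total <- 0
  for (cl in unique(assign)) {
    mem <- which(assign == cl)
    if (length(mem) == 1) sbar <- 1
    else {
      vals <- c()
      for (i in seq_len(length(mem) - 1)) {
        for (j in seq.int(i + 1, length(mem))) {
          vals <- c(vals, S[mem[i], mem[j]])
        }
      }
      sbar <- mean(vals)
    }
    p <- length(mem) / n
    total <- total + p * sbar + temperature * p * log(p)
  }
  total
}

random_similarity <- function(n, lo = -0.5) {
  S <- matrix(stats::runif(n * n, lo, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(paste0("s", 1:n), paste0("s", 1:n))
  S
}

# ---- ranking oracles ----------------------------------------------------

# direct double-sum PSSM oracle
pssm_oracle <- function(rows, weights, H) {
  m <- if (is.matrix(rows)) rows else do.call(rbind, strsplit(rows, ""))
  keep <- which(apply(m, 2, function(c) any(c != "-")))
  out <- matrix(0, length(keep), 20, dimnames = list(NULL, AA20))
  for (ci in seq_along(keep)) {
    col <- m[, keep[ci]]
    res <- col != "-"
    wsum <- sum(weights[res])
    for (b in AA20) {
      v <- 0
      for (r in which(res)) {
        a <- col[r]
        h <- if (a %in% rownames(H)) H[a, b] else H["X", b]
        v <- v + (weights[r] / wsum) * h
      }
      out[ci, b] <- v
    }
  }
  out
}

weighted_entropy_oracle <- function(rows, weights) {
  m <- if (is.matrix(rows)) rows else do.call(rbind, strsplit(rows, ""))
  vals <- numeric(ncol(m))
  for (p in seq_len(ncol(m))) {
    h <- 0
    for (sym in unique(m[, p])) {
      pr <- sum(weights[m[, p] == sym])
      h <- h - pr * log2(pr)
    }
    vals[p] <- log2(21) - h
  }
  mean(vals)
}
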