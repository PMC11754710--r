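# Independent structured-coalescent oracle, written separately from the
# package engine: explicit per-lineage bookkeeping in plain R, supporting
# two demes with symmetric or asymmetric migration and one merge event.
# Used to cross-validate the package's expected pairwise spectra.

oracle_sim_pattern <- function(n1, n2, N1, N2, m12, m21, t_merge, N_anc) {
  # lineages: data.frame-free bookkeeping; each lineage carries the count
  # of sampled leaves per deme beneath it
  deme <- c(rep(1L, n1), rep(2L, n2))
  cnt1 <- c(rep(1L, n1), rep(0L, n2))
  cnt2 <- c(rep(0L, n1), rep(1L, n2))
  alive <- rep(TRUE, n1 + n2)
  birth <- rep(0, n1 + n2)
  seg_len <- numeric(0)   # completed branch lengths
  seg_c1 <- integer(0)
  seg_c2 <- integer(0)
  t <- 0
  merged <- FALSE
  sizes <- c(N1, N2)
  repeat {
    idx <- which(alive)
    if (length(idx) == 1) break
    k1 <- sum(deme[idx] == 1L)
    k2 <- sum(deme[idx] == 2L)
    r_coal1 <- k1 * (k1 - 1) / (4 * sizes[1])
    r_coal2 <- k2 * (k2 - 1) / (4 * sizes[2])
    r_mig <- if (merged) 0 else k1 * m12 + k2 * m21
    R <- r_coal1 + r_coal2 + r_mig
    dt <- if (R > 0) stats::rexp(1, R) else Inf
    if (!merged && t + dt >= t_merge) {
      t <- t_merge
      deme[idx] <- 1L
      sizes[1] <- N_anc
      merged <- TRUE
      next
    }
    t <- t + dt
    u <- stats::runif(1, 0, R)
    if (u < r_coal1 + r_coal2) {
      d <- if (u < r_coal1) 1L else 2L
      cand <- idx[deme[idx] == d]
      pick <- sample(cand, 2)
      # close the two branch segments
      seg_len <- c(seg_len, t - birth[pick])
      seg_c1 <- c(seg_c1, cnt1[pick])
      seg_c2 <- c(seg_c2, cnt2[pick])
      alive[pick] <- FALSE
      deme <- c(deme, d)
      cnt1 <- c(cnt1, sum(cnt1[pick]))
      cnt2 <- c(cnt2, sum(cnt2[pick]))
      alive <- c(alive, TRUE)
      birth <- c(birth, t)
    } else {
      v <- u - r_coal1 - r_coal2
      if (v < k1 * m12) {
        cand <- idx[deme[idx] == 1L]
        pick <- if (length(cand) == 1) cand else sample(cand, 1)
        deme[pick] <- 2L
      } else {
        cand <- idx[deme[idx] == 2L]
        pick <- if (length(cand) == 1) cand else sample(cand, 1)
        deme[pick] <- 1L
      }
    }
  }
  # mutation uniform on total branch length; the total length is returned
  # so callers can weight genealogies the way SNPs sample them
  w <- seg_len / sum(seg_len)
  hit <- sample.int(length(seg_len), 1, prob = w)
  c(seg_c1[hit], seg_c2[hit], sum(seg_len))
}

oracle_pair_counts <- function(n_sims, n1, n2, N1, N2, m12, m21,
                               t_merge, N_anc, seed) {
  set.seed(seed)
  out <- matrix(0, n_sims, 3)
  for (i in seq_len(n_sims))
    out[i, ] <- oracle_sim_pattern(n1, n2, N1, N2, m12, m21, t_merge, N_anc)
  # genealogies carry SNPs proportionally to their total branch length
  idx <- sample.int(n_sims, n_sims, replace = TRUE, prob = out[, 3])
  out[idx, 1:2, drop = FALSE]
}

# fold + tabulate with the same conventions as the package (re-derived
# here so the comparison does not reuse package internals)
oracle_fold_tab <- function(pat, n1, n2) {
  ca <- pat[, 1]; cb <- pat[, 2]
  tot2 <- 2L * (ca + cb); h <- n1 + n2
  ia <- n1 - ca; ib <- n2 - cb
  flip <- tot2 > h | (tot2 == h & (ia < ca | (ia == ca & ib < cb)))
  fi <- ifelse(flip, ia, ca); fj <- ifelse(flip, ib, cb)
  keep <- (fi + fj) > 1
  tab <- table(factor(fi[keep], levels = 0:n1),
               factor(fj[keep], levels = 0:n2))
  matrix(as.integer(tab), n1 + 1, n2 + 1)
}
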