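#' Simulate one genealogy under a demographic model
#'
#' Runs the structured coalescent backwards in time for the model's sampled
#' lineages: within deme `d` of current diploid size `N_d` each lineage pair
#' coalesces at rate `1/(2 N_d)` per generation, lineages migrate at the
#' model's backward rates, and scheduled merge/admixture/size-change events
#' are applied at their times, until a single root lineage remains.
#'
#' @param model a `demographic_model`.
#' @param params named numeric parameter vector (see [sample_params()]).
#' @param seed integer seed for the simulator's own RNG.
#' @return a `genealogy`: list with `n_leaves`, `root`, `parent`,
#'   `child_a`/`child_b`, `node_time` (generations), `branch_length`,
#'   `leaf_deme` and `tmrca`. Leaves are nodes `1..n_leaves` in deme-block
#'   order.
#' @export
simulate_genealogy <- function(model, params, seed) {
  flat <- instantiate_model(model, params)
  g <- .sim_genealogy_cpp(flat, as.double(seed))
  g$demes <- model$demes
  class(g) <- "genealogy"
  g
}

#' Place a single mutation uniformly on a genealogy
#'
#' Drops exactly one mutation at a point chosen uniformly on the total
#' branch length; leaves below it carry the derived allele. The root has no
#' parent branch, so the resulting site pattern is always segregating.
#'
#' @param gen a `genealogy` from [simulate_genealogy()].
#' @param seed integer seed.
#' @return list with `node` (the branch hit), `derived` (logical per leaf)
#'   and `counts` (named derived-allele count per deme).
#' @export
drop_snp <- function(gen, seed = NULL) {
  if (gen$n_leaves < 2) stop("genealogy needs at least 2 leaves")
  bl <- gen$branch_length
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  node <- sample.int(length(bl), 1, prob = bl)
  derived <- logical(gen$n_leaves)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[[1]]; stack <- stack[-1]
    if (is.na(gen$child_a[v])) derived[v] <- TRUE
    else stack <- c(stack, gen$child_a[v], gen$child_b[v])
  }
  counts <- vapply(seq_along(gen$demes), function(d) {
    sum(derived[gen$leaf_deme[seq_len(gen$n_leaves)] == d])
  }, numeric(1))
  names(counts) <- gen$demes
  list(node = node, derived = derived, counts = counts)
}

#' Simulate per-deme derived-count site patterns
#'
#' Simulates `n_sims` genealogies, drops one uniformly placed mutation on
#' each (so every pattern is segregating), and resamples the patterns
#' proportionally to total branch length: a random SNP falls on a
#' genealogy with probability proportional to its length, which is what
#' makes the pattern frequencies match the classical neutral SFS.
#'
#' @inheritParams simulate_genealogy
#' @param n_sims number of SNPs (genealogies) to simulate.
#' @param weight_trees resample genealogies by total branch length
#'   (default); `FALSE` returns one unweighted pattern per genealogy.
#' @return integer matrix `n_sims x n_demes` of derived-allele counts.
#' @export
simulate_site_patterns <- function(model, params, n_sims, seed,
                                   weight_trees = TRUE) {
  flat <- instantiate_model(model, params)
  res <- .sim_site_patterns_cpp(flat, as.integer(n_sims), as.double(seed))
  pat <- res$patterns
  if (weight_trees) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed %% 2147483647)
    idx <- sample.int(nrow(pat), nrow(pat), replace = TRUE,
                      prob = res$weights)
    pat <- pat[idx, , drop = FALSE]
  }
  colnames(pat) <- model$demes
  pat
}

#' Monte Carlo estimate of the expected folded pairwise 2D SFS
#'
#' Simulates `n_sims` genealogies and accumulates, for every branch, its
#' length into the folded cell of its subtree pattern (the
#' Rao-Blackwellised estimator of the SNP sampling distribution: a random
#' segregating site hits a branch with probability proportional to its
#' length). Cell masses are then converted to probabilities over the
#' unmasked cells, with every unmasked cell receiving at least
#' `floor = 1/(10 * n_sims)` probability before renormalisation so that
#' composite log-likelihoods stay finite. Folding and masking match
#' [build_folded_2d_sfs()] exactly.
#'
#' @inheritParams simulate_genealogy
#' @param n_sims number of simulated genealogies.
#' @param pairs optional 2-column character matrix of deme pairs; default
#'   all unordered pairs.
#' @param floor minimum pre-renormalisation probability per unmasked cell.
#' @return list of `folded2dsfs` objects whose `prob` matrices sum to 1
#'   over unmasked cells (the `counts` field holds the accumulated
#'   branch-length masses).
#' @export
expected_pair_sfs <- function(model, params, n_sims, seed, pairs = NULL,
                              floor = 1 / (10 * n_sims)) {
  if (is.null(pairs)) pairs <- t(utils::combn(model$demes, 2))
  flat <- instantiate_model(model, params)
  pairs0 <- matrix(match(pairs, model$demes) - 1L, ncol = 2)
  res <- .sim_expected_sfs_cpp(flat, as.integer(n_sims), as.double(seed),
                               pairs0, FALSE)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    na <- model$sample_n[[a]]; nb <- model$sample_n[[b]]
    counts <- res$pair_mass[[i]]
    dimnames(counts) <- list(paste0("d0_", 0:na), paste0("d1_", 0:nb))
    sfs <- .new_folded2dsfs(counts, .sfs_mask(na, nb), a, b, na, nb,
                            n_snps_used = n_sims)
    out[[i]] <- .sfs_counts_to_probs(sfs, floor = floor)
  }
  names(out) <- paste(pairs[, 1], pairs[, 2], sep = "|")
  out
}

#' Monte Carlo estimate of the folded 1D SFS of one deme
#'
#' Branch-length-weighted estimate of the folded within-deme spectrum,
#' normalised over the deme-segregating classes.
#'
#' @inheritParams expected_pair_sfs
#' @param deme deme name.
#' @return named numeric vector of folded minor-allele-count proportions
#'   (classes `1 .. floor(n/2)`).
#' @export
expected_sfs_1d <- function(model, params, n_sims, seed,
                            deme = model$demes[1]) {
  flat <- instantiate_model(model, params)
  d <- match(deme, model$demes)
  res <- .sim_expected_sfs_cpp(flat, as.integer(n_sims), as.double(seed),
                               matrix(integer(0), 0, 2), TRUE)
  mass <- res$deme_mass[[d]]          # unfolded classes 0..n
  n <- model$sample_n[[deme]]
  folded <- numeric(floor(n / 2))
  for (i in seq_len(n - 1)) {
    f <- min(i, n - i)
    folded[f] <- folded[f] + mass[i + 1]
  }
  stats::setNames(folded / sum(folded), seq_len(floor(n / 2)))
}
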