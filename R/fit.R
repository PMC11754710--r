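#' Fit a demographic model to observed folded pairwise spectra
#'
#' Maximises the composite log10 likelihood by multi-start stochastic
#' hill climbing: each replicate draws `n_starts` random candidates on
#' the parameter ranges (log-uniform for log-scale parameters), keeps the
#' best-scoring one as its start point, and then runs `n_cycles`
#' optimisation cycles. A cycle re-estimates the expected SFS
#' by `n_sims` coalescent simulations and performs one coordinate-wise
#' pass of shrinking line-search steps on the transformed parameters,
#' using common random numbers (one fixed simulation seed per cycle,
#' shared by all replicates) so that within-cycle comparisons are not
#' dominated by Monte Carlo noise. All replicates are finally re-scored
#' with a common seed and the best one is returned (ties broken by the
#' lower replicate index, so results do not depend on execution order).
#'
#' @param model a `demographic_model` (fixed parameters stay fixed).
#' @param obs list of observed `folded2dsfs` (e.g. [all_pair_sfs()]).
#' @param n_sims coalescent simulations per likelihood evaluation.
#' @param n_cycles optimisation cycles per replicate.
#' @param n_replicates independent optimisation replicates.
#' @param seed integer master seed (drives start points, cycle seeds and
#'   the final-scoring seed).
#' @param n_starts random start candidates scored once per replicate; the
#'   best becomes the replicate's start point (1 = a single uniform draw).
#' @param step_init,step_final first/last cycle line-search step, as a
#'   fraction of each transformed parameter range.
#' @param verbose print per-replicate progress.
#' @return a `fit_result`: best `params`, `MaxEstLhood` and `MaxObsLhood`
#'   (log10), `k`, `AIC = 2k - 2 ln(10) MaxEstLhood`, the winning
#'   `replicate` index and all per-replicate likelihood `traces`.
#' @export
fit_model <- function(model, obs, n_sims = 100000, n_cycles = 60,
                      n_replicates = 100, seed = 1, n_starts = 4,
                      step_init = 0.25, step_final = 0.02,
                      verbose = FALSE) {
  obs <- .as_sfs_list(obs)
  pairs <- t(vapply(obs, function(o) c(o$deme_a, o$deme_b), character(2)))
  if (!all(pairs %in% model$demes))
    stop("observed spectra involve demes absent from the model")
  max_obs <- max_observed_log10_likelihood(obs)
  free <- .free_params(model)
  if (length(free) == 0 && n_cycles > 0) n_cycles <- 0
  floor_p <- 1 / (10 * n_sims)

  trans <- function(p, x) if (p$scale == "log") log(x) else x
  untrans <- function(p, z) if (p$scale == "log") exp(z) else z

  eval_ll <- function(full, sim_seed) {
    exp_sfs <- expected_pair_sfs(model, full, n_sims, sim_seed,
                                 pairs = pairs, floor = floor_p)
    composite_log10_likelihood(obs, exp_sfs)
  }
  cycle_seed <- function(cyc) (seed * 100003 + cyc * 7919) %% 2147483647
  final_seed <- cycle_seed(n_cycles + 1)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed((seed * 131 + r) %% 2147483647)
    full <- sample_params(model)
    if (n_starts > 1 && n_cycles > 0 && length(free) > 0) {
      s0 <- cycle_seed(1)
      best_start_ll <- eval_ll(full, s0)
      for (i in seq_len(n_starts - 1)) {
        cand <- sample_params(model)
        ll <- eval_ll(cand, s0)
        if (ll > best_start_ll) {
          best_start_ll <- ll
          full <- cand
        }
      }
    }
    trace <- matrix(NA_real_, max(n_cycles, 0), 2,
                    dimnames = list(NULL, c("cycle_start", "cycle_end")))
    steps <- if (n_cycles > 1)
      step_init * (step_final / step_init)^((seq_len(n_cycles) - 1) /
                                              (n_cycles - 1))
    else rep(step_init, n_cycles)
    for (cyc in seq_len(n_cycles)) {
      sseed <- cycle_seed(cyc)
      cur <- eval_ll(full, sseed)
      trace[cyc, 1] <- cur
      for (nm in names(free)) {
        p <- free[[nm]]
        zl <- trans(p, p$low); zh <- trans(p, p$high)
        z0 <- trans(p, full[[nm]])
        dz <- steps[cyc] * (zh - zl)
        try_z <- function(cand_z) {
          cand_z <- min(max(cand_z, zl), zh)
          if (cand_z == z0) return(FALSE)
          cand <- full
          cand[[nm]] <- untrans(p, cand_z)
          if (length(.check_constraints(model, cand)) > 0) return(FALSE)
          ll <- eval_ll(cand, sseed)
          if (ll > cur) {  # accepted moves never decrease the cycle's ll
            cur <<- ll
            full <<- cand
            z0 <<- cand_z
            TRUE
          } else FALSE
        }
        # bracketing pass, then continuation in the improving direction
        dir <- 0
        if (try_z(z0 + dz)) dir <- 1
        else if (try_z(z0 - dz)) dir <- -1
        if (dir != 0) {
          for (ext in seq_len(4)) if (!try_z(z0 + dir * dz)) break
        }
      }
      trace[cyc, 2] <- cur
    }
    final_ll <- eval_ll(full, final_seed)
    reps[[r]] <- list(params = full, ll = final_ll, trace = trace)
    if (verbose)
      message(sprintf("replicate %d/%d: log10 L = %.3f",
                      r, n_replicates, final_ll))
  }
  lls <- vapply(reps, `[[`, numeric(1), "ll")
  best <- which.max(lls)  # which.max takes the first (lowest index) on ties
  res <- reps[[best]]
  structure(list(
    model = model$name, n_demes = length(model$demes),
    params = res$params, MaxEstLhood = res$ll, MaxObsLhood = max_obs,
    k = model$k, AIC = aic_from_log10(res$ll, model$k),
    replicate = best,
    traces = lapply(reps, `[[`, "trace"),
    replicate_lhoods = lls,
    n_sims = n_sims, n_cycles = n_cycles, n_replicates = n_replicates,
    seed = seed
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit of model %s: log10 L = %.3f (ceiling %.3f), k = %d, AIC = %.2f\n",
              x$model, x$MaxEstLhood, x$MaxObsLhood, x$k, x$AIC))
  cat("  best replicate:", x$replicate, "of", x$n_replicates, "\n")
  print(round(x$params, 6))
  invisible(x)
}

#' AIC model-selection rule
#' @param delta_aic_threshold positive difference in AIC scores treated as
#'   decisive support (default 10).
#' @export
selection_rule <- function(delta_aic_threshold = 10) {
  stopifnot(delta_aic_threshold > 0)
  structure(list(delta_aic_threshold = delta_aic_threshold),
            class = "selection_rule")
}

#' Rank fitted models by AIC
#'
#' Spectra observed under 3-deme and 4-deme partitions are different data,
#' so fits with different deme counts must never be ranked together; mixing
#' them is an error.
#'
#' @param fits list of `fit_result` objects for the same observed spectra.
#' @param rule a [selection_rule()].
#' @return data.frame sorted by AIC with `delta_aic`, the
#'   observed/estimated log-likelihood ratio, and a `significant` flag on
#'   the best model (second-best `delta_aic` at least the threshold).
#' @export
compare_models <- function(fits, rule = selection_rule()) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  nd <- vapply(fits, `[[`, numeric(1), "n_demes")
  if (length(unique(nd)) > 1)
    stop("cannot compare fits with different deme counts (",
         paste(unique(nd), collapse = " vs "),
         "): their observed spectra differ")
  df <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    MaxEstLhood = vapply(fits, `[[`, numeric(1), "MaxEstLhood"),
    MaxObsLhood = vapply(fits, `[[`, numeric(1), "MaxObsLhood"),
    AIC = vapply(fits, `[[`, numeric(1), "AIC"),
    stringsAsFactors = FALSE
  )
  df$obs_est_ratio <- df$MaxObsLhood / df$MaxEstLhood
  df <- df[order(df$AIC), , drop = FALSE]
  df$delta_aic <- df$AIC - df$AIC[1]
  df$significant <- FALSE
  if (nrow(df) > 1)
    df$significant[1] <- df$delta_aic[2] >= rule$delta_aic_threshold
  rownames(df) <- NULL
  df
}

#' Parametric-bootstrap confidence intervals for fitted parameters
#'
#' Simulates `n_pseudo` pseudoreplicate spectra under the fitted
#' parameters with the observed SNP totals, refits each with `n_reps`
#' replicates, and summarises the per-pseudoreplicate best estimates by
#' their mean and the \[2.5%, 97.5%\] percentile interval.
#'
#' @param model a `demographic_model`.
#' @param best_params fitted parameter vector (over all model parameters).
#' @param n_snps SNP total per pair: one number or a vector matching the
#'   pair spectra.
#' @param n_pseudo number of pseudoreplicate spectra.
#' @param n_reps fit replicates per pseudoreplicate.
#' @param n_sims,n_cycles fitting scale per pseudoreplicate refit.
#' @param exp_n_sims simulations used for the generating expected SFS.
#' @param seed integer master seed.
#' @param verbose print progress.
#' @return a `bootstrap_result`: per-parameter `mean`, `ci` (2 x k matrix)
#'   and the `estimates` matrix (`n_pseudo` rows).
#' @export
parametric_bootstrap <- function(model, best_params, n_snps,
                                 n_pseudo = 100, n_reps = 100,
                                 n_sims = 100000, n_cycles = 60,
                                 exp_n_sims = max(200000, n_sims),
                                 seed = 1, verbose = FALSE) {
  viol <- validate_event_order(model, best_params)
  if (length(viol) > 0)
    stop("best_params invalid for model: ", paste(viol, collapse = "; "))
  est <- NULL
  for (b in seq_len(n_pseudo)) {
    pseudo <- pseudoreplicate_sfs(model, best_params, n_snps,
                                  seed = (seed * 31 + b) %% 2147483647,
                                  n_sims = exp_n_sims)
    fit <- fit_model(model, pseudo, n_sims = n_sims, n_cycles = n_cycles,
                     n_replicates = n_reps,
                     seed = (seed * 977 + b) %% 2147483647)
    est <- rbind(est, fit$params)
    if (verbose) message("pseudoreplicate ", b, "/", n_pseudo, " done")
  }
  free_names <- names(.free_params(model))
  ci <- apply(est, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("2.5%", "97.5%")
  structure(list(mean = colMeans(est), ci = ci, estimates = est,
                 n_pseudoreplicates = n_pseudo, free = free_names),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Parametric bootstrap over", x$n_pseudoreplicates,
      "pseudoreplicates\n")
  out <- rbind(mean = x$mean, x$ci)
  print(t(round(out[, x$free, drop = FALSE], 6)))
  invisible(x)
}
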