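#' Composite log10 likelihood of observed spectra under expected cell
#' probabilities
#'
#' Treats the unmasked cells of each pairwise folded spectrum as
#' independent multinomial draws: the statistic is
#' `sum over pairs, unmasked cells of m_cell * log10(p_cell)`, with the
#' expected probabilities renormalised over unmasked cells. Masked cells
#' (pair-monomorphic, pair singletons, fold-unreachable) contribute
#' nothing, mirroring the "ignore singletons and monomorphic sites"
#' convention of SNP-conditioned SFS fitting.
#'
#' @param obs list of `folded2dsfs` count spectra.
#' @param exp matched list of `folded2dsfs` objects carrying `prob`
#'   matrices (from [expected_pair_sfs()]); same pairs, shapes and masks.
#' @return composite log10 likelihood (a non-positive real for count data).
#' @export
composite_log10_likelihood <- function(obs, exp) {
  obs <- .as_sfs_list(obs)
  exp <- .as_sfs_list(exp)
  stopifnot(length(obs) == length(exp))
  ll <- 0
  for (i in seq_along(obs)) {
    o <- obs[[i]]; e <- exp[[i]]
    if (o$n_a != e$n_a || o$n_b != e$n_b ||
        !identical(unname(o$mask), unname(e$mask)))
      stop("observed and expected spectra have mismatched shape or mask (",
           o$deme_a, "|", o$deme_b, ")")
    un <- !o$mask
    m <- o$counts[un]
    p <- e$prob[un]
    p <- p / sum(p)
    if (any(p <= 0 & m > 0))
      stop("expected probability 0 on an observed unmasked cell: ",
           "probability floor guarantee violated")
    nz <- m > 0
    ll <- ll + sum(m[nz] * log10(p[nz]))
  }
  ll
}

#' Likelihood ceiling: observed spectra evaluated at their own proportions
#'
#' The maximum the composite log10 likelihood can reach for the given
#' counts (Gibbs' inequality): `sum m_cell * log10(m_cell / M_pair)` over
#' unmasked cells, with `M_pair` the unmasked total of that pair.
#'
#' @param obs list of `folded2dsfs` count spectra.
#' @return log10 likelihood ceiling.
#' @export
max_observed_log10_likelihood <- function(obs) {
  obs <- .as_sfs_list(obs)
  if (length(obs) == 0) stop("obs must be non-empty")
  ll <- 0
  for (o in obs) {
    m <- o$counts[!o$mask]
    M <- sum(m)
    if (M == 0) next
    nz <- m > 0
    ll <- ll + sum(m[nz] * log10(m[nz] / M))
  }
  ll
}

.as_sfs_list <- function(x) {
  if (inherits(x, "folded2dsfs")) list(x) else x
}

#' AIC from a log10 composite likelihood
#' @param log10_lik maximised composite log10 likelihood.
#' @param k number of free parameters.
#' @return `2k - 2 ln(10) log10_lik`.
#' @export
aic_from_log10 <- function(log10_lik, k) 2 * k - 2 * log(10) * log10_lik
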