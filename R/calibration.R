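#' Calibration constants for divergence-time conversion
#'
#' Defaults are the *Arabidopsis thaliana* per-generation mutation rate
#' (5.9e-9 substitutions/site/generation) and a 3-year generation time,
#' the values appropriate for slow-maturing perennial forbs of the
#' *Phyteuma spicatum* group.
#'
#' @param mu substitutions/site/generation, > 0.
#' @param gen_time years per generation, > 0.
#' @export
calibration_constants <- function(mu = 5.9e-9, gen_time = 3) {
  stopifnot(mu > 0, gen_time > 0)
  structure(list(mu = mu, gen_time = gen_time),
            class = "calibration_constants")
}

#' Convert a pairwise genetic distance to generations since divergence
#'
#' A distance of `d` substitutions/site between two lineages accumulates
#' along both branches, so the time back to their common ancestor is
#' `d / (2 mu)` generations.
#'
#' @param d genetic distance in substitutions/site, non-negative.
#' @param const a [calibration_constants()].
#' @return generations to the common ancestor.
#' @export
distance_to_generations <- function(d, const = calibration_constants()) {
  if (any(d < 0)) stop("genetic distance must be non-negative")
  d / (2 * const$mu)
}

#' Convert generations to years
#' @param t generations, non-negative.
#' @param const a [calibration_constants()].
#' @return `gen_time * t` years.
#' @export
generations_to_years <- function(t, const = calibration_constants()) {
  if (any(t < 0)) stop("generations must be non-negative")
  const$gen_time * t
}

#' Divergence-time sampling bounds from a genetic-distance range
#'
#' Converts the minimum and maximum pairwise distances to generations and
#' rounds each up to the next multiple of `granularity`, yielding the
#' sampling range for the root divergence-time parameter (`TDIV_ANC`).
#' Rounding up (rather than outward) keeps the lower bound above the
#' youngest distance-compatible age.
#'
#' @param d_min,d_max distance range in substitutions/site,
#'   `0 <= d_min <= d_max`.
#' @param const a [calibration_constants()].
#' @param granularity rounding granularity in generations (default 1000;
#'   1 leaves the converted values untouched).
#' @return numeric `c(low, high)` in generations.
#' @export
prior_bounds_from_distances <- function(d_min, d_max,
                                        const = calibration_constants(),
                                        granularity = 1000) {
  if (d_min > d_max) stop("d_min must not exceed d_max")
  g <- ceiling(distance_to_generations(c(d_min, d_max), const) /
                 granularity) * granularity
  if (g[1] == g[2])
    warning("degenerate zero-width sampling range [", g[1], ", ", g[2], "]")
  stats::setNames(g, c("low", "high"))
}
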