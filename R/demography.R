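#' Demographic models as typed event schedules
#'
#' A demographic model is a list of demes with diploid effective sizes, a
#' time-ordered schedule of events (lineage merges, admixture foundings,
#' instantaneous size changes), a migration-rate epoch, and a set of named
#' free parameters with search ranges. Event fields and migration entries
#' may be numeric constants or character expressions in the parameter
#' names (e.g. `"0.005 * N_PGAL"`), resolved by [instantiate_model()].
#'
#' Time is measured in generations before present; sizes are diploid
#' individuals; migration rates are backward per-generation per-lineage
#' probabilities.
#'
#' @param name model label.
#' @param demes character vector of deme names (sampling order).
#' @param sample_n named integer vector, haploid sample size per deme.
#' @param size named character/numeric vector: present diploid size of each
#'   deme (usually a parameter name).
#' @param events list of events, each a list with `type` one of
#'   `"merge"` (`t`, `source`, `dest`), `"admix"` (`t`, `hybrid`,
#'   `parent_a`, `parent_b`, `alpha`) or `"resize"` (`t`, `deme`, `new_N`).
#' @param migration named list `"from>to" = rate` (parameter name or number);
#'   entries absent default to zero. Applies while both demes are extant.
#' @param params list of parameter specs from [param_spec()].
#' @param constraints character vector of inequality expressions over
#'   parameter names that any concrete parameter vector must satisfy.
#' @return an object of class `demographic_model`.
#' @export
demographic_model <- function(name, demes, sample_n, size, events,
                              migration = list(), params = list(),
                              constraints = character()) {
  stopifnot(length(demes) >= 1, !anyDuplicated(demes))
  sample_n <- sample_n[demes]
  if (anyNA(sample_n)) stop("sample_n must name every deme")
  if (any(sample_n %% 2 != 0) || any(sample_n < 0))
    stop("haploid sample sizes must be even and non-negative")
  size <- size[demes]
  if (anyNA(size)) stop("size must name every deme")
  if (length(params) > 0)
    names(params) <- vapply(params, `[[`, "", "name")
  free <- vapply(params, function(p) !isTRUE(p$fixed), logical(1))
  m <- structure(list(
    name = name, demes = demes,
    sample_n = stats::setNames(as.integer(sample_n), demes),
    size = size, events = events, migration = migration,
    params = params, constraints = constraints,
    k = sum(free)
  ), class = "demographic_model")
  m
}

#' Free-parameter specification
#'
#' @param name parameter label (e.g. `"TDIV_ANC"`, `"MIG_GAL_SPI"`).
#' @param low,high search-range bounds, `low < high`.
#' @param scale `"linear"` or `"log"` (log-uniform sampling and log-space
#'   optimisation steps).
#' @param fixed if `TRUE` the parameter is held at `value` and does not
#'   count towards `k`.
#' @param value fixed value (required when `fixed = TRUE`).
#' @export
param_spec <- function(name, low, high, scale = c("linear", "log"),
                       fixed = FALSE, value = NA_real_) {
  scale <- match.arg(scale)
  if (!fixed && !(low < high)) stop("parameter range must have low < high")
  if (scale == "log" && low <= 0) stop("log-scale parameter needs low > 0")
  list(name = name, low = low, high = high, scale = scale,
       fixed = fixed, value = value)
}

## ---- catalogue -------------------------------------------------------------

# default search ranges (user-overridable through build_model overrides)
.rc_defaults <- list(
  N_low = 100, N_high = 2e5,
  mig_low = 1e-8, mig_high = 1e-3,
  alpha_low = 0.01, alpha_high = 0.99,
  t_low = 100, t_high = 139000,
  tanc_low = 42000, tanc_high = 139000,
  bottleneck_frac = 0.005, bottleneck_gens = 50
)

.rc_model_names <- c(
  "3-dicho", "3-dicho+mig", "3-hybGAL",
  "4-dicho-a", "4-dicho-b", "4-dicho+mig-a", "4-dicho+mig-b",
  "4-hybSPW", "4-hybGALearly", "4-hybGALearly+mig",
  "4-hybGALlate", "4-hybGAL+hybSPW", "4-hybGALSPW"
)

.p_N <- function(name, d = .rc_defaults) param_spec(name, d$N_low, d$N_high, "log")
.p_m <- function(name, d = .rc_defaults) param_spec(name, d$mig_low, d$mig_high, "log")
.p_t <- function(name, d = .rc_defaults) param_spec(name, d$t_low, d$t_high, "linear")
.p_a <- function(name, d = .rc_defaults) param_spec(name, d$alpha_low, d$alpha_high, "linear")

.merge_with_resize <- function(t, source, dest, anc_size) {
  list(
    list(type = "merge", t = t, source = source, dest = dest),
    list(type = "resize", t = t, deme = dest, new_N = anc_size)
  )
}

#' Build one of the catalogued speciation models
#'
#' Returns one of the thirteen competing specifications of the origin of
#' *Ph. gallicum*: three 3-deme models (the two `Ph. spicatum` lineages
#' pooled) and ten 4-deme models (western `Ph. spicatum` a separate deme,
#' counting the two divergence-order submodels of `4-dicho` and
#' `4-dicho+mig`). All models carry background `Pnig`/`Pspi` gene flow
#' (4-deme: `Pnig`/`PspE` only) and, in 4-deme models, `PspW`/`PspE` gene
#' flow; `"+mig"` models add focal `Pgal`/`Pspi(W)` gene flow. Every
#' hybrid-founded deme carries a post-hybridisation bottleneck (0.5% of
#' present size for 50 generations). The root divergence time `TDIV_ANC`
#' searches the calibrated range \[42,000, 139,000\] generations.
#'
#' @param name one of `model_names()`. `"4-dicho"`/`"4-dicho+mig"` accept a
#'   `submodel` suffix `-a` (Pgal/Pnig split older) or `-b` (spicatum split
#'   older), or the `submodel` argument.
#' @param overrides named list fixing parameters to values (each must lie
#'   inside the parameter's range) — fixed parameters do not count in `k`.
#' @param submodel `"a"` or `"b"` for the dichotomous 4-deme models.
#' @param sample_n optional named haploid sample sizes replacing the
#'   defaults (3-deme: Pgal 12, Pnig 16, Pspi 32; 4-deme: Pgal 12, Pnig 16,
#'   PspE 24, PspW 8).
#' @return a `demographic_model`.
#' @export
build_model <- function(name, overrides = NULL, submodel = NULL,
                        sample_n = NULL) {
  if (name %in% c("4-dicho", "4-dicho+mig")) {
    if (is.null(submodel)) stop("model '", name, "' needs submodel 'a' or 'b'")
    name <- paste0(name, "-", submodel)
  }
  if (!name %in% .rc_model_names)
    stop("unknown model '", name, "'; valid names: ",
         paste(.rc_model_names, collapse = ", "))
  d <- .rc_defaults
  three <- startsWith(name, "3")
  if (three) {
    demes <- c("Pgal", "Pnig", "Pspi")
    def_n <- c(Pgal = 12L, Pnig = 16L, Pspi = 32L)
    spi <- "Pspi"
  } else {
    demes <- c("Pgal", "Pnig", "PspE", "PspW")
    def_n <- c(Pgal = 12L, Pnig = 16L, PspE = 24L, PspW = 8L)
    spi <- "PspE"
  }
  if (!is.null(sample_n)) def_n[names(sample_n)] <- as.integer(sample_n)

  size <- stats::setNames(paste0("N_", toupper(sub("^P", "P", demes))), demes)
  size[] <- c(Pgal = "N_PGAL", Pnig = "N_PNIG", Pspi = "N_PSPI",
              PspE = "N_PSPE", PspW = "N_PSPW")[demes]
  params <- list(.p_N("N_PGAL"), .p_N("N_PNIG"))
  params <- c(params, if (three) list(.p_N("N_PSPI"))
              else list(.p_N("N_PSPE"), .p_N("N_PSPW")))
  mig <- list()
  # background gene flow: Pnig <-> Pspi (4-deme: eastern lineage only)
  mig[[paste0("Pnig>", spi)]] <- "MIG_NIG_SPI"
  mig[[paste0(spi, ">Pnig")]] <- "MIG_SPI_NIG"
  params <- c(params, list(.p_m("MIG_NIG_SPI"), .p_m("MIG_SPI_NIG")))
  if (!three) {
    mig[["PspW>PspE"]] <- "MIG_SPW_SPE"
    mig[["PspE>PspW"]] <- "MIG_SPE_SPW"
    params <- c(params, list(.p_m("MIG_SPW_SPE"), .p_m("MIG_SPE_SPW")))
  }
  params <- c(params, list(.p_t("TDIV_GAL"),
                           param_spec("TDIV_ANC", d$tanc_low, d$tanc_high)))
  if (!three) params <- c(params, list(.p_t("TDIV_SPW")))
  constraints <- c("TDIV_GAL < TDIV_ANC")
  if (!three) constraints <- c(constraints, "TDIV_SPW < TDIV_ANC")
  events <- list()
  gap <- d$bottleneck_gens  # clearance so bottleneck windows stay event-free

  add_hyb <- function(deme, t_found, pa, pb, alpha, present) {
    c(list(list(type = "resize",
                t = sprintf("max(%s - %d, 0)", t_found, d$bottleneck_gens),
                deme = deme,
                new_N = sprintf("%g * (%s)", d$bottleneck_frac, present)),
           list(type = "admix", t = t_found, hybrid = deme,
                parent_a = pa, parent_b = pb, alpha = alpha)))
  }

  if (name %in% c("3-dicho", "3-dicho+mig")) {
    params <- c(params, list(.p_N("N_ANC_GAL"), .p_N("N_ANC")))
    events <- c(.merge_with_resize("TDIV_GAL", "Pgal", "Pnig", "N_ANC_GAL"),
                .merge_with_resize("TDIV_ANC", "Pnig", "Pspi", "N_ANC"))
    if (name == "3-dicho+mig") {
      mig[["Pgal>Pspi"]] <- "MIG_GAL_SPI"
      mig[["Pspi>Pgal"]] <- "MIG_SPI_GAL"
      params <- c(params, list(.p_m("MIG_GAL_SPI"), .p_m("MIG_SPI_GAL")))
    }
  } else if (name == "3-hybGAL") {
    params <- c(params, list(.p_N("N_ANC"), .p_a("ALPHA_GAL")))
    events <- c(add_hyb("Pgal", "TDIV_GAL", "Pnig", "Pspi", "ALPHA_GAL", "N_PGAL"),
                .merge_with_resize("TDIV_ANC", "Pnig", "Pspi", "N_ANC"))
  } else if (name %in% c("4-dicho-a", "4-dicho-b",
                         "4-dicho+mig-a", "4-dicho+mig-b")) {
    params <- c(params, list(.p_N("N_ANC_GAL"), .p_N("N_ANC_SPW"), .p_N("N_ANC")))
    events <- c(.merge_with_resize("TDIV_SPW", "PspW", "PspE", "N_ANC_SPW"),
                .merge_with_resize("TDIV_GAL", "Pgal", "Pnig", "N_ANC_GAL"),
                .merge_with_resize("TDIV_ANC", "Pnig", "PspE", "N_ANC"))
    constraints <- c(constraints,
                     if (endsWith(name, "-a")) "TDIV_SPW < TDIV_GAL"
                     else "TDIV_GAL < TDIV_SPW")
    if (startsWith(name, "4-dicho+mig")) {
      mig[["Pgal>PspW"]] <- "MIG_GAL_SPW"
      mig[["PspW>Pgal"]] <- "MIG_SPW_GAL"
      params <- c(params, list(.p_m("MIG_GAL_SPW"), .p_m("MIG_SPW_GAL")))
    }
  } else if (name == "4-hybSPW") {
    params <- c(params, list(.p_N("N_ANC_GAL"), .p_N("N_ANC"), .p_a("ALPHA_SPW")))
    events <- c(add_hyb("PspW", "TDIV_SPW", "Pgal", "PspE", "ALPHA_SPW", "N_PSPW"),
                .merge_with_resize("TDIV_GAL", "Pgal", "Pnig", "N_ANC_GAL"),
                .merge_with_resize("TDIV_ANC", "Pnig", "PspE", "N_ANC"))
    constraints <- c(constraints, sprintf("TDIV_SPW < TDIV_GAL - %d", gap))
  } else if (name %in% c("4-hybGALearly", "4-hybGALearly+mig")) {
    params <- c(params, list(.p_N("N_ANC_SPW"), .p_N("N_ANC"), .p_a("ALPHA_GAL")))
    events <- c(.merge_with_resize("TDIV_SPW", "PspW", "PspE", "N_ANC_SPW"),
                add_hyb("Pgal", "TDIV_GAL", "Pnig", "PspE", "ALPHA_GAL", "N_PGAL"),
                .merge_with_resize("TDIV_ANC", "Pnig", "PspE", "N_ANC"))
    constraints <- c(constraints, "TDIV_SPW < TDIV_GAL")
    if (name == "4-hybGALearly+mig") {
      mig[["Pgal>PspW"]] <- "MIG_GAL_SPW"
      mig[["PspW>Pgal"]] <- "MIG_SPW_GAL"
      params <- c(params, list(.p_m("MIG_GAL_SPW"), .p_m("MIG_SPW_GAL")))
    }
  } else if (name == "4-hybGALlate") {
    params <- c(params, list(.p_N("N_ANC_SPW"), .p_N("N_ANC"), .p_a("ALPHA_GAL")))
    events <- c(add_hyb("Pgal", "TDIV_GAL", "Pnig", "PspW", "ALPHA_GAL", "N_PGAL"),
                .merge_with_resize("TDIV_SPW", "PspW", "PspE", "N_ANC_SPW"),
                .merge_with_resize("TDIV_ANC", "Pnig", "PspE", "N_ANC"))
    constraints <- c(constraints, "TDIV_GAL < TDIV_SPW")
  } else if (name == "4-hybGAL+hybSPW") {
    params <- c(params, list(.p_N("N_ANC"), .p_a("ALPHA_GAL"), .p_a("ALPHA_SPW")))
    events <- c(add_hyb("PspW", "TDIV_SPW", "Pgal", "PspE", "ALPHA_SPW", "N_PSPW"),
                add_hyb("Pgal", "TDIV_GAL", "Pnig", "PspE", "ALPHA_GAL", "N_PGAL"),
                .merge_with_resize("TDIV_ANC", "Pnig", "PspE", "N_ANC"))
    constraints <- c(constraints, sprintf("TDIV_SPW < TDIV_GAL - %d", gap))
  } else if (name == "4-hybGALSPW") {
    params <- c(params, list(.p_N("N_ANC_GALSPW"), .p_N("N_ANC"), .p_a("ALPHA_GAL")))
    events <- c(.merge_with_resize("TDIV_SPW", "PspW", "Pgal", "N_ANC_GALSPW"),
                add_hyb("Pgal", "TDIV_GAL", "Pnig", "PspE", "ALPHA_GAL",
                        "N_ANC_GALSPW"),
                .merge_with_resize("TDIV_ANC", "Pnig", "PspE", "N_ANC"))
    constraints <- c(constraints, sprintf("TDIV_SPW < TDIV_GAL - %d", gap))
  }

  names(params) <- vapply(params, `[[`, "", "name")
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% names(params))
        stop("override for unknown parameter '", nm, "'")
      p <- params[[nm]]
      v <- overrides[[nm]]
      if (v < p$low || v > p$high)
        stop("override ", nm, " = ", v, " outside range [", p$low, ", ",
             p$high, "]")
      params[[nm]]$fixed <- TRUE
      params[[nm]]$value <- v
    }
  }
  demographic_model(name, demes, def_n, size, events, mig, params, constraints)
}

#' Names of all catalogued models
#' @return character vector (3 three-deme and 10 four-deme specifications).
#' @export
model_names <- function() .rc_model_names

#' Model catalogue summary
#' @return data.frame with model name, number of demes and free-parameter
#'   count `k`.
#' @export
model_catalogue <- function() {
  rows <- lapply(.rc_model_names, function(nm) {
    m <- build_model(nm)
    data.frame(model = nm, n_demes = length(m$demes), k = m$k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## ---- parameter handling ----------------------------------------------------

.free_params <- function(model) {
  model$params[!vapply(model$params, function(p) isTRUE(p$fixed), logical(1))]
}

.full_param_vector <- function(model, free_values) {
  out <- stats::setNames(numeric(length(model$params)), names(model$params))
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    out[nm] <- if (isTRUE(p$fixed)) p$value else free_values[[nm]]
  }
  out
}

.check_constraints <- function(model, params) {
  env <- list2env(as.list(params))
  ok <- vapply(model$constraints, function(cs) {
    isTRUE(eval(parse(text = cs), envir = env))
  }, logical(1))
  model$constraints[!ok]
}

#' Sample a concrete parameter vector from the search ranges
#'
#' Free parameters are drawn uniformly (log-uniformly for log-scale) on
#' their ranges; draws violating the model's order constraints are
#' rejected and redrawn.
#'
#' @param model a `demographic_model`.
#' @param max_tries rejection-sampling budget.
#' @return named numeric vector over all parameters (fixed ones at their
#'   fixed values).
#' @export
sample_params <- function(model, max_tries = 10000) {
  free <- .free_params(model)
  for (i in seq_len(max_tries)) {
    vals <- vapply(free, function(p) {
      if (p$scale == "log") exp(stats::runif(1, log(p$low), log(p$high)))
      else stats::runif(1, p$low, p$high)
    }, numeric(1))
    names(vals) <- names(free)
    full <- .full_param_vector(model, as.list(vals))
    if (length(.check_constraints(model, full)) == 0) return(full)
  }
  stop("could not sample parameters satisfying constraints in ",
       max_tries, " tries")
}

#' Check that a concrete parameter vector yields a valid event schedule
#'
#' Verifies the model's order constraints, that all event times are
#' non-negative with the root divergence oldest, and that no
#' post-hybridisation bottleneck window contains another event on the
#' same deme.
#'
#' @param model a `demographic_model`.
#' @param params named numeric vector over the model's parameters.
#' @return character vector of violations; empty when the schedule is valid.
#' @export
validate_event_order <- function(model, params) {
  viol <- .check_constraints(model, params)
  ev <- .resolve_events(model, params)
  if (nrow(ev$table) > 0) {
    if (any(ev$table$t < 0)) viol <- c(viol, "event with negative time")
    if ("TDIV_ANC" %in% names(params)) {
      t_anc <- params[["TDIV_ANC"]]
      if (any(ev$table$t > t_anc + 1e-9))
        viol <- c(viol, "event scheduled older than TDIV_ANC")
    }
    # bottleneck windows: a resize (bottleneck start) followed by the
    # founding admixture of the same deme must have no third event
    # touching that deme strictly inside (t_resize, t_admix)
    adm <- ev$table[ev$table$type == "admix", , drop = FALSE]
    for (i in seq_len(nrow(adm))) {
      h <- adm$deme_a[i]
      t1 <- adm$t[i]
      rs <- ev$table[ev$table$type == "resize" & ev$table$deme_a == h &
                       ev$table$t < t1, , drop = FALSE]
      if (nrow(rs) == 0) next
      t0 <- max(rs$t)
      touching <- ev$table$t > t0 + 1e-9 & ev$table$t < t1 - 1e-9 &
        (ev$table$deme_a == h | ev$table$deme_b == h | ev$table$deme_c == h)
      if (any(touching))
        viol <- c(viol, sprintf(
          "event inside the bottleneck window [%g, %g] of deme %s", t0, t1, h))
    }
  }
  viol
}

# resolve event expressions against a parameter vector; returns both a
# data.frame view and the numeric matrix the C++ engine consumes
.resolve_events <- function(model, params) {
  env <- list2env(as.list(params))
  dix <- stats::setNames(seq_along(model$demes) - 1L, model$demes)
  res <- function(x) {
    if (is.numeric(x)) return(x)
    eval(parse(text = x), envir = env)
  }
  n <- length(model$events)
  tab <- data.frame(t = numeric(n), type = character(n),
                    deme_a = character(n), deme_b = character(n),
                    deme_c = character(n), x = numeric(n),
                    stringsAsFactors = FALSE)
  mat <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    e <- model$events[[i]]
    t <- res(e$t)
    if (e$type == "merge") {
      tab[i, ] <- list(t, "merge", e$source, e$dest, "", NA_real_)
      mat[i, ] <- c(t, 0, dix[[e$source]], dix[[e$dest]], 0, 0)
    } else if (e$type == "admix") {
      a <- res(e$alpha)
      tab[i, ] <- list(t, "admix", e$hybrid, e$parent_a, e$parent_b, a)
      mat[i, ] <- c(t, 1, dix[[e$hybrid]], dix[[e$parent_a]],
                    dix[[e$parent_b]], a)
    } else if (e$type == "resize") {
      nn <- res(e$new_N)
      tab[i, ] <- list(t, "resize", e$deme, "", "", nn)
      mat[i, ] <- c(t, 2, dix[[e$deme]], 0, 0, nn)
    } else stop("unknown event type '", e$type, "'")
  }
  ord <- order(tab$t)
  list(table = tab[ord, , drop = FALSE], matrix = mat[ord, , drop = FALSE])
}

#' Resolve a model + parameter vector into the flat engine representation
#'
#' @param model a `demographic_model`.
#' @param params named numeric vector over the model's parameters.
#' @return list with `n_demes`, `sample_n`, `N`, `mig` (matrix) and the
#'   time-sorted numeric `events` matrix consumed by the simulator.
#' @export
instantiate_model <- function(model, params) {
  viol <- validate_event_order(model, params)
  if (length(viol) > 0)
    stop("invalid parameter vector: ", paste(viol, collapse = "; "))
  env <- list2env(as.list(params))
  res <- function(x) if (is.numeric(x)) x else eval(parse(text = x), envir = env)
  D <- length(model$demes)
  N <- vapply(model$size, res, numeric(1))
  mig <- matrix(0, D, D, dimnames = list(model$demes, model$demes))
  for (key in names(model$migration)) {
    ft <- strsplit(key, ">", fixed = TRUE)[[1]]
    mig[ft[1], ft[2]] <- res(model$migration[[key]])
  }
  ev <- .resolve_events(model, params)
  list(n_demes = D, sample_n = unname(model$sample_n), N = unname(N),
       mig = mig, events = ev$matrix, demes = model$demes)
}

## ---- serialisation ---------------------------------------------------------

#' Serialise a demographic model to JSON
#' @param model a `demographic_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- unclass(model)
  x$sample_n <- as.list(x$sample_n)
  x$size <- as.list(x$size)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Parse a demographic model from JSON
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  demographic_model(
    name = x$name, demes = unlist(x$demes),
    sample_n = unlist(x$sample_n), size = unlist(x$size),
    events = x$events, migration = x$migration,
    params = lapply(x$params, function(p) {
      param_spec(p$name, p$low, p$high, p$scale, isTRUE(p$fixed),
                 if (is.null(p$value) || is.na(p$value)) NA_real_ else p$value)
    }),
    constraints = as.character(unlist(x$constraints))
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model:", x$name, "\n")
  cat("  demes:", paste(sprintf("%s (n=%d)", x$demes, x$sample_n),
                        collapse = ", "), "\n")
  cat("  events:", length(x$events), " free parameters (k):", x$k, "\n")
  if (length(x$constraints))
    cat("  constraints:", paste(x$constraints, collapse = "; "), "\n")
  invisible(x)
}
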