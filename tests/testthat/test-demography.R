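test_that("model census: 3 three-deme and 10 four-deme specifications", {
  cat_tab <- model_catalogue()
  expect_equal(nrow(cat_tab), 13)
  expect_equal(sum(cat_tab$n_demes == 3), 3)
  expect_equal(sum(cat_tab$n_demes == 4), 10)
  # submodels a/b exist for both dichotomous 4-deme model families
  expect_true(all(c("4-dicho-a", "4-dicho-b",
                    "4-dicho+mig-a", "4-dicho+mig-b") %in% cat_tab$model))
})

test_that("migration-enabled models have strictly more free parameters", {
  k <- function(nm) build_model(nm)$k
  expect_gt(k("3-dicho+mig"), k("3-dicho"))
  expect_gt(k("4-dicho+mig-a"), k("4-dicho-a"))
  expect_gt(k("4-hybGALearly+mig"), k("4-hybGALearly"))
})

test_that("3-dicho has two merges, background migration only, no admixture", {
  m <- build_model("3-dicho")
  expect_equal(length(m$demes), 3)
  types <- vapply(m$events, `[[`, "", "type")
  expect_equal(sum(types == "merge"), 2)
  expect_equal(sum(types == "admix"), 0)
  expect_setequal(names(m$migration), c("Pnig>Pspi", "Pspi>Pnig"))
})

test_that("3-hybGAL founds Pgal by admixture with its bottleneck pair", {
  m <- build_model("3-hybGAL")
  types <- vapply(m$events, `[[`, "", "type")
  expect_true("admix" %in% types)
  adm <- m$events[[which(types == "admix")]]
  expect_equal(adm$hybrid, "Pgal")
  expect_setequal(c(adm$parent_a, adm$parent_b), c("Pnig", "Pspi"))
  expect_equal(adm$alpha, "ALPHA_GAL")
  # bottleneck: a resize of Pgal to 0.5% of present size, 50 generations
  # before the founding time
  rs <- m$events[[which(types == "resize" &
    vapply(m$events, function(e) identical(e$deme, "Pgal"), TRUE))]]
  expect_match(rs$t, "TDIV_GAL - 50")
  expect_match(rs$new_N, "0.005")
  p <- c(N_PGAL = 10000, N_PNIG = 10000, N_PSPI = 10000, N_ANC = 10000,
         ALPHA_GAL = 0.5, TDIV_GAL = 10000, TDIV_ANC = 50000,
         MIG_NIG_SPI = 1e-6, MIG_SPI_NIG = 1e-6)
  ev <- rangecoal:::.resolve_events(m, p)$table
  rs_row <- ev[ev$type == "resize" & ev$deme_a == "Pgal", ]
  expect_equal(rs_row$t, 9950)
  expect_equal(rs_row$x, 50)  # 0.005 * 10,000
})

test_that("dichotomous submodels differ only in the split-order constraint", {
  a <- build_model("4-dicho+mig", submodel = "a")
  b <- build_model("4-dicho+mig", submodel = "b")
  expect_identical(a$events, b$events)
  expect_identical(names(a$params), names(b$params))
  expect_true("TDIV_SPW < TDIV_GAL" %in% a$constraints)
  expect_true("TDIV_GAL < TDIV_SPW" %in% b$constraints)
  expect_error(build_model("4-dicho"), "submodel")
})

test_that("the 4-deme background gene flow involves PspE only", {
  for (nm in c("4-dicho-a", "4-hybSPW", "4-hybGALlate")) {
    m <- build_model(nm)
    expect_true(all(c("Pnig>PspE", "PspE>Pnig",
                      "PspW>PspE", "PspE>PspW") %in% names(m$migration)))
    expect_false(any(grepl("Pnig>PspW|PspW>Pnig", names(m$migration))))
  }
  # focal Pgal gene flow only in "+mig" models
  expect_false(any(grepl("Pgal", names(build_model("4-dicho-a")$migration))))
  expect_true(any(grepl("Pgal", names(build_model("4-dicho+mig-a")$migration))))
})

test_that("TDIV_ANC searches the calibrated range", {
  for (nm in model_names()) {
    p <- build_model(nm)$params[["TDIV_ANC"]]
    expect_equal(c(p$low, p$high), c(42000, 139000))
  }
})

test_that("unknown acronyms and bad overrides fail loudly", {
  expect_error(build_model("5-panmixia"), "valid names")
  expect_error(build_model("3-dicho", overrides = list(N_PGAL = 10)),
               "outside range")
  expect_error(build_model("3-dicho", overrides = list(NOPE = 1)),
               "unknown parameter")
  m <- build_model("3-dicho", overrides = list(TDIV_ANC = 52000))
  expect_equal(m$k, build_model("3-dicho")$k - 1)
})

test_that("event-order validation flags inverted and window-crossing schedules", {
  m <- build_model("3-dicho")
  p_ok <- c(N_PGAL = 1e4, N_PNIG = 1e4, N_PSPI = 1e4, N_ANC_GAL = 1e4,
            N_ANC = 1e4, TDIV_GAL = 15000, TDIV_ANC = 50000,
            MIG_NIG_SPI = 1e-6, MIG_SPI_NIG = 1e-6)
  expect_length(validate_event_order(m, p_ok), 0)
  p_bad <- p_ok
  p_bad["TDIV_GAL"] <- 60000
  expect_gt(length(validate_event_order(m, p_bad)), 0)
  # an event touching a hybrid deme inside its bottleneck window is flagged
  toy <- demographic_model(
    "toy-window", demes = c("H", "P", "Q"),
    sample_n = c(H = 4, P = 4, Q = 4),
    size = c(H = "N_H", P = "N_P", Q = "N_Q"),
    events = list(
      list(type = "resize", t = "T_H - 50", deme = "H", new_N = "0.005 * N_H"),
      list(type = "merge", t = "T_X", source = "Q", dest = "H"),
      list(type = "admix", t = "T_H", hybrid = "H", parent_a = "P",
           parent_b = "Q", alpha = 0.5),
      list(type = "merge", t = "T_ANC", source = "P", dest = "Q")),
    params = list(param_spec("N_H", 100, 2e5, "log"),
                  param_spec("N_P", 100, 2e5, "log"),
                  param_spec("N_Q", 100, 2e5, "log"),
                  param_spec("T_H", 100, 139000),
                  param_spec("T_X", 100, 139000),
                  param_spec("T_ANC", 42000, 139000)))
  base <- c(N_H = 1e4, N_P = 1e4, N_Q = 1e4,
            T_H = 1000, T_X = 975, T_ANC = 50000)
  expect_true(any(grepl("bottleneck window",
                        validate_event_order(toy, base))))
  base["T_X"] <- 500  # outside the window: fine
  expect_length(validate_event_order(toy, base), 0)
})

test_that("models serialise to JSON and back unchanged", {
  for (nm in c("3-dicho+mig", "4-hybGAL+hybSPW")) {
    m <- build_model(nm)
    m2 <- model_from_json(model_to_json(m))
    expect_equal(m2, m)
  }
})

test_that("sampled parameter vectors respect ranges and constraints", {
  set.seed(11)
  m <- build_model("4-hybSPW")
  for (i in 1:25) {
    p <- sample_params(m)
    expect_length(validate_event_order(m, p), 0)
    for (nm in names(m$params)) {
      spec <- m$params[[nm]]
      expect_gte(p[[nm]], spec$low)
      expect_lte(p[[nm]], spec$high)
    }
  }
})
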