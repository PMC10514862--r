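test_that("builtin presets expose the standard parameter defaults", {
  pres <- builtin_presets()
  expect_setequal(names(pres), c("GRE", "MP2RAGE", "SE", "FLAIR", "TBE", "DIR", "GenericIR"))
  defaults <- function(m) vapply(pres[[m]]$parameters, `[[`, numeric(1), "default")
  expect_identical(defaults("GRE"), c(TR = 113))
  expect_identical(defaults("MP2RAGE"), c(TI = 1816))
  expect_identical(defaults("SE"), c(TR = 8000, TE = 80))
  expect_identical(defaults("FLAIR"), c(TE = 80, TSAT = 1405, TI = 2075))
  expect_identical(defaults("TBE"), c(TR = 5020, TE = 1, TI = 795))
  expect_identical(defaults("DIR"), c(TR = 6670, TE = 80, TI1 = 2208, TI2 = 545))
})

test_that("preset invariants hold: symbols partitioned, defaults within bounds", {
  for (m in builtin_presets()) {
    syms <- free_symbols(m$equation)
    expect_true(all(syms %in% c(m$maps, names(m$parameters))), label = m$name)
    expect_length(intersect(m$maps, names(m$parameters)), 0)
    for (p in m$parameters) {
      expect_true(p$default >= p$min && p$default <= p$max, label = m$name)
    }
  }
})

test_that("model construction rejects invariant violations", {
  expect_error(signal_model("bad", "PD*TR", parameters = list(TR = 100), maps = character()),
               "not declared")
  expect_error(signal_model("bad", "PD*TR", parameters = list(TR = 100, PD = 1),
                            maps = "PD"), "both map and parameter")
  expect_error(signal_model("bad", "TR",
                            parameters = list(TR = list(default = 5, min = 10, max = 20))),
               "outside")
  expect_error(signal_model("bad", "TR",
                            parameters = list(TR = list(default = 5, min = -1, max = 20))),
               "min must be >= 0")
})

test_that("single-voxel GRE evaluation matches direct arithmetic", {
  grid <- ms_grid(c(1, 1, 1))
  maps <- map_set(
    quantitative_map("PD", array(800, c(1, 1, 1)), grid, units = "arbitrary"),
    quantitative_map("T1", array(1000, c(1, 1, 1)), grid, units = "ms"))
  vol <- evaluate_model(builtin_presets()$GRE, maps, scanner_parameters(TR = 113))
  expect_equal(vol$values[1, 1, 1], 800 * (1 - exp(-113 / 1000)), tolerance = 1e-12)
  expect_identical(vol$provenance$model, "GRE")
  expect_equal(unclass(vol$provenance$params)[["TR"]], 113)
})

test_that("SE limits: TE = 0 and TR very large recover PD", {
  maps <- random_map_set(c(4, 4, 4), seed = 5)
  vol <- evaluate_model(builtin_presets()$SE, maps, scanner_parameters(TR = 1e9, TE = 0))
  expect_lt(rel_err(vol$values, maps$maps$PD$values), 1e-6)
})

test_that("vectorized evaluation equals per-voxel scalar oracle for every preset", {
  maps <- random_map_set(c(8, 8, 8), seed = 11)
  for (m in builtin_presets()) {
    vol <- evaluate_model(m, maps)
    want <- oracle_volume(m, maps)
    expect_lt(rel_err(vol$values, want), 1e-6)
  }
})

test_that("abs-wrapped presets are non-negative everywhere", {
  maps <- random_map_set(c(8, 8, 8), seed = 13)
  for (nm in c("MP2RAGE", "FLAIR", "TBE", "DIR", "GenericIR")) {
    vol <- evaluate_model(builtin_presets()[[nm]], maps)
    expect_gte(min(vol$values), 0)
  }
})

test_that("SE signal is monotone in TE and TR", {
  maps <- random_map_set(c(4, 4, 4), seed = 17)
  se <- builtin_presets()$SE
  te_grid <- c(10, 40, 80, 160, 320)
  vols_te <- lapply(te_grid, function(te) {
    evaluate_model(se, maps, scanner_parameters(TR = 8000, TE = te))$values
  })
  for (i in seq_len(length(te_grid) - 1)) {
    expect_true(all(vols_te[[i + 1]] < vols_te[[i]]), label = "decreasing in TE")
  }
  tr_grid <- c(200, 800, 3200, 12800)
  vols_tr <- lapply(tr_grid, function(tr) {
    evaluate_model(se, maps, scanner_parameters(TR = tr, TE = 80))$values
  })
  for (i in seq_len(length(tr_grid) - 1)) {
    expect_true(all(vols_tr[[i + 1]] > vols_tr[[i]]), label = "increasing in TR")
  }
})

test_that("inversion-recovery nulls: T1 = TI/ln 2 gives zero signal", {
  # MP2RAGE and FLAIR null analytically; DIR nulls at roots located by an
  # independent 1-D root finder on its inversion-recovery factor
  grid <- ms_grid(c(2, 2, 1))
  mk <- function(t1) map_set(
    quantitative_map("T1", array(t1, c(2, 2, 1)), grid),
    quantitative_map("T2", array(90, c(2, 2, 1)), grid),
    quantitative_map("PD", array(0.8, c(2, 2, 1)), grid, units = "arbitrary"))

  mp <- builtin_presets()$MP2RAGE
  t1_null <- 1816 / log(2)
  vol <- evaluate_model(mp, mk(t1_null))
  expect_lt(max(vol$values), 1e-9)

  fl <- builtin_presets()$FLAIR
  t1_null <- 2075 / log(2)
  vol <- evaluate_model(fl, mk(t1_null))
  expect_lt(max(vol$values), 1e-9 * 0.8)

  dir_m <- builtin_presets()$DIR
  f <- function(t1) 1 - 2 * exp(-545 / t1) + 2 * exp(-(2208 + 545) / t1) - exp(-6670 / t1)
  # bracket the two sign changes of the double-inversion factor
  grid_t1 <- seq(50, 6000, by = 10)
  sgn <- sign(f(grid_t1))
  flips <- which(diff(sgn) != 0)
  expect_gte(length(flips), 1)
  for (ix in flips) {
    root <- stats::uniroot(f, c(grid_t1[ix], grid_t1[ix + 1]), tol = 1e-12)$root
    vol <- evaluate_model(dir_m, mk(root))
    expect_lt(max(vol$values), 1e-9 * 0.8)
  }
})

test_that("generic model specializes to spin echo as TI grows", {
  maps <- random_map_set(c(6, 6, 6), seed = 23)
  se <- evaluate_model(builtin_presets()$SE, maps, scanner_parameters(TR = 8000, TE = 80))
  gen <- evaluate_model(builtin_presets()$GenericIR, maps,
                        scanner_parameters(TR = 8000, TE = 80, TI = 1e9))
  expect_lt(rel_err(gen$values, se$values), 1e-6)
})

test_that("invalid voxels (non-positive or non-finite maps) evaluate to 0", {
  grid <- ms_grid(c(2, 2, 1))
  t1 <- array(c(1000, 0, -5, NaN), c(2, 2, 1))
  pd <- array(0.9, c(2, 2, 1))
  maps <- map_set(quantitative_map("T1", t1, grid),
                  quantitative_map("PD", pd, grid, units = "arbitrary"))
  vol <- evaluate_model(builtin_presets()$GRE, maps)
  expect_gt(vol$values[1, 1, 1], 0)
  expect_identical(vol$values[2, 1, 1], 0)
  expect_identical(vol$values[1, 2, 1], 0)
  expect_identical(vol$values[2, 2, 1], 0)
  expect_true(all(is.finite(vol$values)))
})

test_that("evaluation errors name the missing ingredient", {
  maps <- random_map_set(c(2, 2, 2), seed = 1)
  only_t1 <- map_set(maps$maps$T1)
  expect_error(evaluate_model(builtin_presets()$SE, only_t1), "T2")
  m <- signal_model("x", "T1*Q", parameters = list(Q = 1), maps = "T1")
  m$parameters <- list()   # strip the default to simulate a missing value
  expect_error(evaluate_model(m, maps), "Q")
  g1 <- random_map_set(c(2, 2, 2), seed = 1)
  g2 <- random_map_set(c(2, 2, 2), seed = 1, grid = ms_grid(c(2, 2, 2), spacing = c(2, 2, 2)))
  expect_error(map_set(c(g1$maps["T1"], g2$maps["T2"])), "shared grid")
})
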