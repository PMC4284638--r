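test_that("the shipped network builds with the expected dimensions", {
  m <- full_model_cached()
  v <- validate_network_model(m)
  expect_identical(v$n_states, 32L)
  expect_identical(v$n_params, 105L)
  expect_identical(m$backend, "compiled")
  expect_length(m$links, 15)
})

test_that("validation reports broken inputs by name", {
  def <- yaml::read_yaml(bar_model_file())
  # remove one species: the reactions referencing it dangle
  def_broken <- def
  def_broken$species <- def_broken$species[
    vapply(def_broken$species, function(s) s$name != "PDE3", TRUE)]
  expect_error(build_full_model(def_broken), "PDE3")

  # drop a kinetic constant from the parameter table
  pt <- unlist(def$parameters)
  expect_error(build_full_model(def, param_table = pt[names(pt) != "kbm"]),
               "kbm")

  # duplicate species
  def_dup <- def
  def_dup$species <- c(def_dup$species, def_dup$species[1])
  expect_error(build_full_model(def_dup), "duplicate")

  # severing every route into Bcl2 disconnects the readout
  def_cut <- def
  def_cut$reactions <- Filter(function(r) !r$target %in% c("Bcl2m", "Bcl2"),
                              def_cut$reactions)
  def_cut$species <- Filter(function(s) s$name != "Bcl2m", def_cut$species)
  expect_error(build_full_model(def_cut), "disconnected|Bcl2")

  # count enforcement
  expect_error(build_full_model(def, expect_counts = c(33L, 105L)),
               "expected 33")
})

test_that("a hand-countable toy builds and simulates", {
  m <- toy_chain_model()
  v <- validate_network_model(m)
  expect_identical(v$n_states, 2L)
  expect_identical(v$n_params, 4L)
  tc <- simulate_timecourse(m, dose = 0, t_end = 60,
                            initial = c(X = 0, Y = 0))
  # steady state: X* = k1/d1 = 2, Y* = k2 X*/d2 = 4
  expect_equal(unname(tc$values[nrow(tc$values), ]), c(2, 4),
               tolerance = 1e-5)
})

test_that("one-species linear system matches its closed form", {
  m <- toy_linear_model(k = 1, u = 1)
  tc <- simulate_timecourse(m, dose = 0, t_end = 2, initial = c(x = 0),
                            times = c(0, 0.5, 1, 2))
  expect_equal(unname(tc$values[, "x"]), 1 - exp(-c(0, 0.5, 1, 2)),
               tolerance = 1e-6)
  # and steady_state finds x* = u = 1
  ss <- steady_state(m, dose = 0)
  expect_equal(unname(ss["x"]), 1, tolerance = 1e-8)
})

test_that("adaptive integration matches a fixed-step RK4 oracle on random toys", {
  for (seed in 1:20) {
    n_sp <- sample(3:6, 1)
    m <- random_mass_action_model(n_species = n_sp, seed = seed)
    y0 <- stats::setNames(m$species$init, m$species$name)
    ref <- rk4_integrate(m, y0, t_end = 2, h = 1e-4, n_out = 5)
    got <- simulate_timecourse(m, dose = 0, t_end = 2, initial = y0,
                               times = ref$times)
    expect_lt(max(abs(got$values - ref$values)), 1e-3)
  }
})

test_that("compiled and interpreted right-hand sides agree on the full model", {
  m <- full_model_cached()
  mi <- m; mi$backend <- "interpreted"; mi$cache <- new.env()
  for (dose in c(0, 1e-9, 1e-6)) {
    t1 <- simulate_timecourse(m, dose, 24, initial = rep(0.05, 32),
                              times = c(0, 6, 24))
    t2 <- simulate_timecourse(mi, dose, 24, initial = rep(0.05, 32),
                              times = c(0, 6, 24))
    expect_lt(max(abs(t1$values - t2$values) / (1e-4 + abs(t1$values))),
              1e-3)
  }
})

test_that("dose 0 from the basal state is a fixed point and pools conserve", {
  m <- full_model_cached()
  b <- basal_state(m)
  tc <- simulate_timecourse(m, dose = 0, t_end = 48)
  drift <- abs(sweep(tc$values, 2, tc$values[1, ], "-")) /
    (1e-8 + rep(pmax(tc$values[1, ], 1e-8), each = nrow(tc$values)))
  expect_lt(max(drift), 1e-4)
  expect_true(all(tc$values >= 0))
  # conserved pools: active member never exceeds its total
  tc2 <- simulate_timecourse(m, 1e-6, 48)
  pooled <- !is.na(m$species$pool)
  tot <- m$totals[m$species$pool[pooled]]
  frac <- sweep(tc2$values[, m$species$name[pooled], drop = FALSE], 2, tot, "/")
  expect_lt(max(frac), 1 + 1e-6)
  expect_true(all(frac >= -1e-9))
})

test_that("halving solver tolerances barely changes the Bcl-2 dose response", {
  m <- full_model_cached()
  doses <- 10^seq(-12, -3, by = 1)
  c1 <- dose_response(m, doses)
  c2 <- dose_response(m, doses,
                      solver_opts = list(rtol = 5e-7, atol = 5e-10))
  expect_lt(max(abs(c2$values / c1$values - 1)), 1e-3)
})

test_that("SBML export round-trips to identical simulations", {
  m <- toy_chain_model()
  f <- tempfile(fileext = ".xml")
  export_model(m, f)
  m2 <- import_sbml(f)
  t1 <- simulate_timecourse(m, 0, 10, initial = c(X = 0, Y = 0),
                            times = c(0, 5, 10))
  t2 <- simulate_timecourse(m2, 0, 10, initial = c(X = 0, Y = 0),
                            times = c(0, 5, 10))
  expect_lt(max(abs(t1$values - t2$values)), 1e-9)

  mf <- full_model_cached()
  ff <- tempfile(fileext = ".xml")
  export_model(mf, ff)
  doc <- xml2::read_xml(ff)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  expect_length(xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), 32)
  m3 <- import_sbml(ff)
  expect_identical(nrow(m3$species), 32L)
  expect_identical(length(m3$params), 105L)
  expect_error(suppressWarnings(
    export_model(mf, file.path(tempdir(), "no", "such", "dir", "x.xml"))))
})
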