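doses_coarse <- 10^seq(-12, -3, by = 0.5)

test_that("null perturbations reproduce the control bit for bit", {
  m <- full_model_cached()
  ctrl <- dose_response(m, doses_coarse)
  b0 <- dose_response(apply_antagonist(m, antagonist("b1", 0)), doses_coarse)
  expect_identical(ctrl$values, b0$values)
  s1 <- dose_response(scale_link(m, "ICER-|Bcl2", 1), doses_coarse)
  expect_identical(ctrl$values, s1$values)
  # scaling to zero reproduces the knockout exactly
  a <- scale_link(m, "ERK->Bcl2", 0)
  b <- knockout_links(m, "ERK->Bcl2")
  expect_identical(a$params, b$params)
  expect_error(scale_link(m, "nope", 0.5), "unknown link")
  expect_error(apply_antagonist(m, list(target = "b3")), "antagonist")
})

test_that("competitive antagonism shifts the binding EC50 by the Schild factor", {
  m <- full_model_cached()
  # isolated binding readout: occupied beta1 receptor at equilibrium
  ec50 <- function(mm) {
    g <- 10^seq(-10, -3, by = 0.02)
    crv <- dose_response(mm, g, readout = "LRb1", observation_time = 12)
    half <- max(crv$values) / 2
    g[which.min(abs(crv$values - half))]
  }
  e0 <- ec50(m)
  KI <- 1e-7; conc <- 3e-7
  e1 <- ec50(apply_antagonist(m, antagonist("b1", conc, KI)))
  expect_equal(e1 / e0, 1 + conc / KI, tolerance = 0.05)
})

test_that("the beta1-blocker widens and the beta2-blocker narrows the survival range", {
  m <- full_model_cached()
  w <- function(r) if (all(is.finite(r))) log10(r[2] / r[1]) else 0
  ctrl <- dose_response(m, doses_coarse)
  w0 <- w(survival_range(ctrl))
  widths_b1 <- vapply(c(1e-7, 1e-6, 1e-5), function(cc)
    w(survival_range(dose_response(
      apply_antagonist(m, antagonist("b1", cc)), doses_coarse))), 0)
  expect_true(all(diff(c(w0, widths_b1)) > -1e-9))  # never shrinks
  expect_gt(widths_b1[3], w0 + 1)                   # and clearly widens
  # upper edge moves to higher ISO with blocker dose
  uppers <- vapply(c(0, 1e-7, 1e-6, 1e-5), function(cc)
    survival_range(dose_response(
      apply_antagonist(m, antagonist("b1", cc)), doses_coarse))[2], 0)
  expect_true(all(diff(uppers) > 0))

  w2 <- w(survival_range(dose_response(
    apply_antagonist(m, antagonist("b2", 5e-7)), doses_coarse)))
  expect_lt(w2, w0)                                 # narrows
})

test_that("blocker heat maps carry the control row and ordered survival edges", {
  m <- full_model_cached()
  iso <- 10^seq(-12, -3, by = 1)
  hb1 <- blocker_heatmap(m, iso, blocker_grid = c(0, 1e-6, 1e-5),
                         subtype = "b1")
  ctrl <- dose_response(m, iso)
  expect_equal(unname(hb1$values[1, ]), unname(ctrl$values), tolerance = 1e-9)
  ok <- is.finite(hb1$survival[, 2])
  expect_true(all(diff(hb1$survival[ok, 2]) > 0))   # upper edge non-decreasing
  hb2 <- blocker_heatmap(m, iso, blocker_grid = c(0, 5e-7), subtype = "b2")
  wdt <- log10(hb2$survival[, 2] / hb2$survival[, 1])
  expect_lt(wdt[2], wdt[1])                         # range narrows
  df <- as.data.frame(hb1)
  expect_identical(nrow(df), length(iso) * 3L)
})

test_that("graded feed-forward-arm inhibition acts dose-range specifically", {
  m <- full_model_cached()
  d12 <- dose_response(m, doses_coarse, observation_time = 12)
  # ICER arm relief: micromolar-specific increase
  si <- dose_response(scale_link(m, "ICER-|Bcl2", 0.3), doses_coarse,
                      observation_time = 12)
  nM <- which(doses_coarse >= 1e-9 & doses_coarse <= 1e-8)
  uM <- which(doses_coarse >= 1e-6)
  expect_lt(max(abs(si$values[nM] / d12$values[nM] - 1)), 0.05)
  expect_gt(min(si$values[uM] / d12$values[uM] - 1), 0.3)
  # ERK arm inhibition: reduction over 1e-10..1e-7 M
  se <- dose_response(scale_link(m, "ERK->Bcl2", 0.3), doses_coarse,
                      observation_time = 12)
  lo <- which(doses_coarse >= 1e-10 & doses_coarse <= 1e-7)
  expect_true(all(se$values[lo] < d12$values[lo]))
})

test_that("PKA inhibition scans trace a switching-like flux profile", {
  m <- full_model_cached()
  inh <- c(0, 10^seq(-7, -2, by = 1))
  scan <- pka_inhibitor_scan(m, inh)
  expect_equal(scan$values[1],
               {tc <- simulate_timecourse(m, 1e-6, 12, times = c(0, 6, 12))
                unname(tc$values[3, "Bcl2"])}, tolerance = 1e-9)
  # read along decreasing inhibition (increasing PKA flux):
  flux_order <- rev(seq_along(inh))
  prof <- scan$values[flux_order] / scan$basal
  ip <- which.max(prof)
  expect_gt(ip, 1); expect_lt(ip, length(prof))     # interior peak
  expect_gt(prof[ip], prof[1] + 0.3)                # clear rise
  expect_gt(prof[ip], prof[length(prof)] + 0.3)     # and fall
  # under saturating inhibition the switching dose response disappears
  sat <- set_model_params(m, c(kpka = unname(m$params["kpka"]) / 1001))
  sw <- classify_switching(dose_response(sat, doses_coarse))
  expect_false(sw$is_switching)
})

test_that("cAMP clamping yields an early rise and a late fall of Bcl-2", {
  m <- full_model_cached()
  b <- basal_state(m)
  cl <- camp_clamp(m, level = 1.0, duration = 48)
  v6 <- cl$values[which.min(abs(cl$times - 6)), "Bcl2"]
  v24 <- cl$values[which.min(abs(cl$times - 24)), "Bcl2"]
  expect_gt(v6, b[["Bcl2"]] * 1.1)
  expect_lt(v24, v6)
  expect_lt(v24, b[["Bcl2"]])
  # clamping at the basal cAMP level leaves the trajectory flat
  cl0 <- camp_clamp(m, level = b[["cAMP"]], duration = 24)
  dev <- sweep(abs(sweep(cl0$values, 2, cl0$values[1, ], "-")), 2,
               pmax(cl0$values[1, ], 1e-6), "/")
  expect_lt(max(dev), 1e-3)
  # no analogue at all: the control stays at basal
  ctl <- camp_clamp(m, level = 0, duration = 24)
  expect_lt(max(abs(ctl$values[, "Bcl2"] - b[["Bcl2"]])) / b[["Bcl2"]], 1e-4)
})
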