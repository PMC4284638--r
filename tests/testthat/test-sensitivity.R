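test_that("the Bcl-2 integral matches closed forms and converges", {
  # constant Bcl2 = c over [24, 48]: integral = 24 c
  tt <- seq(0, 48, by = 0.5)
  mk <- function(y) {
    v <- matrix(y, length(tt), 1, dimnames = list(NULL, "Bcl2"))
    structure(list(times = tt, values = v), class = "bar_timecourse")
  }
  expect_equal(bcl2_metric(mk(rep(0.7, length(tt)))), 24 * 0.7)
  # linear ramp a -> b across the window: integral = 12 (a + b)
  ramp <- 0.2 + (tt - 24) / 24 * 0.6
  expect_equal(bcl2_metric(mk(ramp)), 12 * (0.2 + 0.8), tolerance = 1e-12)
  # quadrature converges: halving the grid changes the result < 0.1%
  m <- full_model_cached()
  t1 <- simulate_timecourse(m, 1e-6, 48, times = seq(0, 48, length.out = 97))
  t2 <- simulate_timecourse(m, 1e-6, 48, times = seq(0, 48, length.out = 49))
  expect_lt(abs(bcl2_metric(t1) / bcl2_metric(t2) - 1), 1e-3)
  expect_error(bcl2_metric(mk(ramp)[c("times", "values")] |>
                             (\(x) structure(list(times = x$times[1:10],
                                                  values = x$values[1:10, , drop = FALSE]),
                                             class = "bar_timecourse"))()),
               "span")
})

test_that("local elasticities recover power-law exponents", {
  m <- full_model_cached()
  # synthetic metric M = c * kbm^1.7 * kerkd^-0.5
  metric <- function(model, params) {
    3 * params[["kbm"]]^1.7 * params[["kerkd"]]^-0.5
  }
  s <- lsa(m, c("kbm", "kerkd", "kckd"), delta = 0.01, metric = metric)
  expect_equal(unname(s["kbm"]), 1.7, tolerance = 0.02)
  expect_equal(unname(s["kerkd"]), -0.5, tolerance = 0.02)
  expect_equal(unname(s["kckd"]), 0)       # parameter absent from the metric
  sc <- lsa(m, c("kbm"), delta = 0.01, central = TRUE, metric = metric)
  expect_equal(unname(sc["kbm"]), 1.7, tolerance = 0.005)
  expect_error(lsa(m, "kbm", metric = function(model, params) 0), "undefined")
})

test_that("Sobol points stay in bounds and beat iid uniform discrepancy", {
  nom <- c(a = 0.5, b = 20, c = 1e-3)
  S <- sobol_sample(nom, fold = 10, N = 256)
  expect_true(all(sweep(S, 2, nom / 10, ">=") & sweep(S, 2, nom * 10, "<=")))
  # fold = 1 collapses every point onto the nominal vector
  S1 <- sobol_sample(nom, fold = 1, N = 16)
  expect_true(all(abs(sweep(S1, 2, nom, "/") - 1) < 1e-12))
  # log-marginals are uniform
  ks <- stats::ks.test(log(S[, "b"]), "punif", log(2), log(200))
  expect_gt(ks$p.value, 0.01)
  # star-discrepancy proxy (max deviation of empirical box counts) lower
  # than an iid uniform sample of the same size, averaged over axes
  u <- sobol_sequence(256, 3)
  set.seed(1); v <- matrix(stats::runif(256 * 3), 256, 3)
  disc <- function(x) {
    g <- seq(0.05, 0.95, by = 0.05)
    max(vapply(g, function(t) max(abs(colMeans(x <= t) - t)), 0))
  }
  expect_lt(disc(u), disc(v))
  expect_error(sobol_sample(c(a = -1), N = 16), "positive")
  expect_error(sobol_sample(nom, N = 4), "at least 8")
})

test_that("PRCC matches an independent precision-matrix oracle", {
  set.seed(10)
  for (rep in 1:5) {
    N <- 150; P <- 5
    X <- matrix(stats::rnorm(N * P), N, P,
                dimnames = list(NULL, paste0("p", 1:P)))
    beta <- stats::rnorm(P)
    y <- X %*% beta + stats::rnorm(N, 0, 0.5)
    expect_lt(max(abs(prcc(X, y) - prcc_oracle(X, y))), 1e-10)
  }
})

test_that("PRCC resolves monotone dependence and the null", {
  set.seed(11)
  N <- 400
  X <- matrix(stats::runif(N * 4), N, 4,
              dimnames = list(NULL, paste0("p", 1:4)))
  y <- rank(X[, 1])                       # output is a rank of parameter 1
  pr <- prcc(X, y)
  expect_gt(pr["p1"], 0.99)
  expect_lt(max(abs(pr[2:4])), 3 / sqrt(N))
  y0 <- stats::runif(N)                   # output independent of all inputs
  expect_lt(max(abs(prcc(X, y0))), 3 / sqrt(N))
  Xd <- X; Xd[, 2] <- 1                   # degenerate column
  expect_error(prcc(Xd, y), "p2")
  expect_error(prcc(X[1:6, ], y[1:6]), "N > P")
})

test_that("the combined report ranks a dominant parameter first", {
  m <- full_model_cached()
  # constructed ground truth: metric dominated by kbm
  metric <- function(model, params)
    params[["kbm"]]^2 * (1 + 0.02 * log(params[["kckd"]]))
  l <- lsa(m, c("kbm", "kckd"), metric = metric)
  expect_gt(abs(l["kbm"]), abs(l["kckd"]))
  S <- sobol_sample(m$params[c("kbm", "kckd")], fold = 10, N = 128)
  M <- apply(S, 1, function(r) metric(m, as.list(r)))
  pr <- prcc(S, M)
  expect_gt(abs(pr["kbm"]), abs(pr["kckd"]))
})

test_that("the full-model report is deterministic and flags tiny samples", {
  m <- full_model_cached()
  targets <- c("kac", "kpde", "kicm", "kbm")
  r1 <- gsa_report(m, targets, N = 16, fold = 3)
  r2 <- gsa_report(m, targets, N = 16, fold = 3)
  expect_identical(r1$prcc, r2$prcc)
  expect_false(attr(r1, "wide_uncertainty"))
  r3 <- gsa_report(m, targets, N = 8, fold = 3)
  expect_true(attr(r3, "wide_uncertainty"))
  expect_true(all(abs(r1$prcc) <= 1))
})
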