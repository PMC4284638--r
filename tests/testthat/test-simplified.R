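test_that("compiled screen engine matches the lsoda reference path", {
  set.seed(3)
  ps <- sample_parameters(6, seed = 3)
  masks <- enumerate_masks(8)[sample(1:256, 6), , drop = FALSE]
  Sg <- c(0.01, 0.3, 10)
  vals <- .Call(barswitch:::C_simplified_screen, masks, ps,
                as.numeric(Sg), 0.1, 1e-6)
  for (im in seq_len(nrow(masks))) for (is in seq_len(nrow(ps))) {
    sm <- build_simplified(masks[im, ], param_row_to_list(ps[is, ]))
    ref <- c(simulate_simplified(sm, 0)[["Bcl2"]],
             vapply(Sg, function(s) simulate_simplified(sm, s)[["Bcl2"]], 0))
    got <- vals[(im - 1) * nrow(ps) + is, ]
    expect_lt(max(abs(got - ref) / (1 + abs(ref))), 1e-4)
  }
})

test_that("simplified steady states obey closed forms", {
  # node with a single activator, n = 1, S >> K: x* ~ beta + b0
  p <- mid_parameters()
  p$n <- rep(1, 8); p$K <- rep(0.01, 8)
  sm <- build_simplified(c(0, 1, 0, 0, 0, 0, 0, 0), p)   # only S->ERK on
  st <- simulate_simplified(sm, S = 100)
  expect_equal(st[["ERK"]], 1 * (100 / 100.01) + 0.1, tolerance = 1e-3)
  # all-off: activated nodes settle at basal production b0; PDE, which is
  # produced constitutively (it has no activating link), settles at beta + b0
  sm0 <- build_simplified(rep(0, 8), mid_parameters())
  st0 <- simulate_simplified(sm0, S = 5)
  expect_equal(unname(st0), c(0.1, 1.1, 0.1, 0.1, 0.1), tolerance = 1e-4)
  # all-on with mid-range parameters: bounded non-negative steady state
  sm1 <- build_simplified(rep(1, 8), mid_parameters())
  st1 <- simulate_simplified(sm1, S = 1)
  expect_true(all(st1 >= 0 & st1 <= 1.2))
})

test_that("parameter sampling respects its log-uniform ranges", {
  ps <- sample_parameters(5000, seed = 4)
  expect_true(all(ps[, 1:5] >= 10 & ps[, 1:5] <= 1000))
  expect_true(all(ps[, 6:10] >= 0.1 & ps[, 6:10] <= 10))
  expect_true(all(ps[, 11:18] >= 0.01 & ps[, 11:18] <= 1))
  expect_true(all(ps[, 19:26] >= 1 & ps[, 19:26] <= 10))
  # log10(tau) uniform on [1, 3]
  ks <- stats::ks.test(log10(ps[, 1]), "punif", 1, 3)
  expect_gt(ks$p.value, 0.01)
  # reproducible; empty draw allowed; bad ranges rejected
  expect_identical(ps, sample_parameters(5000, seed = 4))
  expect_identical(nrow(sample_parameters(0)), 0L)
  expect_error(sample_parameters(10, ranges = list(tau = c(5, 2), n = c(1, 10),
                                                   K = c(0.01, 1),
                                                   beta = c(0.1, 10))),
               "invalid")
})

test_that("robustness counts match per-cell manual classification on a toy subset", {
  masks <- enumerate_masks(8)[c(104, 112, 256, 1), , drop = FALSE]
  ps <- sample_parameters(200, seed = 9)
  rt <- robustness_screen(masks, ps, theta_up = 1.2, theta_down = 0.8)
  Sg <- 10^seq(-3, 1, by = 0.5)
  for (im in 1:2) {  # re-check the two interesting structures by hand
    manual <- 0
    for (is in seq_len(50)) {
      sm <- build_simplified(masks[im, ], param_row_to_list(ps[is, ]))
      crv <- simplified_dose_response(sm, Sg)
      manual <- manual + isTRUE(classify_switching(crv)$is_switching)
    }
    rt_sub <- robustness_screen(masks[im, , drop = FALSE],
                                ps[1:50, , drop = FALSE])
    expect_identical(rt_sub$count, as.integer(manual))
  }
  # a mask with no path into Bcl2 scores zero
  no_path <- matrix(c(1, 1, 1, 1, 1, 1, 0, 0), 1)  # ERK->Bcl2, PKA->Bcl2 off
  expect_identical(robustness_screen(no_path, ps)$count, 0L)
})

test_that("counts grow monotonically as classifier thresholds relax", {
  masks <- enumerate_masks(8)[c(104, 112, 128, 232), , drop = FALSE]
  ps <- sample_parameters(300, seed = 5)
  strict <- robustness_screen(masks, ps, theta_up = 1.3, theta_down = 0.7)
  loose <- robustness_screen(masks, ps, theta_up = 1.15, theta_down = 0.85)
  expect_true(all(loose$count >= strict$count))
})

test_that("screens are deterministic and rankings break ties by index", {
  masks <- enumerate_masks(8)[c(104, 112), , drop = FALSE]
  ps <- sample_parameters(100, seed = 2)
  a <- robustness_screen(masks, ps)
  b <- robustness_screen(masks, ps)
  expect_identical(a, b)
  tab <- data.frame(index = c(5L, 2L, 9L), count = c(4L, 7L, 4L))
  top <- rank_circuits(tab, 3)
  expect_identical(top$index, c(2L, 5L, 9L))
  expect_warning(rank_circuits(tab, 5), "clipped")
})
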