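test_that("mask enumeration is a bijection", {
  for (L in c(0, 1, 4, 8, 15)) {
    mm <- enumerate_masks(L)
    expect_identical(nrow(mm), as.integer(2^L))
    expect_identical(ncol(mm), as.integer(L))
    if (L > 0) {
      idx <- as.integer(mm %*% 2^(0:(L - 1)))
      expect_identical(sort(idx), 0:(2^L - 1))  # each index exactly once
    }
  }
  expect_error(enumerate_masks(21), "range")
})

test_that("coarse-graining the full model yields 6 units and 15 links", {
  m <- full_model_cached()
  cg <- coarse_grain(m)
  expect_length(cg$units, 6)
  expect_identical(nrow(cg$links), 15L)
  expect_setequal(cg$links$name, vapply(m$links, `[[`, "", "name"))
  expect_true(all(lengths(cg$links$gates) >= 1))
  # incomplete mapping is rejected
  bad <- m$units; bad$Ca <- setdiff(bad$Ca, "Cai")
  expect_error(coarse_grain(m, bad), "Cai")
})

test_that("identity mapping recovers raw inter-species couplings", {
  m <- toy_chain_model()
  idmap <- stats::setNames(as.list(m$species$name), m$species$name)
  cg <- coarse_grain(m, idmap)
  # only X -> Y remains (self-regulation is internal)
  expect_identical(nrow(cg$links), 1L)
  expect_identical(cg$links$from, "X")
  expect_identical(cg$links$to, "Y")
  expect_identical(cg$links$sign, 1)
})

test_that("a 3-species chain with a 2-unit mapping gives one inter-unit link", {
  m <- random_mass_action_model(3, seed = 99)
  cg <- coarse_grain(m, list(A = c("S1", "S2"), B = "S3"))
  cross <- cg$links[cg$links$from != cg$links$to, , drop = FALSE]
  expect_gte(nrow(cross), 1L)
})

test_that("knockouts zero the gated parameters and compose", {
  m <- full_model_cached()
  ln <- vapply(m$links, `[[`, "", "name")
  m1 <- knockout_links(m, "PKA->ERK")
  expect_identical(unname(m1$params["ksh"]), 0)
  expect_identical(unname(m$params["ksh"]) > 0, TRUE)  # input untouched
  # idempotent
  m2 <- knockout_links(m1, "PKA->ERK")
  expect_identical(m1$params, m2$params)
  # commutes across disjoint links
  a <- knockout_links(knockout_links(m, "PKA->ERK"), "Ca->Bcl2")
  b <- knockout_links(knockout_links(m, "Ca->Bcl2"), "PKA->ERK")
  expect_identical(a$params, b$params)
  # all-on mask is the identity
  m3 <- knockout_links(m, rep(1L, length(ln)))
  expect_identical(m3$params, m$params)
  expect_error(knockout_links(m, rep(1L, 7)), "mask length")
  expect_error(knockout_links(m, "no-such-link"), "unknown")
})

test_that("knocking out every link flattens the Bcl-2 response", {
  m <- full_model_cached()
  m0 <- knockout_links(m, rep(0L, 15))
  crv <- dose_response(m0, 10^seq(-12, -3, by = 1.5))
  expect_lt(max(abs(crv$values / crv$basal - 1)), 0.05)
  expect_false(classify_switching(crv)$is_switching)
})

test_that("an exhaustive screen of a 3-link subset matches one-by-one runs", {
  m <- full_model_cached()
  links <- c("ICER-|Bcl2", "ERK->Bcl2", "Ca->Bcl2")
  doses <- 10^seq(-12, -3, by = 1.5)
  scr <- screen_full(m, links = links, doses = doses)
  expect_identical(nrow(scr), 8L)
  ln <- vapply(m$links, `[[`, "", "name")
  for (i in c(1, 4, 8)) {  # spot-check masks manually
    bits <- as.integer(enumerate_masks(3)[i, ])
    full_mask <- rep(1L, 15)
    full_mask[match(links, ln)] <- bits
    sw <- classify_switching(dose_response(knockout_links(m, full_mask), doses))
    expect_identical(scr$is_switching[i], sw$is_switching)
  }
})

test_that("necessity extraction agrees with brute-force set intersection", {
  set.seed(21)
  for (rep in 1:25) {
    L <- 4
    masks <- enumerate_masks(L)
    phen <- stats::runif(2^L) < 0.3
    phen[sample(2^L, 1)] <- TRUE  # at least one switching mask
    scr <- data.frame(index = 0:(2^L - 1),
                      bits = apply(masks, 1, paste, collapse = ""),
                      is_switching = phen, failed = FALSE)
    attr(scr, "links") <- paste0("L", 1:L)
    got <- essential_links(scr)
    idx <- which(colSums(masks[phen, , drop = FALSE]) == sum(phen))
    want <- paste0("L", idx, recycle0 = TRUE)
    expect_setequal(as.character(got), want)
  }
  # degenerate screen: only the all-on mask switches -> all links essential
  masks <- enumerate_masks(3)
  scr <- data.frame(index = 0:7, bits = apply(masks, 1, paste, collapse = ""),
                    is_switching = c(rep(FALSE, 7), TRUE), failed = FALSE)
  attr(scr, "links") <- c("a", "b", "c")
  expect_setequal(as.character(essential_links(scr)), c("a", "b", "c"))
  # no switching masks at all -> error
  scr$is_switching <- FALSE
  expect_error(essential_links(scr), "no switching")
})

test_that("minimal-sufficient extraction finds a minimal switching mask", {
  masks <- enumerate_masks(3)
  # switching iff links 1 and 2 are both on (link 3 irrelevant)
  phen <- masks[, 1] == 1 & masks[, 2] == 1
  scr <- data.frame(index = 0:7, bits = apply(masks, 1, paste, collapse = ""),
                    is_switching = phen, failed = FALSE)
  attr(scr, "links") <- c("a", "b", "c")
  got <- essential_links(scr, criterion = "minimal-sufficient")
  expect_setequal(as.character(got), c("a", "b"))
})
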