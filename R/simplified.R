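# The simplified five-node circuit model (PKA, PDE, ERK, ICER, Bcl-2 with
# the eight essential regulatory links), random parameter sampling, and the
# structure-by-parameter robustness screen.

#' Names of the eight essential links of the simplified model
#'
#' Order defines the mask bit order used throughout the screen.
#' @return Character vector of length 8.
#' @export
simplified_links <- function() {
  c("S->PKA", "S->ERK", "PKA->ICER", "ICER-|PDE",
    "PDE-|PKA", "ICER-|Bcl2", "ERK->Bcl2", "PKA->Bcl2")
}

#' Build a simplified five-node circuit model
#'
#' Non-dimensional Michaelis-Menten/Hill model over nodes PKA, PDE, ERK,
#' ICER and Bcl-2. Each node obeys
#' `tau_x dx/dt = beta_x * prod(activations) * prod(inhibitions) + b0_x - x`
#' with Hill activation `u^n/(K^n+u^n)` per active incoming activation link
#' and Hill inhibition `Ki^n/(Ki^n+y^n)` per active repression (multiplied,
#' i.e. AND gating). Links removed by the mask drop their factor; a node
#' whose activators are all removed keeps only its basal production
#' `b0 = b0_frac * beta`. All simulations start from zero initial
#' conditions.
#'
#' @param mask 0/1 vector of length 8 over [simplified_links()].
#' @param params Named list/vector with `tau` (5), `beta` (5), `K` (8) and
#'   `n` (8) in link order; see [sample_parameters()].
#' @param b0_frac Basal production as a fraction of `beta` (default 0.1).
#' @return A `bar_simplified` object.
#' @export
build_simplified <- function(mask = rep(1L, 8), params = mid_parameters(),
                             b0_frac = 0.1) {
  stopifnot(length(mask) == 8)
  p <- as.list(params)
  stopifnot(length(p$tau) == 5, length(p$beta) == 5,
            length(p$K) == 8, length(p$n) == 8)
  structure(list(mask = as.integer(mask), tau = as.numeric(p$tau),
                 beta = as.numeric(p$beta), K = as.numeric(p$K),
                 n = as.numeric(p$n), b0 = b0_frac * as.numeric(p$beta),
                 nodes = c("PKA", "PDE", "ERK", "ICER", "Bcl2")),
            class = "bar_simplified")
}

#' Geometric mid-points of the documented sampling ranges
#'
#' @return Parameter list accepted by [build_simplified()].
#' @export
mid_parameters <- function() {
  list(tau = rep(100, 5), beta = rep(1, 5), K = rep(0.1, 8), n = rep(3, 8))
}

# production term beta*act*inh + b0 (reference implementation mirroring the
# compiled screen engine)
simplified_production <- function(sm, x, S) {
  on <- sm$mask == 1
  act <- function(u, j) u^sm$n[j] / (sm$K[j]^sm$n[j] + u^sm$n[j])
  inh <- function(y, j) sm$K[j]^sm$n[j] / (sm$K[j]^sm$n[j] + y^sm$n[j])
  x <- pmax(x, 0)
  prod <- numeric(5)
  prod[1] <- if (on[1])
    sm$beta[1] * act(S, 1) * (if (on[5]) inh(x[2], 5) else 1) + sm$b0[1]
  else sm$b0[1]
  prod[2] <- sm$beta[2] * (if (on[4]) inh(x[4], 4) else 1) + sm$b0[2]
  prod[3] <- if (on[2]) sm$beta[3] * act(S, 2) + sm$b0[3] else sm$b0[3]
  prod[4] <- if (on[3]) sm$beta[4] * act(x[1], 3) + sm$b0[4] else sm$b0[4]
  if (on[7] || on[8]) {
    a <- 1
    if (on[7]) a <- a * act(x[3], 7)
    if (on[8]) a <- a * act(x[1], 8)
    prod[5] <- sm$beta[5] * a * (if (on[6]) inh(x[4], 6) else 1) + sm$b0[5]
  } else prod[5] <- sm$b0[5]
  prod
}

#' Simulate the simplified model to steady state (reference path)
#'
#' Integrates with `deSolve::lsoda` from zero initial conditions until
#' every node balances its production or `t = 10 * max(tau)`. The compiled
#' screening engine implements the same dynamics; this R path is the
#' readable reference used to cross-check it.
#'
#' @param sm A `bar_simplified`.
#' @param S Dimensionless stimulus level.
#' @param tol Convergence tolerance on |production - x|/(1 + |x|).
#' @return Named steady-state vector over the five nodes.
#' @export
simulate_simplified <- function(sm, S, tol = 1e-6) {
  rhs <- function(t, x, parms)
    list((simplified_production(sm, x, S) - x) / sm$tau)
  x <- rep(0, 5)
  tmax <- 10 * max(sm$tau)
  for (chunk in 1:10) {
    out <- deSolve::ode(x, c(0, tmax / 10), rhs, NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-10)
    x <- pmax(out[nrow(out), -1], 0)
    if (all(abs(simplified_production(sm, x, S) - x) <= tol * (1 + abs(x))))
      break
  }
  stats::setNames(x, sm$nodes)
}

#' Dose response of the simplified model's Bcl-2 node
#'
#' @param sm A `bar_simplified`.
#' @param S_grid Stimulus grid (dimensionless), default 2 points/decade over
#'   1e-3 to 1e1.
#' @return A `bar_curve` with basal = steady state at S = 0.
#' @export
simplified_dose_response <- function(sm, S_grid = 10^seq(-3, 1, by = 0.5)) {
  basal <- simulate_simplified(sm, 0)[["Bcl2"]]
  vals <- vapply(S_grid, function(s) simulate_simplified(sm, s)[["Bcl2"]], 0)
  structure(list(doses = S_grid, values = vals, readout = "Bcl2",
                 observation_time = Inf, basal = basal),
            class = "bar_curve")
}

#' Sample random parameter sets for the simplified model
#'
#' Each parameter is drawn independently log-uniformly within its range:
#' `tau` in \[10, 1000\], `n` in \[1, 10\], `K` and `Ki` in \[0.01, 1\], and
#' `beta` in \[0.1, 10\].
#'
#' @param N Number of parameter sets (>= 0).
#' @param ranges Named list of length-2 ranges overriding the defaults.
#' @param seed RNG seed.
#' @return Numeric matrix `N x 26` (columns `tau1..tau5, beta1..beta5,
#'   K1..K8, n1..n8`).
#' @export
sample_parameters <- function(N = 10000,
                              ranges = list(tau = c(10, 1000),
                                            n = c(1, 10),
                                            K = c(0.01, 1),
                                            beta = c(0.1, 10)),
                              seed = 1) {
  stopifnot(N >= 0)
  for (r in ranges)
    if (r[1] <= 0 || r[1] >= r[2])
      stop("invalid sampling range [", r[1], ", ", r[2], "]")
  loguni <- function(n, r) exp(stats::runif(n, log(r[1]), log(r[2])))
  set.seed(seed)
  out <- matrix(NA_real_, N, 26)
  colnames(out) <- c(paste0("tau", 1:5), paste0("beta", 1:5),
                     paste0("K", 1:8), paste0("n", 1:8))
  if (N == 0) return(out)
  for (j in 1:5)  out[, j] <- loguni(N, ranges$tau)
  for (j in 6:10) out[, j] <- loguni(N, ranges$beta)
  for (j in 11:18) out[, j] <- loguni(N, ranges$K)
  for (j in 19:26) out[, j] <- loguni(N, ranges$n)
  out
}

#' Split a sampled parameter row into the build_simplified() layout
#'
#' @param row One row of the matrix returned by [sample_parameters()].
#' @return List with `tau`, `beta`, `K`, `n`.
#' @export
param_row_to_list <- function(row) {
  list(tau = row[1:5], beta = row[6:10], K = row[11:18], n = row[19:26])
}

#' Robustness screen of rewired simplified circuits
#'
#' For every circuit mask and every random parameter set, integrates the
#' simplified model to steady state from zero initial conditions over the
#' stimulus grid (compiled engine), classifies the Bcl-2 dose response as
#' switching, and tabulates per-mask counts. A structure is called robust
#' when its count reaches `threshold` (a fraction of `N`).
#'
#' @param masks Integer matrix of masks (rows), default all 2^8.
#' @param paramsets Matrix from [sample_parameters()].
#' @param S_grid Stimulus grid spanning at least 4 decades.
#' @param theta_up,theta_down Classifier thresholds.
#' @param threshold Robustness cutoff as a fraction of the parameter sets
#'   (default 0.01).
#' @param b0_frac Basal production fraction.
#' @return A `bar_robustness` data frame: `index`, `bits`, `count`, `n`,
#'   `robust`, `rank` (dense rank by descending count, ties by mask index)
#'   and `has_iffl` (mask contains S->PKA, S->ERK, PKA->ICER, ICER-|Bcl2
#'   and ERK->Bcl2: the ERK/ICER incoherent feed-forward pair).
#' @export
robustness_screen <- function(masks = enumerate_masks(8),
                              paramsets = sample_parameters(300),
                              S_grid = 10^seq(-3, 1, by = 0.5),
                              theta_up = 1.2, theta_down = 0.8,
                              threshold = 0.01, b0_frac = 0.1) {
  if (log10(max(S_grid) / min(S_grid)) < 4 - 1e-9)
    stop("stimulus grid must span at least 4 decades")
  storage.mode(masks) <- "integer"
  vals <- .Call(C_simplified_screen, masks, paramsets, as.numeric(S_grid),
                as.numeric(b0_frac), 1e-6)
  n_masks <- nrow(masks); n_sets <- nrow(paramsets)
  basal <- vals[, 1]
  fold <- vals[, -1, drop = FALSE] / basal
  # vectorised switching classification over all (mask, set) cells
  peak_i <- max.col(fold, ties.method = "first")
  peak_f <- fold[cbind(seq_len(nrow(fold)), peak_i)]
  term_f <- fold[, ncol(fold)]
  interior <- peak_i > 1 & peak_i < ncol(fold)
  sw <- interior & peak_f >= theta_up & term_f <= theta_down &
    is.finite(peak_f) & is.finite(term_f)
  counts <- as.integer(rowsum(as.integer(sw),
                              rep(seq_len(n_masks), each = n_sets)))
  bits <- apply(masks, 1, paste, collapse = "")
  iffl_bits <- match(c("S->PKA", "S->ERK", "PKA->ICER", "ICER-|Bcl2",
                       "ERK->Bcl2"), simplified_links())
  has_iffl <- apply(masks[, iffl_bits, drop = FALSE] == 1, 1, all)
  out <- data.frame(index = seq_len(n_masks) - 1L, bits = bits,
                    count = counts, n = n_sets,
                    robust = counts >= threshold * n_sets,
                    has_iffl = has_iffl, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$index), ]
  out$rank <- seq_len(nrow(out))
  out <- out[order(out$index), ]
  rownames(out) <- NULL
  class(out) <- c("bar_robustness", "data.frame")
  out
}

#' Rank circuits by robustness
#'
#' @param table A `bar_robustness` table.
#' @param k Number of top structures to return (clipped with a warning when
#'   larger than the table).
#' @return The top-`k` rows ordered by descending count (ties broken by
#'   ascending mask index).
#' @export
rank_circuits <- function(table, k = 4) {
  if (k > nrow(table)) {
    warning("k clipped from ", k, " to ", nrow(table))
    k <- nrow(table)
  }
  ord <- order(-table$count, table$index)
  out <- table[ord[seq_len(k)], ]
  rownames(out) <- NULL
  out
}
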