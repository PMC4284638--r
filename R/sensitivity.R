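# Sensitivity analysis of the time-integrated Bcl-2 response: local
# elasticities (LSA), Sobol low-discrepancy sampling over a fold-range
# around nominal values, and partial rank correlation coefficients (PRCC).

#' Time-integrated Bcl-2 metric
#'
#' Trapezoidal integral of the Bcl-2 concentration between `t0` and `t1`
#' hours (defaults 24-48 h, the observation window used with 1 uM ISO).
#'
#' @param timecourse A `bar_timecourse` covering `[t0, t1]`.
#' @param t0,t1 Integration window (h).
#' @return Scalar integral (uM h).
#' @export
bcl2_metric <- function(timecourse, t0 = 24, t1 = 48) {
  tt <- timecourse$times
  if (min(tt) > t0 + 1e-9 || max(tt) < t1 - 1e-9)
    stop("time course does not span [", t0, ", ", t1, "] h")
  keep <- tt >= t0 - 1e-12 & tt <= t1 + 1e-12
  x <- tt[keep]; y <- timecourse$values[keep, "Bcl2"]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# metric evaluated on the full model under a given parameter vector
metric_under_params <- function(model, params, iso = 1e-6, t0 = 24, t1 = 48) {
  m <- set_model_params(model, params)
  tc <- simulate_timecourse(m, iso, t_end = t1,
                            times = seq(0, t1, length.out = 97))
  bcl2_metric(tc, t0, t1)
}

#' Local sensitivity (elasticity) of the Bcl-2 metric
#'
#' For each parameter, the percent change of the metric caused by a 1%
#' parameter increase: `[(M(p * (1 + delta)) - M(p)) / M(p)] / delta`
#' (forward difference; `central = TRUE` uses both directions).
#'
#' @param model A `bar_model`.
#' @param parameters Character vector of parameter names (default: all).
#' @param delta Relative perturbation (default 0.01).
#' @param central Use central differences.
#' @param metric Function `(model, params) -> scalar`; defaults to the
#'   24-48 h Bcl-2 integral under 1 uM ISO.
#' @return Named numeric vector of elasticities (sign preserved).
#' @export
lsa <- function(model, parameters = names(model$params), delta = 0.01,
                central = FALSE, metric = metric_under_params) {
  p0 <- model$params
  M0 <- metric(model, p0)
  if (!is.finite(M0) || M0 == 0)
    stop("metric at nominal parameters is ", M0, " (relative change undefined)")
  vapply(parameters, function(pn) {
    up <- p0; up[pn] <- up[pn] * (1 + delta)
    if (central) {
      dn <- p0; dn[pn] <- dn[pn] * (1 - delta)
      (metric(model, up) - metric(model, dn)) / M0 / (2 * delta)
    } else {
      (metric(model, up) - M0) / M0 / delta
    }
  }, 0)
}

#' Sobol low-discrepancy samples around nominal parameters
#'
#' Generates a base-2 Sobol sequence (Gray-code construction,
#' direction numbers after Joe & Kuo) and maps each coordinate
#' log-uniformly onto `[p/fold, p*fold]` around the nominal value, i.e.
#' a `fold^2`-fold total span interpreted symmetrically on the log axis.
#' With `fold = 1` every point equals the nominal vector.
#'
#' @param nominal Named positive numeric vector.
#' @param fold Half-range factor (default 10: a "10-fold range around"
#'   nominal).
#' @param N Number of points (>= 8).
#' @param skip Points of the sequence to skip (default 0; the first point
#'   maps to the nominal vector itself).
#' @return `N x length(nominal)` matrix with named columns.
#' @export
sobol_sample <- function(nominal, fold = 10, N = 1024, skip = 0) {
  if (any(nominal <= 0)) stop("nominal parameters must be positive")
  if (N < 8) stop("N must be at least 8")
  u <- sobol_sequence(N, length(nominal), skip = skip)
  lo <- log(nominal / fold); hi <- log(nominal * fold)
  out <- exp(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  colnames(out) <- names(nominal)
  out
}

# Direction numbers (s, a, m_i) for dimensions 2..24 after Joe & Kuo;
# dimension 1 is the van der Corput sequence.
.sobol_dirs <- list(
  list(s = 1, a = 0, m = 1), list(s = 2, a = 1, m = c(1, 3)),
  list(s = 3, a = 1, m = c(1, 3, 1)), list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)), list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)), list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)), list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)), list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1, m = c(1, 3, 3, 9, 7, 49)), list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)), list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 15, 13, 25)), list(s = 6, a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(s = 7, a = 1, m = c(1, 3, 7, 11, 23, 15, 103)), list(s = 7, a = 4, m = c(1, 3, 7, 13, 13, 15, 69)),
  list(s = 7, a = 7, m = c(1, 1, 3, 13, 7, 35, 63)), list(s = 7, a = 8, m = c(1, 3, 5, 9, 1, 25, 53)),
  list(s = 7, a = 14, m = c(1, 3, 1, 13, 9, 35, 107)))

#' Base-2 Sobol sequence
#'
#' Gray-code implementation; deterministic (no scrambling).
#'
#' @param N Number of points.
#' @param d Dimension (1 to 24).
#' @param skip Leading points to skip.
#' @return `N x d` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(N, d, skip = 0) {
  if (d < 1 || d > 24) stop("Sobol dimension supported up to 24")
  nbits <- 31L
  # direction integers V[b, j], scaled by 2^-nbits at the end
  V <- matrix(0, nbits, d)
  V[, 1] <- bitwShiftL(1L, nbits - seq_len(nbits))
  for (j in seq_len(d - 1)) {
    dd <- .sobol_dirs[[j]]
    s <- dd$s; a <- dd$a; m <- dd$m
    v <- integer(nbits)
    v[seq_len(s)] <- bitwShiftL(as.integer(m), nbits - seq_len(s))
    if (nbits > s) for (b in (s + 1):nbits) {
      x <- bitwXor(v[b - s], bitwShiftR(v[b - s], s))
      if (s > 1) for (k in seq_len(s - 1))
        if (bitwAnd(bitwShiftR(a, s - 1 - k), 1L) == 1L)
          x <- bitwXor(x, v[b - k])
      v[b] <- x
    }
    V[, j + 1] <- v
  }
  total <- N + skip
  X <- matrix(0, N, d)
  state <- integer(d)
  for (i in seq_len(total)) {
    if (i > skip) X[i - skip, ] <- state / 2^nbits
    # Antonov-Saleev: flip the direction of the lowest zero bit of i-1
    c <- 1L; ii <- i - 1L
    while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
    state <- bitwXor(state, V[c, ])
  }
  X
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms the sample matrix and the output, then for each
#' parameter regresses both its rank column and the output ranks linearly
#' on all other rank-transformed parameters and correlates the two
#' residual vectors.
#'
#' @param samples `N x P` matrix of parameter samples.
#' @param outputs Length-`N` output vector.
#' @return Named numeric vector of PRCC values in `[-1, 1]`.
#' @export
prcc <- function(samples, outputs) {
  N <- nrow(samples); P <- ncol(samples)
  if (N <= P + 2) stop("need N > P + 2 samples")
  R <- apply(samples, 2, rank)
  ry <- rank(outputs)
  degen <- apply(R, 2, function(x) stats::sd(x) == 0)
  if (any(degen))
    stop("rank-degenerate parameter column(s): ",
         paste(colnames(samples)[degen], collapse = ", "))
  out <- numeric(P)
  for (j in seq_len(P)) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    rj <- stats::lm.fit(Z, R[, j])$residuals
    rm <- stats::lm.fit(Z, ry)$residuals
    out[j] <- sum((rj - mean(rj)) * (rm - mean(rm))) /
      sqrt(sum((rj - mean(rj))^2) * sum((rm - mean(rm))^2))
  }
  stats::setNames(out, colnames(samples))
}

#' Combined local + global sensitivity report
#'
#' Runs [lsa()] on the target parameters, draws [sobol_sample()] points,
#' evaluates the Bcl-2 metric on each, computes [prcc()], and returns a
#' table sorted by |PRCC|. Reports with the minimal N = 8 carry a
#' wide-uncertainty flag.
#'
#' @param model A `bar_model`.
#' @param targets Parameter names to analyse.
#' @param N Number of Sobol points.
#' @param fold Sampling half-range factor.
#' @param iso Stimulus (M) under which the metric is evaluated.
#' @param delta LSA perturbation.
#' @return A `bar_gsa` data frame: `parameter`, `lsa`, `prcc`, `rank`, with
#'   attributes `n`, `fold`, `wide_uncertainty` and `failed` (count of
#'   failed metric evaluations, excluded from the PRCC).
#' @export
gsa_report <- function(model, targets, N = 256, fold = 10, iso = 1e-6,
                       delta = 0.01) {
  metric <- function(m, p) metric_under_params(m, p, iso = iso)
  l <- lsa(model, targets, delta = delta, metric = metric)
  nom <- model$params[targets]
  S <- sobol_sample(nom, fold = fold, N = N)
  M <- apply(S, 1, function(row) {
    tryCatch(metric(model, stats::setNames(row, targets)),
             error = function(e) NA_real_)
  })
  ok <- is.finite(M)
  pr <- prcc(S[ok, , drop = FALSE], M[ok])
  out <- data.frame(parameter = targets, lsa = unname(l), prcc = unname(pr),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$prcc)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n") <- sum(ok)
  attr(out, "fold") <- fold
  attr(out, "failed") <- sum(!ok)
  attr(out, "wide_uncertainty") <- sum(ok) <= 8
  class(out) <- c("bar_gsa", "data.frame")
  out
}
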