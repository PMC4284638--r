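# Toy models and independent oracles used across the suite.

# one-species relaxation dx/dt = k (u - x); closed form x(t) = u(1 - e^{-kt})
toy_linear_model <- function(k = 1, u = 1) {
  new_network_model(
    species = data.frame(name = "x", role = "protein", pool = NA, init = 0,
                         stringsAsFactors = FALSE),
    params = c(k_in = k * u, k_out = k),
    reactions = list(
      list(id = "in", target = "x", sign = 1, k = "k_in", factors = list()),
      list(id = "out", target = "x", sign = -1, k = "k_out",
           factors = list(list(type = "lin", var = "x")))),
    name = "linear relaxation toy")
}

# ligand -> X -> Y mass-action chain (2 dynamic species, constant source)
toy_chain_model <- function(k1 = 2, k2 = 1, d1 = 1, d2 = 0.5) {
  new_network_model(
    species = data.frame(name = c("X", "Y"), role = "protein", pool = NA,
                         init = c(0, 0), stringsAsFactors = FALSE),
    params = c(k1 = k1, k2 = k2, d1 = d1, d2 = d2),
    reactions = list(
      list(id = "sx", target = "X", sign = 1, k = "k1", factors = list()),
      list(id = "dx", target = "X", sign = -1, k = "d1",
           factors = list(list(type = "lin", var = "X"))),
      list(id = "sy", target = "Y", sign = 1, k = "k2",
           factors = list(list(type = "lin", var = "X"))),
      list(id = "dy", target = "Y", sign = -1, k = "d2",
           factors = list(list(type = "lin", var = "Y")))),
    name = "2-species chain toy")
}

# random mass-action toy: n species, synthesis/decay plus random
# bimolecular-style couplings expressed in the factor grammar
random_mass_action_model <- function(n_species = 5, seed = 1) {
  set.seed(seed)
  sp <- paste0("S", seq_len(n_species))
  params <- c()
  rxs <- list()
  for (i in seq_len(n_species)) {
    kin <- paste0("kin", i); kout <- paste0("kout", i)
    params[kin] <- runif(1, 0.5, 2)
    params[kout] <- runif(1, 0.5, 2)
    rxs[[length(rxs) + 1]] <- list(id = paste0("in", i), target = sp[i],
                                   sign = 1, k = kin, factors = list())
    rxs[[length(rxs) + 1]] <- list(id = paste0("out", i), target = sp[i],
                                   sign = -1, k = kout,
                                   factors = list(list(type = "lin", var = sp[i])))
  }
  n_cpl <- n_species
  for (j in seq_len(n_cpl)) {
    pick <- sample(n_species, 3)
    kc <- paste0("kc", j)
    params[kc] <- runif(1, 0.1, 1)
    # A + B -> A + C (rate k * A * B; consumes B, produces C): bounded
    stoich <- stats::setNames(c(-1, 1), sp[pick[2:3]])
    rxs[[length(rxs) + 1]] <- list(
      id = paste0("cpl", j), stoich = stoich, k = kc,
      factors = list(list(type = "lin", var = sp[pick[1]]),
                     list(type = "lin", var = sp[pick[2]])))
  }
  m <- new_network_model(
    species = data.frame(name = sp, role = "protein", pool = NA,
                         init = runif(n_species, 0, 0.5),
                         stringsAsFactors = FALSE),
    params = params, reactions = rxs,
    name = sprintf("random %d-species mass-action toy", n_species))
  m
}

# stimulus-driven relaxation toy: dx/dt = kin * occ(L) - kout * x with
# competitive beta1-type occupancy; basal (L = 0) is x = 0, and under a
# constant dose x(t) = (kin occ / kout)(1 - e^{-kout t})
toy_stim_model <- function(kin = 2, kout = 1, KL = 1e-8) {
  new_network_model(
    species = data.frame(name = "x", role = "protein", pool = NA, init = 0,
                         stringsAsFactors = FALSE),
    params = c(kin = kin, kout = kout, KL1 = KL),
    reactions = list(
      list(id = "in", target = "x", sign = 1, k = "kin",
           factors = list(list(type = "occ", receptor = "b1"))),
      list(id = "out", target = "x", sign = -1, k = "kout",
           factors = list(list(type = "lin", var = "x")))),
    name = "stimulus relaxation toy")
}

# fixed-step classical RK4 oracle, independent of deSolve
rk4_integrate <- function(model, y0, t_end, h = 1e-4, n_out = 5) {
  y <- y0
  t_out <- seq(0, t_end, length.out = n_out)
  out <- matrix(NA_real_, n_out, length(y0))
  out[1, ] <- y
  k_next <- 2
  t <- 0
  n_steps <- ceiling(t_end / h)
  h <- t_end / n_steps
  for (s in seq_len(n_steps)) {
    k1 <- model_rhs(model, y)
    k2 <- model_rhs(model, y + h / 2 * k1)
    k3 <- model_rhs(model, y + h / 2 * k2)
    k4 <- model_rhs(model, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    while (k_next <= n_out && t >= t_out[k_next] - h / 2) {
      out[k_next, ] <- y
      k_next <- k_next + 1
    }
  }
  list(times = t_out, values = out)
}

# pointwise inequality-check oracle for switching classification
switching_oracle <- function(doses, values, basal, up = 1.2, down = 0.8) {
  fold <- values / basal
  ip <- which.max(fold)
  interior <- length(fold) >= 3 && ip > 1 && ip < length(fold)
  isTRUE(interior && fold[ip] >= up && fold[length(fold)] <= down)
}

# partial correlation via precision matrix on rank-transformed data:
# independent route to the residual-correlation construction
prcc_oracle <- function(samples, outputs) {
  R <- cbind(apply(samples, 2, rank), rank(outputs))
  S <- stats::cov(R)
  P <- solve(S)
  k <- ncol(samples)
  out <- numeric(k)
  for (j in seq_len(k))
    out[j] <- -P[j, k + 1] / sqrt(P[j, j] * P[k + 1, k + 1])
  stats::setNames(out, colnames(samples))
}

full_model_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- bar_full_model()
    m
  }
})
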