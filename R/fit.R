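# Least-squares parameter estimation with an elitist genetic algorithm.
#
# Datasets use the shared schema: a data frame with columns
# observable, time_h, mean, sem, stimulus_M, plus an observable -> species
# mapping. Before differencing, every observable is scaled to its own
# maximum (blot-style fold-change data carry no absolute scale).

#' Sum-of-squares objective for time-course data
#'
#' Simulates the model once per stimulus dose, extracts each observable at
#' the dataset's time points, normalises simulation and data per observable
#' to their own maxima, and returns the summed squared difference. A failed
#' integration returns `penalty` (flagged via attribute).
#'
#' @param model A `bar_model`.
#' @param params Named numeric vector of parameter values to score (subset
#'   of the model's parameters).
#' @param dataset Data frame (`observable`, `time_h`, `mean`, `sem`,
#'   `stimulus_M`).
#' @param mapping Named character vector `observable -> species`; defaults
#'   to identity.
#' @param penalty Value returned when integration fails (default 1e6).
#' @return Scalar SSE (attribute `failed` = TRUE after an integration
#'   failure).
#' @export
sse_objective <- function(model, params, dataset, mapping = NULL,
                          penalty = 1e6) {
  if (length(params)) model <- set_model_params(model, params)
  if (is.null(mapping)) {
    obs <- unique(dataset$observable)
    mapping <- stats::setNames(obs, obs)
  }
  bad <- setdiff(unique(dataset$observable), names(mapping))
  if (length(bad)) stop("unmapped observables: ", paste(bad, collapse = ", "))
  bad_sp <- setdiff(unlist(mapping), model$species$name)
  if (length(bad_sp))
    stop("unmapped observables (no such model species): ",
         paste(bad_sp, collapse = ", "))
  sse <- 0
  for (d in unique(dataset$stimulus_M)) {
    sub <- dataset[dataset$stimulus_M == d, , drop = FALSE]
    tgrid <- sort(unique(c(0, sub$time_h)))
    tc <- tryCatch(
      simulate_timecourse(model, d, t_end = max(tgrid), times = tgrid),
      error = function(e) NULL)
    if (is.null(tc)) {
      out <- penalty; attr(out, "failed") <- TRUE; return(out)
    }
    for (ob in unique(sub$observable)) {
      oo <- sub[sub$observable == ob, , drop = FALSE]
      sim <- tc$values[match(oo$time_h, tc$times), mapping[[ob]]]
      sim_n <- sim / max(max(sim), 1e-12)
      dat_n <- oo$mean / max(max(oo$mean), 1e-12)
      sse <- sse + sum((sim_n - dat_n)^2)
    }
  }
  attr(sse, "failed") <- FALSE
  sse
}

#' Fit parameters with an elitist genetic algorithm
#'
#' Minimises [sse_objective()] over log-scaled parameters inside the given
#' bounds. The GA uses tournament selection, uniform crossover, Gaussian
#' mutation in log space, and copies the elite fraction unchanged into the
#' next generation, so the best score never worsens.
#'
#' @param model A `bar_model`.
#' @param dataset Dataset data frame (see [sse_objective()]).
#' @param bounds 2-row matrix (`lower`, `upper`) with one column per free
#'   parameter, finite and positive; column names are the parameter names.
#' @param pop Population size.
#' @param generations Number of generations (0 = score the random initial
#'   population only).
#' @param elite Fraction copied unchanged (default 0.1).
#' @param mutate_sd Gaussian mutation s.d. in log10 units.
#' @param p_mutate Per-gene mutation probability.
#' @param seed RNG seed.
#' @param mapping Observable mapping for [sse_objective()].
#' @return A `bar_fit`: `par` (best parameters), `value` (SSE), `trace`
#'   (per-generation best SSE, non-increasing), `seed`, `bounds`.
#' @export
fit_parameters <- function(model, dataset, bounds, pop = 40,
                           generations = 30, elite = 0.1, mutate_sd = 0.15,
                           p_mutate = 0.3, seed = 1, mapping = NULL) {
  stopifnot(is.matrix(bounds), nrow(bounds) == 2)
  if (any(!is.finite(bounds)) || any(bounds <= 0))
    stop("bounds must be finite and positive")
  pn <- colnames(bounds)
  lo <- log10(bounds[1, ]); hi <- log10(bounds[2, ])
  stopifnot(all(lo < hi))
  np <- length(pn)
  set.seed(seed)
  score <- function(x) {
    p <- stats::setNames(10^x, pn)
    sse_objective(model, p, dataset, mapping)
  }
  X <- matrix(stats::runif(pop * np, rep(lo, each = pop), rep(hi, each = pop)),
              pop, np)
  fit <- apply(X, 1, score)
  if (all(!is.finite(fit))) stop("objective non-finite for the whole population")
  n_elite <- max(1L, floor(elite * pop))
  trace <- numeric(generations + 1)
  trace[1] <- min(fit)
  if (generations > 0) for (g in seq_len(generations)) {
    ord <- order(fit)
    newX <- X[ord[seq_len(n_elite)], , drop = FALSE]
    while (nrow(newX) < pop) {
      # tournament selection of two parents
      pick <- function() {
        cand <- sample.int(pop, 2)
        cand[which.min(fit[cand])]
      }
      p1 <- X[pick(), ]; p2 <- X[pick(), ]
      cross <- stats::runif(np) < 0.5
      child <- ifelse(cross, p1, p2)
      mut <- stats::runif(np) < p_mutate
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, mutate_sd)
      child <- pmin(pmax(child, lo), hi)
      newX <- rbind(newX, child)
    }
    keep <- fit[ord[seq_len(n_elite)]]
    X <- newX
    fit <- c(keep, apply(X[-seq_len(n_elite), , drop = FALSE], 1, score))
    trace[g + 1] <- min(fit)
  }
  best <- which.min(fit)
  structure(list(par = stats::setNames(10^X[best, ], pn), value = fit[best],
                 trace = trace[seq_len(if (generations > 0) generations + 1 else 1)],
                 seed = seed, bounds = bounds),
            class = "bar_fit")
}

#' @export
print.bar_fit <- function(x, ...) {
  cat("<bar_fit> SSE", format(x$value, digits = 5), "after",
      length(x$trace) - 1, "generations\n")
  print(signif(x$par, 4))
  invisible(x)
}
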