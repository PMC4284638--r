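# Synthetic experimental data with the statistical structure the analysis
# assumes: noisy time courses for fitting, labelled dose-response shapes
# for classifier validation, and parameter-recovery benchmarks.

#' Specification for a synthetic time-course dataset
#'
#' @param model Generating `bar_model` (its current parameters are the
#'   ground truth).
#' @param observables Species recorded (defaults mirror the measured
#'   panel: p-ERK1/2, p-CREB, ICER, SOS/Grb2 complex, PDE3, CaMKII, cAMP
#'   and PKA activity).
#' @param doses Stimulus doses (M), default 10 pM / 10 nM / 10 uM.
#' @param times Sampling times (h), dense early and sparse late.
#' @param cv Coefficient of variation of the multiplicative log-normal
#'   noise (median of the noise factor is 1, i.e. mu = 0 in log space).
#' @param replicates Independent replicates per point (>= 1).
#' @param seed RNG seed.
#' @return A `bar_synth_spec` list.
#' @export
synthetic_spec <- function(model,
                           observables = c("pERK", "pCREB", "ICER",
                                           "SOSGrb2", "PDE3", "CaMKIIa",
                                           "cAMP", "PKAc"),
                           doses = c(1e-11, 1e-8, 1e-5),
                           times = c(0, 0.25, 0.5, 1, 2, 4, 8, 12, 24, 48),
                           cv = 0.2, replicates = 3, seed = 1) {
  stopifnot(cv >= 0, replicates >= 1, all(times >= 0))
  bad <- setdiff(observables, model$species$name)
  if (length(bad)) stop("unknown observables: ", paste(bad, collapse = ", "))
  structure(list(model = model, observables = observables, doses = doses,
                 times = sort(unique(times)), cv = cv,
                 replicates = replicates, seed = seed),
            class = "bar_synth_spec")
}

#' Generate synthetic time-course data
#'
#' Simulates the generating model at each dose, multiplies every
#' observable value by independent log-normal noise
#' (`sdlog = sqrt(log(1 + cv^2))`, `meanlog = 0`, so the median equals the
#' clean value), and summarises replicates as mean and s.e.m. in the shared
#' dataset schema.
#'
#' @param spec A [synthetic_spec()].
#' @param path Optional directory; when given, `dataset.csv`,
#'   `replicates.csv` and `manifest.json` are written there.
#' @return List with `dataset` (observable, time_h, mean, sem, stimulus_M),
#'   `replicates` (long, one row per replicate), `clean` (noiseless
#'   values) and `manifest` (true parameters, seed, checksums).
#' @export
generate_timecourses <- function(spec, path = NULL) {
  m <- spec$model
  sims <- lapply(spec$doses, function(d)
    simulate_timecourse(m, d, t_end = max(spec$times), times = spec$times))
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  rows <- list(); reps <- list(); clean <- list()
  for (i in seq_along(spec$doses)) {
    vals <- sims[[i]]$values[, spec$observables, drop = FALSE]
    for (ob in spec$observables) {
      v <- vals[, ob]
      noise <- matrix(stats::rlnorm(length(v) * spec$replicates, 0, sdlog),
                      length(v), spec$replicates)
      Y <- v * noise
      rows[[length(rows) + 1]] <- data.frame(
        observable = ob, time_h = spec$times,
        mean = rowMeans(Y),
        sem = apply(Y, 1, stats::sd) / sqrt(spec$replicates),
        stimulus_M = spec$doses[i], stringsAsFactors = FALSE)
      reps[[length(reps) + 1]] <- data.frame(
        observable = ob, time_h = rep(spec$times, spec$replicates),
        replicate = rep(seq_len(spec$replicates), each = length(v)),
        value = as.vector(Y), stimulus_M = spec$doses[i],
        stringsAsFactors = FALSE)
      clean[[length(clean) + 1]] <- data.frame(
        observable = ob, time_h = spec$times, value = v,
        stimulus_M = spec$doses[i], stringsAsFactors = FALSE)
    }
  }
  dataset <- do.call(rbind, rows)
  replicates <- do.call(rbind, reps)
  clean <- do.call(rbind, clean)
  manifest <- list(
    true_params = as.list(m$params), seed = spec$seed, cv = spec$cv,
    replicates = spec$replicates, doses = spec$doses,
    observables = spec$observables,
    checksums = list(dataset = dataset_checksum(dataset),
                     replicates = dataset_checksum(replicates)))
  if (!is.null(path)) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(dataset, file.path(path, "dataset.csv"),
                     row.names = FALSE)
    utils::write.csv(replicates, file.path(path, "replicates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(dataset = dataset, replicates = replicates, clean = clean,
       manifest = manifest)
}

# order-insensitive numeric checksum (no external digest dependency)
dataset_checksum <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  x <- unlist(df[num], use.names = FALSE)
  sprintf("%.10e", sum(x * seq_along(x) %% 97) + sum(x))
}

#' Generate labelled dose-response curves
#'
#' Builds curves of known shape for classifier validation: monotone-up,
#' monotone-down, flat, bell (returning to basal) and switching (bell whose
#' terminal value lies below `theta_down * basal`). Gaussian noise of
#' amplitude `noise * basal` is added after shaping.
#'
#' @param n Curves per requested shape (>= 1).
#' @param shapes Subset of `c("monotone-up", "monotone-down", "flat",
#'   "bell", "switching")`.
#' @param noise Relative noise amplitude.
#' @param seed RNG seed.
#' @param doses Dose grid.
#' @param basal Basal value.
#' @return List of `bar_curve` objects with a `label` field attached.
#' @export
generate_curves <- function(n, shapes = c("monotone-up", "monotone-down",
                                          "flat", "bell", "switching"),
                            noise = 0, seed = 1,
                            doses = default_dose_grid(per_decade = 2),
                            basal = 1) {
  stopifnot(n >= 1)
  known <- c("monotone-up", "monotone-down", "flat", "bell", "switching")
  bad <- setdiff(shapes, known)
  if (length(bad)) stop("unknown shape(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  lx <- log10(doses); lmid <- mean(range(lx)); lspan <- diff(range(lx))
  out <- list()
  for (sh in shapes) for (i in seq_len(n)) {
    amp <- stats::runif(1, 0.8, 2.5)       # peak height above basal
    shape_vals <- switch(sh,
      "monotone-up" = basal * (1 + amp / (1 + exp(-(lx - lmid) * 2))),
      "monotone-down" = basal * (1 - 0.7 / (1 + exp(-(lx - lmid) * 2))),
      "flat" = rep(basal, length(lx)),
      "bell" = basal * (1 + amp * exp(-((lx - lmid) / (lspan / 6))^2)),
      "switching" = {
        drop <- stats::runif(1, 0.3, 0.7)  # terminal fraction of basal
        bell <- amp * exp(-((lx - (lmid - lspan / 8)) / (lspan / 7))^2)
        fall <- (1 - drop) / (1 + exp(-(lx - (lmid + lspan / 4)) * 4))
        basal * (1 + bell - fall)
      })
    vals <- shape_vals + stats::rnorm(length(lx), 0, noise * basal)
    out[[length(out) + 1]] <- structure(
      list(doses = doses, values = vals, readout = "synthetic",
           observation_time = NA_real_, basal = basal, label = sh),
      class = "bar_curve")
  }
  out
}

#' Parameter-recovery benchmark
#'
#' For each noise level and seed: generate a synthetic dataset from the
#' model's current (true) parameters, fit the free parameters with the GA,
#' and report per-parameter bias and relative RMSE.
#'
#' @param model Generating `bar_model`.
#' @param free Character vector of free parameter names.
#' @param noise_levels Vector of CVs.
#' @param n_seeds Seeds per noise level.
#' @param spread Bounds are `true/spread` to `true*spread` (default 10).
#' @param pop,generations GA settings.
#' @param spec_args Extra arguments for [synthetic_spec()].
#' @return Data frame: `noise`, `parameter`, `bias`, `rel_rmse`.
#' @export
recovery_benchmark <- function(model, free, noise_levels = c(0, 0.2),
                               n_seeds = 3, spread = 10, pop = 24,
                               generations = 15, spec_args = list()) {
  if (!length(free)) {
    return(data.frame(noise = numeric(0), parameter = character(0),
                      bias = numeric(0), rel_rmse = numeric(0)))
  }
  truth <- model$params[free]
  bounds <- rbind(lower = truth / spread, upper = truth * spread)
  colnames(bounds) <- free
  rows <- list()
  for (nv in noise_levels) {
    est <- matrix(NA_real_, n_seeds, length(free),
                  dimnames = list(NULL, free))
    for (s in seq_len(n_seeds)) {
      spec <- do.call(synthetic_spec,
                      c(list(model = model, cv = nv, seed = s), spec_args))
      dat <- generate_timecourses(spec)$dataset
      ft <- fit_parameters(model, dat, bounds, pop = pop,
                           generations = generations, seed = s)
      est[s, ] <- ft$par[free]
    }
    for (pn in free) {
      err <- (est[, pn] - truth[pn]) / truth[pn]
      rows[[length(rows) + 1]] <- data.frame(
        noise = nv, parameter = pn, bias = mean(err),
        rel_rmse = sqrt(mean(err^2)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
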