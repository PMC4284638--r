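# Integration of network models: time courses, steady states, dose-response
# curves and parameter-jitter ensembles.

#' Default ISO dose grid
#'
#' Log-spaced agonist grid, 10 points per decade over 1e-12 to 1e-3 M
#' (91 points).
#'
#' @param from,to Grid limits (M).
#' @param per_decade Points per decade.
#' @return Ascending numeric vector of doses in molar.
#' @export
default_dose_grid <- function(from = 1e-12, to = 1e-3, per_decade = 10) {
  10^seq(log10(from), log10(to), by = 1 / per_decade)
}

default_solver_opts <- list(rtol = 1e-6, atol = 1e-9, method = "lsoda",
                            maxsteps = 50000)

# Low-level integration over a time grid. `y0` named state vector.
integrate_model <- function(model, y0, times, solver_opts = list()) {
  so <- utils::modifyList(default_solver_opts, solver_opts)
  if (identical(model$backend, "compiled")) {
    out <- deSolve::ode(
      y = unname(y0), times = times, func = "barswitch_full_rhs",
      parms = unname(full_parms_vector(model)), dllname = "barswitch",
      initfunc = "barswitch_full_init", method = so$method,
      rtol = so$rtol, atol = so$atol, maxsteps = so$maxsteps)
  } else {
    out <- deSolve::ode(
      y = unname(y0), times = times, func = model_rhs_fn(model),
      parms = NULL, method = so$method,
      rtol = so$rtol, atol = so$atol, maxsteps = so$maxsteps)
  }
  di <- attr(out, "istate")
  if (!is.null(di) && di[1] < 0)
    stop("integration failed (istate = ", di[1], ") at dose L = ",
         model$controls[["L"]], " M")
  if (nrow(out) < length(times))
    stop("integrator returned a truncated trajectory (", nrow(out), "/",
         length(times), " steps); solver diagnostics: istate = ",
         if (is.null(di)) NA else di[1])
  vals <- out[, -1, drop = FALSE]
  if (min(vals) < -1e-6)
    stop("negative state beyond tolerance (min = ", format(min(vals)), ")")
  vals[vals < 0] <- 0
  colnames(vals) <- model$species$name
  list(times = out[, 1], values = vals)
}

#' Simulate a time course
#'
#' Integrates the model under a constant agonist dose, starting from the
#' basal (unstimulated) steady state by default.
#'
#' @param model A `bar_model`.
#' @param dose ISO concentration (M), >= 0.
#' @param t_end End of simulation (h).
#' @param initial Named initial state vector, or `"basal"` to start from the
#'   pre-equilibrated dose-0 steady state.
#' @param times Optional explicit output time grid (h); defaults to a dense
#'   grid of 241 points over `[0, t_end]`.
#' @param solver_opts List of solver settings (`rtol`, `atol`, `method`,
#'   `maxsteps`).
#' @return A `bar_timecourse`: list with `times`, `values` (time x species
#'   matrix), `dose` and `stimulus` description.
#' @export
simulate_timecourse <- function(model, dose, t_end = 48, initial = "basal",
                                times = NULL, solver_opts = list()) {
  stopifnot(dose >= 0, t_end > 0)
  y0 <- resolve_initial(model, initial, solver_opts)
  if (is.null(times)) times <- seq(0, t_end, length.out = 241)
  stopifnot(!is.unsorted(times))
  m <- set_model_controls(model, L = dose)
  m$cache <- model$cache  # controls other than L are unchanged upstream
  sim <- integrate_model(m, y0, times, solver_opts)
  structure(list(times = sim$times, values = sim$values, dose = dose,
                 stimulus = sprintf("constant ISO %.3g M from t = 0", dose)),
            class = "bar_timecourse")
}

resolve_initial <- function(model, initial, solver_opts = list()) {
  if (is.character(initial) && identical(initial, "basal"))
    return(basal_state(model, solver_opts))
  if (is.null(names(initial)))
    names(initial) <- model$species$name
  if (any(initial < 0)) stop("initial state must be non-negative")
  initial[model$species$name]
}

#' Basal (unstimulated) steady state
#'
#' Pre-equilibrates the model at dose 0 for 200 h from the declared initial
#' state, continues in 200 h blocks until the right-hand-side norm is small,
#' then polishes by Newton iteration. The result is cached on the model
#' object, so repeated dose-response evaluations reuse it.
#'
#' @param model A `bar_model`.
#' @param solver_opts Solver settings.
#' @return Named state vector.
#' @export
basal_state <- function(model, solver_opts = list()) {
  key <- "basal"
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  st <- steady_state(model, dose = 0, solver_opts = solver_opts)
  assign(key, st, envir = model$cache)
  st
}

#' Steady state under a constant dose
#'
#' Long-time integration (200 h blocks, up to `max_t`) followed by Newton
#' polishing on the interpreted right-hand side. Convergence requires the
#' RHS norm to fall below `tol`.
#'
#' @param model A `bar_model`.
#' @param dose ISO concentration (M).
#' @param tol Absolute tolerance on the RHS max-norm (default 1e-9).
#' @param max_t Maximum integration time (h) before giving up.
#' @param initial Initial state (named vector) or `NULL` for the declared
#'   model initial values.
#' @param solver_opts Solver settings.
#' @return Named state vector with attribute `residual`.
#' @export
steady_state <- function(model, dose = 0, tol = 1e-9, max_t = 2400,
                         initial = NULL, solver_opts = list()) {
  m <- set_model_controls(model, L = dose)
  y <- if (is.null(initial)) {
    stats::setNames(model$species$init, model$species$name)
  } else resolve_initial(model, initial, solver_opts)
  t_done <- 0
  repeat {
    sim <- integrate_model(m, y, c(0, 100, 200), solver_opts)
    y <- sim$values[3, ]
    t_done <- t_done + 200
    res <- max(abs(model_rhs(m, y)))
    if (res < 1e-6 || t_done >= max_t) break
  }
  # Newton polish on the interpreted RHS
  y <- newton_polish(m, y, tol = tol)
  res <- max(abs(model_rhs(m, y)))
  if (res > tol)
    stop("steady state did not converge (possible oscillation); residual = ",
         format(res))
  attr(y, "residual") <- res
  y
}

newton_polish <- function(model, y, tol = 1e-9, max_iter = 20) {
  n <- length(y)
  for (it in seq_len(max_iter)) {
    f <- model_rhs(model, y)
    if (max(abs(f)) < tol * 0.1) break
    J <- matrix(0, n, n)
    h <- pmax(abs(y), 1e-6) * 1e-7
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- yp[j] + h[j]
      J[, j] <- (model_rhs(model, yp) - f) / h[j]
    }
    # states with no dynamics left (e.g. a knocked-out receptor) give an
    # all-zero row; pin them so the Newton system stays solvable
    inert <- rowSums(abs(J)) < 1e-12 & abs(f) < 1e-12
    if (any(inert)) J[cbind(which(inert), which(inert))] <- 1
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    # damped update, keep states non-negative
    lambda <- 1
    repeat {
      y_new <- pmax(y + lambda * step, 0)
      if (max(abs(model_rhs(model, y_new))) <= max(abs(f)) || lambda < 1e-4)
        break
      lambda <- lambda / 2
    }
    if (max(abs(y_new - y)) < 1e-14) { y <- y_new; break }
    y <- y_new
  }
  y
}

#' Dose-response curve
#'
#' For each dose, simulates from the basal steady state for
#' `observation_time` hours and records the readout.
#'
#' @param model A `bar_model`.
#' @param doses Ascending agonist grid (M); default 10 points/decade over
#'   1e-12 to 1e-3 M.
#' @param readout Species name (e.g. `"Bcl2"`, `"PKAc"`, `"pERK"`).
#' @param observation_time Observation time after stimulation (h).
#' @param solver_opts Solver settings.
#' @return A `bar_curve`: `doses`, `values`, `readout`, `observation_time`,
#'   and the `basal` readout value.
#' @export
dose_response <- function(model, doses = default_dose_grid(),
                          readout = "Bcl2", observation_time = 24,
                          solver_opts = list()) {
  if (!length(doses)) stop("empty dose grid")
  if (length(doses) > 1 && is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly ascending")
  if (!readout %in% model$species$name)
    stop("unknown readout: ", readout)
  y0 <- basal_state(model, solver_opts)
  vals <- vapply(doses, function(d) {
    if (d == 0) return(unname(y0[readout]))
    m <- set_model_controls(model, L = d)
    sim <- integrate_model(m, y0, c(0, observation_time / 2, observation_time),
                           solver_opts)
    sim$values[3, readout]
  }, 0)
  structure(list(doses = doses, values = vals, readout = readout,
                 observation_time = observation_time,
                 basal = unname(y0[readout])),
            class = "bar_curve")
}

#' @export
print.bar_curve <- function(x, ...) {
  cat("<bar_curve> ", x$readout, " at ", x$observation_time, " h, ",
      length(x$doses), " doses [",
      format(min(x$doses)), ", ", format(max(x$doses)), "] M\n", sep = "")
  cat("  basal ", format(x$basal, digits = 4), "; range [",
      format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.bar_curve <- function(x, ...) {
  data.frame(dose_M = x$doses, readout = x$readout, value = x$values)
}

#' @export
as.data.frame.bar_timecourse <- function(x, ...) {
  data.frame(time_h = rep(x$times, ncol(x$values)),
             species = rep(colnames(x$values), each = nrow(x$values)),
             value = as.vector(x$values))
}

#' Ensemble dose-response under parameter jitter
#'
#' Repeats the dose-response simulation with multiplicative uniform jitter
#' on every kinetic parameter (independently per parameter and replicate,
#' factors drawn from `U[1 - variation, 1 + variation]`), and summarises
#' per-dose mean and standard error of the mean. Replicates whose
#' integration fails are dropped and counted.
#'
#' @param model A `bar_model`.
#' @param n Number of replicates (>= 1).
#' @param variation Fractional jitter amplitude in `[0, 1)`.
#' @param seed RNG seed (reproducible ensembles).
#' @param jitter_hill Also jitter Hill exponents (default `FALSE`:
#'   cooperativity coefficients are treated as structural constants, only
#'   rate and affinity constants vary).
#' @param doses,readout,observation_time,solver_opts As [dose_response()].
#' @return A `bar_ensemble`: `doses`, `mean`, `sem`, per-replicate matrix
#'   `values`, `n_failed`, and the classifier-ready deterministic `basal`.
#' @export
ensemble_dose_response <- function(model, n = 30, variation = 0.3, seed = 1,
                                   jitter_hill = FALSE,
                                   doses = default_dose_grid(),
                                   readout = "Bcl2", observation_time = 24,
                                   solver_opts = list()) {
  stopifnot(n >= 1, variation >= 0, variation < 1)
  set.seed(seed)
  hill_pars <- c("nsw", "npka", "nic", "npr", "nb", "nbi", "ncam")
  vals <- matrix(NA_real_, n, length(doses))
  basals <- numeric(n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    fac <- stats::runif(length(model$params), 1 - variation, 1 + variation)
    if (!jitter_hill)
      fac[names(model$params) %in% hill_pars] <- 1
    mi <- set_model_params(model, model$params * fac)
    crv <- tryCatch(
      dose_response(mi, doses, readout, observation_time, solver_opts),
      error = function(e) NULL)
    if (is.null(crv)) { n_failed <- n_failed + 1L; next }
    vals[i, ] <- crv$values
    basals[i] <- crv$basal
  }
  ok <- stats::complete.cases(vals)
  structure(list(
    doses = doses, readout = readout, observation_time = observation_time,
    values = vals[ok, , drop = FALSE], basals = basals[ok],
    mean = colMeans(vals[ok, , drop = FALSE]),
    sem = apply(vals[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok)),
    n = sum(ok), n_failed = n_failed), class = "bar_ensemble")
}
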