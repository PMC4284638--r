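# In-silico pharmacological and molecular perturbations: competitive
# beta1/beta2 receptor blockers, graded scaling of regulatory links
# (siRNA / kinase-inhibitor surrogates), PKA inhibition, and cAMP clamping.

#' Define a competitive receptor antagonist
#'
#' @param target `"b1"` (beta1-AR, e.g. metoprolol) or `"b2"` (beta2-AR,
#'   e.g. ICI 118,551).
#' @param concentration Antagonist concentration (M, >= 0).
#' @param K_I Dissociation constant (M, > 0). Defaults: 1e-7 M for the
#'   beta1 blocker, 1e-9 M for the beta2 blocker (configuration values, in
#'   the published affinity range of the two compounds).
#' @return An `bar_antagonist` list.
#' @export
antagonist <- function(target = c("b1", "b2"), concentration,
                       K_I = c(b1 = 1e-7, b2 = 1e-9)[[target]]) {
  target <- match.arg(target)
  stopifnot(K_I > 0, concentration >= 0)
  structure(list(target = target, concentration = concentration, K_I = K_I),
            class = "bar_antagonist")
}

#' Apply a competitive antagonist to the model
#'
#' Receptor occupancy of the targeted subtype becomes
#' `(L/K_L) / (1 + L/K_L + I/K_I)`, i.e. purely competitive binding; the
#' agonist EC50 shifts by the Schild factor `1 + I/K_I` while the other
#' subtype is untouched.
#'
#' @param model A `bar_model`.
#' @param antagonist An [antagonist()] object.
#' @return Modified `bar_model` (the input is unchanged).
#' @export
apply_antagonist <- function(model, antagonist) {
  if (!inherits(antagonist, "bar_antagonist"))
    stop("need an antagonist() object")
  if (!antagonist$target %in% c("b1", "b2"))
    stop("unknown receptor subtype: ", antagonist$target)
  if (antagonist$target == "b1")
    set_model_controls(model, B1conc = antagonist$concentration,
                       B1KI = antagonist$K_I)
  else
    set_model_controls(model, B2conc = antagonist$concentration,
                       B2KI = antagonist$K_I)
}

#' Scale a regulatory link
#'
#' Multiplies every parameter gated by the named link by `factor` in
#' `[0, 1]`; factor 0 reproduces [knockout_links()] for that link, factor 1
#' returns the model unchanged. Graded feed-forward-arm inhibition (e.g.
#' ICER siRNA on `"Bcl2->ICER"`, MEK inhibition on `"ERK->Bcl2"`) is
#' expressed this way.
#'
#' @param model A `bar_model`.
#' @param link Registered link name.
#' @param factor Scaling factor in `[0, 1]`.
#' @return Modified `bar_model`.
#' @export
scale_link <- function(model, link, factor) {
  stopifnot(factor >= 0, factor <= 1)
  link_names <- vapply(model$links, `[[`, "", "name")
  i <- match(link, link_names)
  if (is.na(i)) stop("unknown link: ", link)
  gates <- unlist(model$links[[i]]$gates)
  set_model_params(model, model$params[gates] * factor)
}

#' PKA-inhibitor scan at fixed agonist dose
#'
#' Scales the catalytic activation of PKA by the competitive factor
#' `1 / (1 + inhibitor / K_I)` and records Bcl-2 at `t_obs` hours under a
#' fixed ISO dose, one value per inhibitor dose (the protocol of a
#' RP-cAMPS preincubation experiment).
#'
#' @param model A `bar_model`.
#' @param inhibitor_doses Ascending inhibitor concentrations (arbitrary
#'   molar units consistent with `K_I`).
#' @param iso Agonist dose (M), default 1e-6.
#' @param K_I Inhibitor constant (default 1e-5 M).
#' @param t_obs Observation time (h), default 12.
#' @return A `bar_curve` over inhibitor dose (basal = Bcl-2 of the
#'   unstimulated model).
#' @export
pka_inhibitor_scan <- function(model, inhibitor_doses, iso = 1e-6,
                               K_I = 1e-5, t_obs = 12) {
  vals <- vapply(inhibitor_doses, function(inh) {
    fac <- 1 / (1 + inh / K_I)
    mi <- set_model_params(model, c(kpka = unname(model$params["kpka"]) * fac))
    tc <- simulate_timecourse(mi, iso, t_end = t_obs,
                              times = c(0, t_obs / 2, t_obs))
    tc$values[nrow(tc$values), "Bcl2"]
  }, 0)
  structure(list(doses = inhibitor_doses, values = vals, readout = "Bcl2",
                 observation_time = t_obs,
                 basal = unname(basal_state(model)["Bcl2"])),
            class = "bar_curve")
}

#' Bcl-2 heat map over agonist and blocker concentrations
#'
#' @param model A `bar_model`.
#' @param iso_grid Ascending ISO grid (M).
#' @param blocker_grid Ascending blocker grid (M); a 0 row reproduces the
#'   plain dose response.
#' @param subtype `"b1"` or `"b2"`.
#' @param K_I Blocker dissociation constant (see [antagonist()]).
#' @param observation_time Hours (default 24).
#' @param theta_up Threshold used for the per-blocker-level survival range.
#' @return A `bar_heatmap`: `values` (blocker x iso matrix of Bcl-2),
#'   `survival` (per blocker level, the [survival_range()] interval), grids
#'   and metadata. `as.data.frame()` gives the long (iso_M, blocker_M,
#'   bcl2) table.
#' @export
blocker_heatmap <- function(model, iso_grid = default_dose_grid(per_decade = 2),
                            blocker_grid = 10^seq(-11, -4, by = 1),
                            subtype = c("b1", "b2"),
                            K_I = c(b1 = 1e-7, b2 = 1e-9)[[subtype]],
                            observation_time = 24, theta_up = 1.2) {
  subtype <- match.arg(subtype)
  stopifnot(!is.unsorted(iso_grid), !is.unsorted(blocker_grid))
  vals <- matrix(NA_real_, length(blocker_grid), length(iso_grid),
                 dimnames = list(format(blocker_grid, digits = 3),
                                 format(iso_grid, digits = 3)))
  surv <- matrix(NA_real_, length(blocker_grid), 2)
  for (i in seq_along(blocker_grid)) {
    mi <- apply_antagonist(model, antagonist(subtype, blocker_grid[i], K_I))
    crv <- dose_response(mi, iso_grid, "Bcl2", observation_time)
    vals[i, ] <- crv$values
    surv[i, ] <- survival_range(crv, theta_up = theta_up)
  }
  structure(list(values = vals, survival = surv, iso_grid = iso_grid,
                 blocker_grid = blocker_grid, subtype = subtype, K_I = K_I,
                 observation_time = observation_time),
            class = "bar_heatmap")
}

#' @export
as.data.frame.bar_heatmap <- function(x, ...) {
  data.frame(iso_M = rep(x$iso_grid, each = length(x$blocker_grid)),
             blocker_M = rep(x$blocker_grid, length(x$iso_grid)),
             bcl2 = as.vector(x$values))
}

#' Clamp intracellular cAMP to a fixed level
#'
#' Emulates treatment with a membrane-permeable, phosphodiesterase-
#' resistant cAMP analogue: the cAMP state is held at `level` for
#' `duration` hours (receptor input and PDE degradation of the analogue are
#' bypassed), then released.
#'
#' @param model A `bar_model`.
#' @param level Clamped cAMP level (uM, >= 0).
#' @param duration Clamp duration (h).
#' @param times Output grid (h), default dense over `[0, duration]`.
#' @return A `bar_timecourse` starting from the basal state.
#' @export
camp_clamp <- function(model, level, duration = 48, times = NULL) {
  stopifnot(level >= 0, duration > 0)
  y0 <- basal_state(model)
  # level 0 means no analogue: the control run with native cAMP dynamics
  mi <- if (level > 0)
    set_model_controls(model, clamp_on = 1, clamp_val = level)
  else model
  y0c <- y0
  if (level > 0) y0c["cAMP"] <- level
  if (is.null(times)) times <- seq(0, duration, length.out = 241)
  sim <- integrate_model(mi, y0c, times)
  structure(list(times = sim$times, values = sim$values, dose = 0,
                 stimulus = sprintf("cAMP clamped at %.3g uM for %g h",
                                    level, duration)),
            class = "bar_timecourse")
}
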