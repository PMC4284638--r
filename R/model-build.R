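# Building and validating network models from the declarative model file.

#' Path to the shipped declarative model file
#'
#' The full beta-AR signalling network (32 dynamic states, 105 kinetic
#' parameters) as a declarative YAML description: species (with conserved-pool
#' membership), pool totals, kinetic parameters, reactions in a small
#' rate-law grammar, the named regulatory-link registry, and the
#' species-to-functional-unit mapping used for coarse-graining. The equation
#' set is a synthetic reconstruction of the published network structure,
#' calibrated to reproduce its reported dose-response phenotypes.
#'
#' @return File path of the YAML model description.
#' @export
bar_model_file <- function() {
  system.file("extdata", "bar_model.yaml", package = "barswitch",
              mustWork = TRUE)
}

#' Build a network model from a declarative description
#'
#' Reads a declarative model file (see [bar_model_file()]) and assembles a
#' validated `bar_model` object. Validation checks that species names are
#' unique, that every rate constant referenced by a reaction exists in the
#' parameter table, that pool totals are positive, that every registered
#' regulatory link gates at least one existing parameter, and that the
#' reaction graph connects the stimulus to the Bcl-2 readout.
#'
#' @param model_file Path to a YAML model description, or an already-parsed
#'   list with the same structure. Defaults to the shipped full network.
#' @param param_table Optional named numeric vector overriding the parameter
#'   values stored in the model file (all referenced constants must be
#'   covered).
#' @param totals Optional named numeric vector overriding conserved pool
#'   totals.
#' @param expect_counts Optional integer vector `c(n_states, n_params)`;
#'   when supplied, building fails unless the model has exactly these counts.
#'   The shipped full model is built with `c(32L, 105L)`.
#' @return A `bar_model` object.
#' @export
build_full_model <- function(model_file = bar_model_file(),
                             param_table = NULL, totals = NULL,
                             expect_counts = NULL) {
  def <- if (is.character(model_file)) yaml::read_yaml(model_file) else model_file
  species <- data.frame(
    name = vapply(def$species, `[[`, "", "name"),
    role = vapply(def$species, `[[`, "", "role"),
    pool = vapply(def$species, function(s) s$pool %||% NA_character_, ""),
    init = vapply(def$species, function(s) as.numeric(s$init %||% 0), 0),
    stringsAsFactors = FALSE)
  params <- unlist(def$parameters)
  if (!is.null(param_table)) {
    bad <- setdiff(names(params), names(param_table))
    if (length(bad))
      stop("param_table is missing constants: ", paste(bad, collapse = ", "))
    params <- param_table[names(params)]
  }
  tot <- unlist(def$totals)
  if (!is.null(totals)) {
    bad <- setdiff(names(tot), names(totals))
    if (length(bad)) stop("totals is missing pools: ", paste(bad, collapse = ", "))
    tot <- totals[names(tot)]
  }
  model <- new_network_model(
    species = species, params = params, totals = tot,
    reactions = def$reactions, links = def$link_registry,
    units = def$unit_mapping, stimulus = def$stimulus,
    name = def$name %||% "network model")
  if (!is.null(expect_counts)) {
    if (nrow(model$species) != expect_counts[1])
      stop("model has ", nrow(model$species), " state variables, expected ",
           expect_counts[1])
    if (length(model$params) != expect_counts[2])
      stop("model has ", length(model$params), " kinetic parameters, expected ",
           expect_counts[2])
  }
  model
}

#' The shipped full beta-AR network model
#'
#' Convenience constructor: builds the shipped declarative model file and
#' enforces the expected 32 state variables and 105 kinetic parameters, so
#' any transcription error in the model file surfaces as a validation
#' failure. Simulation of this model uses the compiled right-hand side.
#'
#' @return A validated `bar_model` with 32 states and 105 parameters.
#' @export
bar_full_model <- function() {
  build_full_model(bar_model_file(), expect_counts = c(32L, 105L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a network model from parts
#'
#' Low-level constructor used by [build_full_model()] and by the toy-model
#' helpers in the test suite. Normalises reactions (single-target
#' `target`/`sign` form or multi-species `stoich` form for mass-action toys),
#' then validates the assembled model.
#'
#' @param species Data frame with columns `name`, `role`, `pool`, `init`.
#' @param params Named numeric vector of kinetic parameters (> 0).
#' @param totals Named numeric vector of conserved pool totals.
#' @param reactions List of reactions; each has `k` (rate-constant name),
#'   `factors` (list of factor descriptors) and either `target` + `sign` or a
#'   named `stoich` vector.
#' @param links Optional regulatory-link registry.
#' @param units Optional species-to-unit mapping.
#' @param stimulus Optional stimulus description.
#' @param name Model name.
#' @param validate Set `FALSE` to skip validation (internal use).
#' @return A `bar_model` object.
#' @export
new_network_model <- function(species, params, totals = numeric(0),
                              reactions = list(), links = list(),
                              units = NULL, stimulus = NULL,
                              name = "network model", validate = TRUE) {
  reactions <- lapply(reactions, function(r) {
    if (is.null(r$stoich)) {
      r$stoich <- stats::setNames(as.numeric(r$sign), r$target)
    } else {
      r$stoich <- unlist(r$stoich)
    }
    r$factors <- r$factors %||% list()
    r
  })
  model <- structure(list(
    name = name, species = species, params = params, totals = totals,
    reactions = reactions, links = links, units = units,
    stimulus = stimulus,
    controls = c(L = 0, B1conc = 0, B1KI = 1, B2conc = 0, B2KI = 1,
                 clamp_on = 0, clamp_val = 0),
    backend = "interpreted",
    cache = new.env(parent = emptyenv())
  ), class = "bar_model")
  if (validate) validate_network_model(model)
  # the shipped full network has a matching compiled right-hand side
  if (identical(nrow(species), 32L) && identical(length(params), 105L) &&
      identical(species$name[1], "LRb1") && identical(species$name[32], "CNa"))
    model$backend <- "compiled"
  model
}

#' Validate a network model
#'
#' @param model A `bar_model`.
#' @return Invisibly, a list with `n_states` and `n_params` counts.
#' @export
validate_network_model <- function(model) {
  sp <- model$species$name
  if (anyDuplicated(sp))
    stop("duplicate species: ", paste(unique(sp[duplicated(sp)]), collapse = ", "))
  if (length(model$totals) && any(model$totals <= 0))
    stop("non-positive pool totals: ",
         paste(names(model$totals)[model$totals <= 0], collapse = ", "))
  if (any(!is.finite(model$params)) || any(model$params < 0))
    stop("kinetic parameters must be finite and >= 0")
  known <- c(names(model$params), names(model$totals))
  for (r in model$reactions) {
    if (!r$k %in% known)
      stop("reaction ", r$id %||% "?", ": missing parameter '", r$k, "'")
    miss <- setdiff(names(r$stoich), sp)
    if (length(miss))
      stop("reaction ", r$id %||% "?", " targets unknown species: ",
           paste(miss, collapse = ", "), " (dangling reaction)")
    for (f in r$factors) {
      for (fld in c("K", "n", "a")) {
        if (!is.null(f[[fld]]) && is.character(f[[fld]]) && !f[[fld]] %in% known)
          stop("reaction ", r$id %||% "?", ": missing parameter '", f[[fld]], "'")
      }
      if (!is.null(f$var) && !f$var %in% sp)
        stop("reaction ", r$id %||% "?", ": unknown species '", f$var,
             "' (dangling reaction)")
      if (!is.null(f$pool) && !f$pool %in% names(model$totals))
        stop("reaction ", r$id %||% "?", ": unknown pool '", f$pool, "'")
    }
  }
  for (lk in model$links) {
    if (!length(lk$gates))
      stop("link ", lk$name, " gates no parameters")
    miss <- setdiff(unlist(lk$gates), names(model$params))
    if (length(miss))
      stop("link ", lk$name, " gates unknown parameters: ",
           paste(miss, collapse = ", "))
  }
  # stimulus -> ... -> Bcl2 connectivity over the influence graph
  if ("Bcl2" %in% sp) {
    reach <- influence_reachable(model)
    if (!"Bcl2" %in% reach)
      stop("Bcl2 is disconnected from the stimulus")
  }
  invisible(list(n_states = length(sp), n_params = length(model$params)))
}

# species reachable from the stimulus through reaction factor couplings
influence_reachable <- function(model) {
  edges <- influence_edges(model)
  frontier <- unique(edges$to[edges$from == ".stimulus"])
  seen <- frontier
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  seen
}

# directed influence edges (factor species/stimulus -> stoich targets), with
# sign = factor monotonicity * stoich sign; free-pool self terms are skipped
influence_edges <- function(model) {
  from <- character(0); to <- character(0); sign <- numeric(0)
  for (r in model$reactions) {
    for (f in r$factors) {
      src <- NULL; mono <- 1
      if (identical(f$type, "occ")) { src <- ".stimulus"; mono <- 1 }
      else if (!is.null(f$var)) {
        src <- f$var
        mono <- if (identical(f$type, "inh")) -1 else if (identical(f$type, "free")) -1 else 1
      }
      if (is.null(src)) next
      for (tg in names(r$stoich)) {
        if (identical(src, tg)) next
        from <- c(from, src); to <- c(to, tg)
        sign <- c(sign, mono * sign(r$stoich[[tg]]))
      }
    }
  }
  data.frame(from = from, to = to, sign = sign, stringsAsFactors = FALSE)
}

#' @export
print.bar_model <- function(x, ...) {
  cat("<bar_model> ", x$name, "\n", sep = "")
  cat("  states: ", nrow(x$species), "   kinetic parameters: ",
      length(x$params), "\n", sep = "")
  cat("  pools: ", length(x$totals), "   reactions: ", length(x$reactions),
      "   registered links: ", length(x$links), "\n", sep = "")
  cat("  backend: ", x$backend, "\n", sep = "")
  invisible(x)
}

# Named parameter vector in compiled-code order: params, totals, controls.
full_parms_vector <- function(model) {
  c(model$params, model$totals, model$controls)
}

#' Replace kinetic parameter values
#'
#' Returns a copy of the model with the named parameters overridden;
#' cached steady states are invalidated.
#'
#' @param model A `bar_model`.
#' @param new_params Named numeric vector (subset of the model parameters).
#' @return Modified `bar_model`.
#' @export
set_model_params <- function(model, new_params) {
  model$params[names(new_params)] <- new_params
  model$cache <- new.env(parent = emptyenv())
  model
}

set_model_controls <- function(model, ...) {
  ctl <- c(...)
  model$controls[names(ctl)] <- ctl
  model$cache <- new.env(parent = emptyenv())
  model
}

# ---------------------------------------------------------------------------
# Generic interpreted right-hand side (reference implementation; also used
# for toy models and for Newton polishing of steady states).

factor_value <- function(f, y, model, occ) {
  p <- function(x) if (is.character(x)) {
    v <- model$params[x]; if (is.na(v)) model$totals[[x]] else unname(v)
  } else x
  switch(f$type,
    lin  = max(y[[f$var]], 0),
    mm   = { v <- max(y[[f$var]], 0); v / (p(f$K) + v) },
    hill = { v <- max(y[[f$var]], 0); n <- p(f$n); K <- p(f$K)
             if (v <= 0) 0 else v^n / (K^n + v^n) },
    inh  = { a <- if (is.null(f$a)) 1 else p(f$a)
             n <- if (is.null(f$n)) 1 else p(f$n)
             u <- a * max(y[[f$var]], 0); K <- p(f$K)
             if (u <= 0) 1 else K^n / (K^n + u^n) },
    free = model$totals[[f$pool]] - y[[f$var]],
    tot  = model$totals[[f$pool]],
    occ  = occ[[f$receptor]],
    stop("unknown factor type: ", f$type))
}

#' Evaluate the model right-hand side
#'
#' Interpreted evaluation of d(state)/dt from the declarative reaction list.
#' This is the reference implementation against which the compiled
#' right-hand side of the full model is checked.
#'
#' @param model A `bar_model`.
#' @param y Named state vector.
#' @return Named vector of time derivatives.
#' @export
model_rhs <- function(model, y) {
  ctl <- model$controls
  occ <- list(b1 = 0, b2 = 0)
  if ("KL1" %in% names(model$params)) {
    q1 <- ctl[["L"]] / model$params[["KL1"]]
    occ$b1 <- q1 / (1 + q1 + ctl[["B1conc"]] / ctl[["B1KI"]])
  }
  if ("KL2" %in% names(model$params)) {
    q2 <- ctl[["L"]] / model$params[["KL2"]]
    occ$b2 <- q2 / (1 + q2 + ctl[["B2conc"]] / ctl[["B2KI"]])
  }
  yl <- as.list(y)
  if (ctl[["clamp_on"]] > 0.5 && "cAMP" %in% names(yl))
    yl[["cAMP"]] <- ctl[["clamp_val"]]
  dy <- stats::setNames(numeric(length(y)), names(y))
  for (r in model$reactions) {
    k <- model$params[r$k]
    if (is.na(k)) k <- model$totals[[r$k]]
    rate <- unname(k)
    for (f in r$factors) rate <- rate * factor_value(f, yl, model, occ)
    for (tg in names(r$stoich)) dy[tg] <- dy[tg] + r$stoich[[tg]] * rate
  }
  if (ctl[["clamp_on"]] > 0.5 && "cAMP" %in% names(dy)) dy[["cAMP"]] <- 0
  dy
}

# deSolve-compatible interpreted RHS closure
model_rhs_fn <- function(model) {
  spn <- model$species$name
  function(t, y, parms) {
    names(y) <- spn
    list(unname(model_rhs(model, y)))
  }
}
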