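# Classification of dose-response curves as "switching" (rise above basal at
# intermediate doses, fall below basal at the highest dose) and computation
# of the survival range.

#' Classify a dose-response curve as switching or not
#'
#' A curve switches when (i) its maximal fold change over basal reaches
#' `theta_up` at a strictly interior dose of the grid (excluding both
#' endpoints, so monotone curves never qualify) and (ii) the fold change at
#' the maximal dose has dropped to `theta_down` or below. All summary fields
#' are populated whether or not the curve switches.
#'
#' @param curve A `bar_curve` (or list with `doses` and `values`).
#' @param basal Basal readout value (> 0); defaults to the `basal` field of
#'   the curve.
#' @param theta_up Rise threshold on the fold change (default 1.2).
#' @param theta_down Fall threshold on the terminal fold change (default 0.8).
#' @return A `bar_switching` list: `is_switching`, `peak_dose`, `peak_fold`,
#'   `terminal_fold`, `survival_range` (numeric length-2, `NA` when empty)
#'   and the thresholds used.
#' @export
classify_switching <- function(curve, basal = curve$basal,
                               theta_up = 1.2, theta_down = 0.8) {
  if (is.null(basal) || !is.finite(basal) || basal <= 0)
    stop("basal must be a positive number (fold change undefined)")
  doses <- curve$doses; values <- curve$values
  if (!length(doses)) stop("empty curve")
  fold <- values / basal
  ip <- which.max(fold)
  interior <- length(fold) >= 3 && ip > 1 && ip < length(fold)
  is_sw <- interior && fold[ip] >= theta_up && fold[length(fold)] <= theta_down
  sr <- survival_range(curve, basal, theta_up)
  structure(list(
    is_switching = is_sw,
    peak_dose = doses[ip],
    peak_fold = unname(fold[ip]),
    terminal_fold = unname(fold[length(fold)]),
    survival_range = sr,
    theta_up = theta_up, theta_down = theta_down),
    class = "bar_switching")
}

#' @export
print.bar_switching <- function(x, ...) {
  cat("<bar_switching> switching:", x$is_switching, "\n")
  cat("  peak", format(x$peak_fold, digits = 3), "x basal at",
      format(x$peak_dose), "M; terminal",
      format(x$terminal_fold, digits = 3), "x basal\n")
  if (all(is.finite(x$survival_range)))
    cat("  survival range [", format(x$survival_range[1]), ", ",
        format(x$survival_range[2]), "] M\n", sep = "")
  else cat("  survival range: empty\n")
  invisible(x)
}

#' Survival range of a dose-response curve
#'
#' Contiguous dose interval over which the fold change stays at or above
#' `theta_up`, with edges located by linear interpolation in log10(dose).
#' If the threshold is crossed several times, the widest interval (in log
#' dose) is returned and all intervals are attached as attribute
#' `all_intervals`.
#'
#' @inheritParams classify_switching
#' @return Length-2 numeric `c(lower, upper)` in molar, or `c(NA, NA)` when
#'   the threshold is never reached.
#' @export
survival_range <- function(curve, basal = curve$basal, theta_up = 1.2) {
  if (is.null(basal) || !is.finite(basal) || basal <= 0)
    stop("basal must be a positive number (fold change undefined)")
  doses <- curve$doses; fold <- curve$values / basal
  lx <- log10(doses)
  above <- fold >= theta_up
  if (!any(above)) {
    out <- c(NA_real_, NA_real_)
    attr(out, "all_intervals") <- matrix(numeric(0), 0, 2)
    return(out)
  }
  # locate maximal runs of `above`, interpolate the crossing at each edge
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- matrix(NA_real_, sum(r$values), 2); k <- 0
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    k <- k + 1
    i0 <- starts[j]; i1 <- ends[j]
    lo <- if (i0 == 1) lx[1] else {
      # crossing between i0-1 (below) and i0 (above)
      lx[i0 - 1] + (theta_up - fold[i0 - 1]) / (fold[i0] - fold[i0 - 1]) *
        (lx[i0] - lx[i0 - 1])
    }
    hi <- if (i1 == length(fold)) lx[length(lx)] else {
      lx[i1] + (fold[i1] - theta_up) / (fold[i1] - fold[i1 + 1]) *
        (lx[i1 + 1] - lx[i1])
    }
    iv[k, ] <- c(lo, hi)
  }
  widths <- iv[, 2] - iv[, 1]
  best <- which.max(widths)
  out <- 10^iv[best, ]
  attr(out, "all_intervals") <- 10^iv
  out
}
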