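#' Survival curve container
#'
#' A right-continuous step function S(t) on a strictly increasing time grid,
#' with the implicit point S(0) = 1. All model predictions and Kaplan-Meier
#' estimates in the package are represented this way.
#'
#' @param times strictly increasing positive time grid (months).
#' @param surv survival probabilities at `times`; non-increasing, in [0, 1].
#' @return an object of class `survival_curve`.
#' @export
survival_curve <- function(times, surv) {
  stopifnot(length(times) == length(surv))
  if (length(times) > 0) {
    if (any(!is.finite(times)) || any(diff(times) <= 0) || times[1] <= 0) {
      stop("times must be finite, positive and strictly increasing")
    }
    if (any(!is.finite(surv)) || any(surv < -1e-12) || any(surv > 1 + 1e-12)) {
      stop("survival probabilities must lie in [0, 1]")
    }
    if (any(diff(surv) > 1e-10)) stop("survival probabilities must be non-increasing")
    surv <- pmin(pmax(surv, 0), 1)
    surv <- cummin(surv)  # clamp tiny numerical wiggles
  }
  structure(list(times = as.numeric(times), surv = as.numeric(surv)),
            class = "survival_curve")
}

#' Evaluate a survival curve at arbitrary times
#'
#' Step-function (right-continuous) evaluation with S(t) = 1 for t below the
#' first grid point and last-value carried forward beyond the grid.
#'
#' @param curve a `survival_curve`.
#' @param t numeric vector of times.
#' @return numeric vector of survival probabilities.
#' @export
eval_curve <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (length(curve$times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$times)
  out <- c(1, curve$surv)[idx + 1L]
  out
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("<survival_curve> ", length(x$times), " time points",
      if (length(x$times) > 0)
        sprintf(", t in [%.3g, %.3g], S(last) = %.3f",
                x$times[1], x$times[length(x$times)], x$surv[length(x$surv)]),
      "\n", sep = "")
  invisible(x)
}

# Re-express a curve on a new grid (step interpolation). Used to place the two
# counterfactual predictions on a common evaluation grid.
regrid_curve <- function(curve, times) {
  survival_curve(times, eval_curve(curve, times))
}
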