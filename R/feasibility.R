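# Attainable bounds on the eigenvector moments and the convergence map over
# a (v*, s*) target grid. The closed-form bounds follow from the unit-norm
# nonnegative eigenvector convention (derived here, not transcribed):
#   v = 1/n - <x>^2 with <x> in [1/n, 1/sqrt(n)]  =>  v <= (n-1)/n^2
# and the classical extremal population skewness of n numbers,
#   |s| <= (n-2)/sqrt(n-1).

#' Closed-form feasibility bounds
#'
#' @param n Node count (>= 3; for n < 3 the skewness bound degenerates).
#' @return A [FeasibilityBounds-class] with `vMax = (n-1)/n^2` and
#'   `sBound = (n-2)/sqrt(n-1)`.
#' @examples
#' feasibilityBounds(6)   # vMax = 5/36, sBound = 4/sqrt(5)
#' feasibilityBounds(10)  # vMax = 0.09
#' @export
feasibilityBounds <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("feasibility bounds require n >= 3 (the skewness bound is ",
         "degenerate for n < 3)", call. = FALSE)
  new("FeasibilityBounds", n = n,
      vMax = (n - 1) / n^2,
      sBound = (n - 2) / sqrt(n - 1))
}

## half-width of the acceptance band around a target, matching the
## per-metric convergence rule
.toleranceBand <- function(target, criteria) {
  if (abs(target) >= criteria@tolAbs) criteria@tol * abs(target)
  else criteria@tolAbs
}

#' Validate generation criteria against the attainable bounds
#'
#' Returns a character vector of violations (empty when the criteria are
#' admissible) rather than raising. A target is only flagged when its whole
#' acceptance band lies outside the attainable region, so a printed target
#' that abuts a bound within rounding (e.g. \eqn{|s^*| = 1.79} against the
#' \eqn{n = 6} bound \eqn{4/\sqrt 5 \approx 1.7889}) is still admissible,
#' while e.g. \eqn{s^* = 3} is rejected.
#'
#' Checked rules: \eqn{0 \le v^* \le v_{max}}, \eqn{|s^*| \le s_{bound}},
#' and no skewness criterion together with \eqn{v^* = 0} (skewness is
#' undefined for a homogeneous eigenvector).
#'
#' @param criteria A [GenerationCriteria-class].
#' @return Character vector of violation messages (possibly empty).
#' @examples
#' ok <- generationCriteria(10, 20, 0.005, 0.4)
#' validateCriteria(ok)  # character(0)
#' @export
validateCriteria <- function(criteria) {
  stopifnot(is(criteria, "GenerationCriteria"))
  viol <- character(0)
  n <- criteria@n
  if (n >= 3L) {
    b <- feasibilityBounds(n)
    if (criteria@vStar > b@vMax + .toleranceBand(criteria@vStar, criteria))
      viol <- c(viol, sprintf(
        "variance criterion v* = %g exceeds the attainable maximum (n-1)/n^2 = %g for n = %d",
        criteria@vStar, b@vMax, n))
    if (!is.na(criteria@sStar) &&
        abs(criteria@sStar) > b@sBound + .toleranceBand(criteria@sStar, criteria))
      viol <- c(viol, sprintf(
        "skewness criterion |s*| = %g exceeds the extremal bound (n-2)/sqrt(n-1) = %g for n = %d",
        abs(criteria@sStar), b@sBound, n))
  } else if (!is.na(criteria@sStar)) {
    viol <- c(viol, "skewness criterion requires n >= 3")
  }
  if (!is.na(criteria@sStar) && criteria@vStar == 0)
    viol <- c(viol,
      "skewness criterion requested with v* = 0: skewness is undefined for a homogeneous eigenvector")
  viol
}

#' Convergence map over a (v*, s*) grid
#'
#' Runs [generateNetwork()] at every combination of the variance and
#' skewness grids with a shared spectral-radius target, weight box and
#' tolerances, recording convergence and the achieved metrics. Grid points
#' whose criteria violate the attainable bounds are recorded as
#' not-converged with the violation message and no generation is attempted.
#' Per-point seeds are derived deterministically from `seed`, so the whole
#' map is reproducible.
#'
#' @param n Node count.
#' @param rStar Shared target spectral radius.
#' @param vGrid,sGrid Numeric vectors of variance / skewness targets.
#' @param wMin,wMax Weight box.
#' @param tol,tolAbs Convergence tolerances (see
#'   [GenerationCriteria-class]).
#' @param maxOuter Perturbation cap per grid point.
#' @param seed Base RNG seed.
#' @return A [ConvergenceMap-class].
#' @examples
#' m <- feasibilityMap(10, 20, vGrid = 0.005, sGrid = 0.4, seed = 1)
#' mapGrid(m)
#' @export
feasibilityMap <- function(n, rStar, vGrid, sGrid, wMin = 1, wMax = 50,
                           tol = 0.01, tolAbs = 0.01, maxOuter = 100L,
                           seed = 1L) {
  stopifnot(length(vGrid) >= 1, length(sGrid) >= 1)
  pts <- expand.grid(v_star = vGrid, s_star = sGrid,
                     KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(pts))
  for (k in seq_len(nrow(pts))) {
    crit <- generationCriteria(n, rStar = rStar, vStar = pts$v_star[k],
                               sStar = pts$s_star[k], wMin = wMin,
                               wMax = wMax, tol = tol, tolAbs = tolAbs,
                               maxOuter = maxOuter,
                               seed = (as.integer(seed) + 104729L * k) %%
                                 .Machine$integer.max)
    viol <- validateCriteria(crit)
    if (length(viol)) {
      rows[[k]] <- data.frame(
        v_star = pts$v_star[k], s_star = pts$s_star[k], converged = FALSE,
        r_achieved = NA_real_, v_achieved = NA_real_, s_achieved = NA_real_,
        outer_iterations = NA_integer_,
        violation = paste(viol, collapse = "; "))
      next
    }
    res <- generateNetwork(crit)
    rows[[k]] <- data.frame(
      v_star = pts$v_star[k], s_star = pts$s_star[k],
      converged = res@converged,
      r_achieved = res@achieved@r, v_achieved = res@achieved@v,
      s_achieved = res@achieved@s,
      outer_iterations = res@outerIterations, violation = "")
  }
  new("ConvergenceMap", rStar = as.numeric(rStar), n = as.integer(n),
      wMin = as.numeric(wMin), wMax = as.numeric(wMax),
      grid = do.call(rbind, rows))
}

#' Grid of a convergence map
#'
#' @param x A [ConvergenceMap-class].
#' @return The data frame of grid records.
#' @export
mapGrid <- function(x) {
  stopifnot(is(x, "ConvergenceMap"))
  x@grid
}
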