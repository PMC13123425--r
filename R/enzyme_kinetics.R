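#' Simulate a fluorogenic-substrate progress curve
#'
#' Single-exponential substrate-depletion model for a FRET-substrate cleavage
#' assay: `RFU(t) = plateau * (1 - exp(-k t)) + noise`. The early-phase slope
#' (the initial rate) is `plateau * k`. Default sampling is a reading every
#' 2 minutes for 60 minutes.
#'
#' @param plateau Fluorescence at complete substrate conversion (RFU).
#' @param rate_constant First-order rate constant `k` in 1/s.
#' @param times Sampling times in s. Default `seq(0, 3600, by = 120)`.
#' @param noise_sd Gaussian noise SD in RFU. Default 0.
#' @param seed Optional integer seed.
#' @param condition Label stored on the trace (e.g. ligand + concentration).
#'
#' @return A data frame of class `"kinetic_trace"` with columns `time` (s)
#'   and `rfu`, and attribute `condition`.
#' @examples
#' simulate_progress_curve(plateau = 1000, rate_constant = 2e-4, seed = 1)
#' @export
simulate_progress_curve <- function(plateau, rate_constant,
                                    times = seq(0, 3600, by = 120),
                                    noise_sd = 0, seed = NULL,
                                    condition = "") {
  if (plateau <= 0 || rate_constant <= 0) stop("`plateau` and `rate_constant` must be > 0")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  rfu <- plateau * (1 - exp(-rate_constant * times))
  if (noise_sd > 0) rfu <- rfu + stats::rnorm(length(times), 0, noise_sd)
  out <- data.frame(time = times, rfu = rfu)
  attr(out, "condition") <- condition
  class(out) <- c("kinetic_trace", class(out))
  out
}

#' Initial rate of a kinetic progress curve
#'
#' Least-squares slope of fluorescence against time over the early linear
#' window of the progress curve (default: the first 10 minutes, where FRET
#' substrate cleavage is still far from saturation).
#'
#' @param trace A data frame with columns `time` (s) and `rfu`.
#' @param window Length of the initial window in s. Default 600.
#'
#' @return Initial rate in RFU/s.
#' @examples
#' tr <- simulate_progress_curve(1000, 2e-4)
#' initial_rate(tr)
#' @export
initial_rate <- function(trace, window = 600) {
  if (!is.data.frame(trace)) stop("`trace` must be a data frame")
  names(trace)[names(trace) == "time_s"] <- "time"
  if (!all(c("time", "rfu") %in% names(trace)))
    stop("`trace` must have columns `time` and `rfu`")
  sel <- trace$time <= window
  if (sum(sel) < 3L) stop("the initial-rate window must contain at least 3 points")
  unname(stats::coef(stats::lm(rfu ~ time, data = trace[sel, ]))[2])
}

#' Linear standard curve for enzyme activity calibration
#'
#' Fits rate = intercept + slope * [enzyme] through calibration points
#' measured at known enzyme concentrations, and stores the reference
#' concentration that defines 100 percent activity.
#'
#' @param enzyme_conc Known enzyme concentrations (nM), >= 2 values.
#' @param rate Measured initial rates (RFU/s), same length.
#' @param reference_conc Enzyme concentration defining 100 percent relative
#'   activity (nM). Default 12.5 nM, the working protease concentration of
#'   the FRETS assay.
#'
#' @return An object of class `"standard_curve"` with `slope` (RFU/s per nM),
#'   `intercept` (RFU/s), `reference_conc`, and the calibration points.
#' @examples
#' standard_curve(c(0, 6.25, 12.5, 25), c(0, 0.5, 1.0, 2.0))
#' @export
standard_curve <- function(enzyme_conc, rate, reference_conc = 12.5) {
  if (length(enzyme_conc) < 2L || length(rate) != length(enzyme_conc))
    stop("the standard curve needs at least 2 calibration points")
  fit <- stats::lm(rate ~ enzyme_conc)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("standard-curve slope must be > 0 (rate must grow with enzyme concentration)")
  structure(list(slope = slope, intercept = intercept,
                 reference_conc = reference_conc,
                 points = data.frame(enzyme_conc = enzyme_conc, rate = rate)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: rate = %.4g + %.4g * [enzyme] RFU/s (reference %.3g nM)\n",
              x$intercept, x$slope, x$reference_conc))
  invisible(x)
}

#' Relative enzymatic activity from a standard curve
#'
#' Converts a measured initial rate into an enzyme-equivalent concentration
#' via the standard curve, `(rate - intercept) / slope`, and expresses it as
#' a percentage of the curve's reference concentration. Rates below the
#' curve's intercept are clamped to 0 percent with a warning.
#'
#' @param rate Initial rate in RFU/s (vectorised).
#' @param curve A [standard_curve()] object.
#'
#' @return Relative activity in percent.
#' @examples
#' sc <- standard_curve(c(0, 12.5), c(0, 1), reference_conc = 12.5)
#' relative_activity(0.5, sc) # 50
#' @export
relative_activity <- function(rate, curve) {
  if (!inherits(curve, "standard_curve")) stop("`curve` must be a standard_curve")
  equiv <- (rate - curve$intercept) / curve$slope
  if (any(equiv < 0)) {
    warning("rate below the standard-curve intercept: activity clamped to 0%")
    equiv[equiv < 0] <- 0
  }
  100 * equiv / curve$reference_conc
}

#' Fold enhancement of activity across a ligand concentration series
#'
#' Normalises relative activities by the ligand-free (zero-concentration)
#' reference and reports the maximum fold change and the concentration at
#' which it occurs — the summary used to state, e.g., that a mutant ligand
#' doubles protease activity at its most effective concentration.
#'
#' @param activities A data frame with columns `conc` (ligand concentration,
#'   any consistent unit) and `activity` (percent). Must contain a
#'   `conc == 0` row with positive activity.
#'
#' @return A list with `max_fold`, `at_conc`, and `profile` (data frame with
#'   `conc`, `activity`, `fold`).
#' @examples
#' enhancement_profile(data.frame(conc = c(0, 125, 500),
#'                                activity = c(100, 150, 200)))
#' @export
enhancement_profile <- function(activities) {
  if (!is.data.frame(activities) || !all(c("conc", "activity") %in% names(activities)))
    stop("`activities` must be a data frame with columns `conc` and `activity`")
  ref <- activities$activity[activities$conc == 0]
  if (length(ref) == 0L)
    stop("a zero-concentration reference row is required")
  ref <- mean(ref)
  if (!is.finite(ref) || ref <= 0)
    stop("the zero-concentration reference activity must be > 0")
  profile <- activities[order(activities$conc), , drop = FALSE]
  profile$fold <- profile$activity / ref
  imax <- which.max(profile$fold)
  list(max_fold = profile$fold[imax], at_conc = profile$conc[imax],
       profile = profile)
}
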