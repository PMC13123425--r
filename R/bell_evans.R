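#' Bell-Evans unfolding rate at a given force
#'
#' `k(F) = k0 * exp(gamma * F / kBT)`: the unfolding rate grows exponentially
#' with applied force, with the barrier position `gamma` setting the force
#' sensitivity.
#'
#' @param force Force in pN; vectorised. Must be >= 0.
#' @param params A [bell_evans_params()] object.
#'
#' @return Unfolding rate in 1/s, same length as `force`.
#' @examples
#' bell_rate(0, bell_evans_params(0.15, 0.71)) # 0.15
#' @export
bell_rate <- function(force, params) {
  params <- as_bell_evans_params(params)
  if (!is.numeric(force) || any(!is.finite(force))) stop("`force` must be finite numeric")
  if (any(force < 0)) stop("force must be >= 0")
  params$k0 * exp(params$gamma * force / params$kBT)
}

#' Most probable rupture force under a constant loading rate
#'
#' Evans-Ritchie prediction for the mode of the rupture-force distribution of
#' a Bell-Evans bond loaded at constant rate `r`:
#' `F* = (kBT / gamma) * log(gamma * r / (k0 * kBT))`.
#' `F*` is affine in `log(r)` with slope `kBT / gamma`. When the logarithm's
#' argument is <= 1 (very slow loading), the mode of the distribution sits at
#' zero force; the function then returns 0 with a warning rather than a
#' negative force.
#'
#' @param loading_rate Loading rate in pN/s; vectorised. Must be > 0.
#' @param params A [bell_evans_params()] object with `k0 > 0` and `gamma > 0`.
#'
#' @return Most probable rupture force in pN.
#' @examples
#' evans_ritchie_force(10, bell_evans_params(0.15, 0.71)) # ~14.15 pN
#' @export
evans_ritchie_force <- function(loading_rate, params) {
  params <- as_bell_evans_params(params)
  if (!is.numeric(loading_rate) || any(!is.finite(loading_rate)))
    stop("`loading_rate` must be finite numeric")
  if (any(loading_rate <= 0)) stop("loading rate must be > 0")
  if (params$gamma == 0 || params$k0 == 0)
    stop("Evans-Ritchie force requires k0 > 0 and gamma > 0")
  arg <- params$gamma * loading_rate / (params$k0 * params$kBT)
  f <- (params$kBT / params$gamma) * log(arg)
  if (any(arg <= 1)) {
    warning("loading rate at or below k0*kBT/gamma: most probable force clamped to 0")
    f[arg <= 1] <- 0
  }
  f
}

#' Fit the Bell-Evans model to most-probable-force vs loading-rate data
#'
#' Estimates the unstressed unfolding rate `k0` and barrier position `gamma`
#' from pairs of loading rate and most probable rupture force. The primary
#' route is nonlinear least squares of the Evans-Ritchie relation; starting
#' values come from the equivalent linear regression of force on
#' `log(loading rate)` (slope `kBT/gamma`), and the two routes agree exactly
#' on noiseless data.
#'
#' @param points A data frame with numeric columns `loading_rate` (pN/s,
#'   all > 0) and `force` (pN); at least 2 rows at distinct loading rates.
#' @param kBT Thermal energy in pN nm, held fixed.
#' @param method `"nls"` (default) or `"linear"` (regression on `log(r)` with
#'   back-transformation, no refinement).
#'
#' @return An object of class `"bell_evans_fit"`: a list with `params` (a
#'   [bell_evans_params()] object), `se` (asymptotic standard errors for `k0`
#'   and `gamma`), `residual_sd`, `n`, `method`.
#' @examples
#' truth <- bell_evans_params(0.15, 0.71)
#' r <- c(1, 3, 10, 30, 100)
#' pts <- data.frame(loading_rate = r, force = evans_ritchie_force(r, truth))
#' fit_bell_evans(pts)
#' @export
fit_bell_evans <- function(points, kBT = kBT_25C, method = c("nls", "linear")) {
  method <- match.arg(method)
  if (!is.data.frame(points))
    stop("`points` must be a data frame with columns `loading_rate` and `force`")
  names(points)[names(points) == "loading_rate_pNs"] <- "loading_rate"
  names(points)[names(points) == "force_pN"] <- "force"
  if (!all(c("loading_rate", "force") %in% names(points)))
    stop("`points` must have columns `loading_rate` and `force`")
  r <- points$loading_rate
  f <- points$force
  if (any(!is.finite(r)) || any(!is.finite(f))) stop("rate points must be finite")
  if (any(r <= 0)) stop("loading rates must be > 0")
  if (any(f < 0)) stop("most probable forces must be >= 0")
  if (length(unique(r)) < 2L)
    stop("Bell-Evans fitting needs at least 2 distinct loading rates")

  lin <- stats::lm(f ~ log(r))
  slope <- unname(stats::coef(lin)[2])
  intercept <- unname(stats::coef(lin)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("Bell-Evans fit failed: force does not increase with log(loading rate)")
  gamma0 <- kBT / slope
  k0_0 <- (gamma0 / kBT) * exp(-intercept * gamma0 / kBT)

  if (method == "linear" || length(r) == 2L) {
    # two points determine the line exactly; skip NLS refinement
    se <- c(k0 = NA_real_, gamma = NA_real_)
    if (length(r) > 2L) {
      # delta-method errors from the regression coefficients
      V <- suppressWarnings(stats::vcov(lin))
      g_b <- -kBT / slope^2                                  # dgamma/dslope
      se_gamma <- sqrt(V[2, 2]) * abs(g_b)
      # k0 = exp(-intercept/slope) / slope
      dk_da <- -k0_0 / slope
      dk_db <- k0_0 * (intercept / slope^2 - 1 / slope)
      se_k0 <- sqrt(dk_da^2 * V[1, 1] + dk_db^2 * V[2, 2] + 2 * dk_da * dk_db * V[1, 2])
      se <- c(k0 = se_k0, gamma = se_gamma)
    }
    return(structure(list(
      params = bell_evans_params(k0 = k0_0, gamma = gamma0, kBT = kBT),
      se = se,
      residual_sd = if (length(r) > 2L) stats::sigma(lin) else 0,
      n = length(r),
      method = "linear",
      fit = lin
    ), class = "bell_evans_fit"))
  }

  er <- function(r, lk0, g) (kBT / g) * (log(g * r / kBT) - lk0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      f ~ er(r, lk0, g),
      start = list(lk0 = log(k0_0), g = gamma0),
      lower = c(lk0 = -Inf, g = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("Bell-Evans fit did not converge: ", conditionMessage(e))
  )
  est <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))$coefficients
  k0_hat <- exp(unname(est["lk0"]))
  se <- c(k0 = k0_hat * unname(sm["lk0", "Std. Error"]),  # delta method on log scale
          gamma = unname(sm["g", "Std. Error"]))
  structure(list(
    params = bell_evans_params(k0 = k0_hat, gamma = unname(est["g"]), kBT = kBT),
    se = se,
    residual_sd = stats::sigma(fit),
    n = length(r),
    method = "nls",
    fit = fit
  ), class = "bell_evans_fit")
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat(sprintf("Bell-Evans fit (%s)\n", x$method))
  cat(sprintf("  k0    = %.4g +/- %.3g 1/s\n", x$params$k0, x$se["k0"]))
  cat(sprintf("  gamma = %.4g +/- %.3g nm\n", x$params$gamma, x$se["gamma"]))
  cat(sprintf("  kBT = %g pN nm (fixed), n = %d, residual sd = %.3g pN\n",
              x$params$kBT, x$n, x$residual_sd))
  invisible(x)
}

#' @export
coef.bell_evans_fit <- function(object, ...) {
  c(k0 = object$params$k0, gamma = object$params$gamma)
}

#' Force at which two Bell-Evans unfolding-rate curves cross
#'
#' Solves `k0_a * exp(gamma_a F / kBT) = k0_b * exp(gamma_b F / kBT)` in
#' closed form: `F = kBT * log(k0_a / k0_b) / (gamma_b - gamma_a)`. Below the
#' crossover the parameter set with the smaller zero-force rate is the more
#' stable (slower-unfolding) state; above it the order flips. The value is
#' returned signed: a negative crossover means the curves only cross at an
#' unphysical (negative) force.
#'
#' @param params_a,params_b [bell_evans_params()] objects with `k0 > 0` and
#'   the same `kBT`.
#'
#' @return Crossover force in pN (signed).
#' @examples
#' a <- bell_evans_params(0.15, 0.71)   # domain alone
#' b <- bell_evans_params(0.017, 1.88)  # ligand-bound
#' crossover_force(a, b) # ~7.66 pN
#' @export
crossover_force <- function(params_a, params_b) {
  a <- as_bell_evans_params(params_a)
  b <- as_bell_evans_params(params_b)
  if (a$kBT != b$kBT)
    stop("the two parameter sets must share the same kBT")
  if (a$k0 <= 0 || b$k0 <= 0)
    stop("crossover requires k0 > 0 in both parameter sets")
  if (a$gamma == b$gamma)
    stop("degenerate parameters: equal barrier positions give parallel rate curves")
  a$kBT * log(a$k0 / b$k0) / (b$gamma - a$gamma)
}

#' Force-dependent stability ratio of two Bell-Evans states
#'
#' Ratio of the ligand-bound unfolding rate to the reference unfolding rate
#' over a grid of forces. Values below 1 mean the bound state unfolds more
#' slowly (is stabilized) at that force; values above 1 mean it is
#' destabilized. The ratio equals 1 exactly at [crossover_force()].
#'
#' @param force_grid Numeric vector of forces in pN, all >= 0, non-empty.
#' @param reference,bound [bell_evans_params()] objects sharing `kBT`.
#'
#' @return A data frame with columns `force` (pN) and `rate_ratio`
#'   (`bell_rate(F, bound) / bell_rate(F, reference)`).
#' @examples
#' stability_profile(0:15, bell_evans_params(0.15, 0.71),
#'                   bell_evans_params(0.017, 1.88))
#' @export
stability_profile <- function(force_grid, reference, bound) {
  reference <- as_bell_evans_params(reference)
  bound <- as_bell_evans_params(bound)
  if (length(force_grid) == 0L) stop("`force_grid` must be non-empty")
  if (reference$kBT != bound$kBT)
    stop("the two parameter sets must share the same kBT")
  data.frame(
    force = force_grid,
    rate_ratio = bell_rate(force_grid, bound) / bell_rate(force_grid, reference)
  )
}
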