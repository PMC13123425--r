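#' Serial-dilution concentration schedule
#'
#' Concentrations of a geometric serial dilution: `steps + 1` values starting
#' at `top`, each subsequent one divided by `factor`. The default 15-step
#' 2-fold schedule ends at `top / 2^15` and is the standard layout of an MST
#' binding titration.
#'
#' @param top Highest concentration (molar), > 0.
#' @param steps Number of dilution steps, >= 0. Default 15.
#' @param factor Dilution factor per step, > 1. Default 2.
#'
#' @return Numeric vector of `steps + 1` concentrations, strictly decreasing.
#' @examples
#' serial_dilution(1000e-9) # 16 values, last = 1000e-9 / 32768
#' @export
serial_dilution <- function(top, steps = 15L, factor = 2) {
  if (!is.numeric(top) || length(top) != 1L || !is.finite(top) || top <= 0)
    stop("`top` concentration must be a single value > 0")
  if (steps < 0 || steps != round(steps)) stop("`steps` must be a non-negative integer")
  if (factor <= 1) stop("`factor` must be > 1")
  top / factor^(0:steps)
}

#' Hill-model dose-response signal
#'
#' `S(c) = baseline + amplitude * c^n / (ec50^n + c^n)`: baseline at zero
#' concentration, `baseline + amplitude` at saturation, half-maximal at
#' `c = ec50`.
#'
#' @param conc Ligand concentration (molar); vectorised, >= 0.
#' @param ec50 Half-maximal concentration (molar), > 0.
#' @param hill_n Hill coefficient, > 0. Default 1.
#' @param amplitude Signal change at saturation. Default 1.
#' @param baseline Signal at zero concentration. Default 0.
#'
#' @return Signal, same length as `conc`.
#' @examples
#' hill_response(6.1e-9, ec50 = 6.1e-9) # half-maximal: 0.5
#' @export
hill_response <- function(conc, ec50, hill_n = 1, amplitude = 1, baseline = 0) {
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (ec50 <= 0) stop("`ec50` must be > 0")
  if (hill_n <= 0) stop("`hill_n` must be > 0")
  cn <- conc^hill_n
  baseline + amplitude * cn / (ec50^hill_n + cn)
}

#' Simulate an MST-style binding titration
#'
#' Evaluates the Hill model on a serial-dilution schedule and adds i.i.d.
#' Gaussian noise, producing the normalized dose-response series an MST
#' binding experiment yields.
#'
#' @param ec50 True half-maximal concentration (molar).
#' @param hill_n True Hill coefficient. Default 1.
#' @param top Top concentration (molar). Default 500 nM, a typical titration
#'   ceiling for plasma-protein interactions.
#' @param steps,factor Dilution schedule, see [serial_dilution()].
#' @param amplitude,baseline Signal parameters, see [hill_response()].
#' @param noise_sd Gaussian noise SD in signal units. Default 0.
#' @param seed Optional integer seed.
#' @param replicate_id,target_label Provenance strings stored on the series.
#'
#' @return A data frame of class `"titration_series"` with columns `conc`
#'   (molar, descending) and `signal`, plus attributes `replicate_id` and
#'   `target_label`.
#' @examples
#' simulate_titration(ec50 = 6.1e-9, noise_sd = 0.02, seed = 3)
#' @export
simulate_titration <- function(ec50, hill_n = 1, top = 500e-9, steps = 15L,
                               factor = 2, amplitude = 1, baseline = 0,
                               noise_sd = 0, seed = NULL,
                               replicate_id = "rep_1", target_label = "") {
  conc <- serial_dilution(top, steps, factor)
  if (!is.null(seed)) set.seed(seed)
  signal <- hill_response(conc, ec50, hill_n, amplitude, baseline)
  if (noise_sd > 0) signal <- signal + stats::rnorm(length(conc), 0, noise_sd)
  out <- data.frame(conc = conc, signal = signal)
  attr(out, "replicate_id") <- replicate_id
  attr(out, "target_label") <- target_label
  class(out) <- c("titration_series", class(out))
  out
}

#' Fit the Hill model to a binding titration
#'
#' Nonlinear least squares of the Hill dose-response curve, estimating
#' baseline, amplitude, EC50 (log-parameterised to stay positive) and the
#' Hill coefficient (bounded to `[0.3, 4]`). A series is flagged
#' `no_binding` when the fitted signal change across the measured
#' concentration range is smaller than 3 times the residual SD — the dose
#' response is then indistinguishable from noise, as for a fragment the
#' ligand does not bind. The fitted EC50 is the
#' Kd-equivalent affinity when the Hill coefficient is close to 1.
#'
#' @param series A data frame with columns `conc` (molar, > 0) and `signal`;
#'   at least 6 points spanning more than 2 decades of concentration.
#'
#' @return An object of class `"hill_fit"`: a list with `ec50`, `hill_n`,
#'   `amplitude`, `baseline`, `se` (named standard errors), `residual_sd`,
#'   `converged`, `no_binding`, `n`.
#' @examples
#' ts <- simulate_titration(ec50 = 6.1e-9, noise_sd = 0.02, seed = 3)
#' fit_hill(ts)
#' @export
fit_hill <- function(series) {
  if (!is.data.frame(series)) stop("`series` must be a data frame")
  names(series)[names(series) == "conc_M"] <- "conc"
  if (!all(c("conc", "signal") %in% names(series)))
    stop("`series` must have columns `conc` and `signal`")
  conc <- series$conc
  sig <- series$signal
  if (any(!is.finite(conc)) || any(!is.finite(sig))) stop("titration values must be finite")
  if (any(conc <= 0)) stop("concentrations must be > 0")
  if (length(conc) < 6L) stop("Hill fitting needs at least 6 points")
  if (log10(max(conc) / min(conc)) <= 2)
    stop("titration must span more than 2 decades of concentration")

  b0 <- min(sig)
  A0 <- max(sig) - min(sig)
  half <- b0 + A0 / 2
  above <- conc[sig >= half]
  e0 <- if (length(above) > 0) min(above) else exp(mean(log(range(conc))))
  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        sig ~ b + A * conc^n / (exp(le * n) + conc^n),
        start = start,
        lower = c(b = -Inf, A = 0, le = log(min(conc)) - 7, n = 0.3),
        upper = c(b = Inf, A = Inf, le = log(max(conc)) + 7, n = 4),
        control = minpack.lm::nls.lm.control(maxiter = 1000)
      ),
      error = function(e) NULL
    )
  }
  fit <- try_fit(list(b = b0, A = max(A0, 1e-6), le = log(e0), n = 1))
  if (is.null(fit)) {
    # a start sitting exactly on a zero-residual solution can give LM a
    # singular gradient; a perturbed restart resolves it
    fit <- try_fit(list(b = b0, A = max(1.3 * A0, 1e-6), le = log(e0) + 0.5,
                        n = 1.2))
  }
  if (is.null(fit)) {
    # irrecoverable fit (e.g. perfectly flat series): classify from the data
    rsd <- stats::sd(sig)
    return(structure(list(ec50 = NA_real_, hill_n = NA_real_,
                          amplitude = 0, baseline = mean(sig),
                          se = c(ec50 = NA_real_, hill_n = NA_real_,
                                 amplitude = NA_real_, baseline = NA_real_),
                          residual_sd = rsd, converged = FALSE,
                          no_binding = TRUE, n = length(conc)),
                     class = "hill_fit"))
  }
  est <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))$coefficients
  ec50 <- exp(unname(est["le"]))
  rsd <- stats::sigma(fit)
  amplitude <- unname(est["A"])
  # signal change the fit predicts across the measured concentration range;
  # a runaway EC50 outside the range leaves this near zero even if the
  # asymptotic amplitude is large
  nh <- unname(est["n"])
  phi <- function(cc) cc^nh / (ec50^nh + cc^nh)
  observable_span <- amplitude * abs(phi(max(conc)) - phi(min(conc)))
  no_binding <- observable_span < 3 * rsd
  structure(list(
    ec50 = ec50,
    hill_n = unname(est["n"]),
    amplitude = amplitude,
    baseline = unname(est["b"]),
    se = c(ec50 = ec50 * unname(sm["le", "Std. Error"]),
           hill_n = unname(sm["n", "Std. Error"]),
           amplitude = unname(sm["A", "Std. Error"]),
           baseline = unname(sm["b", "Std. Error"])),
    residual_sd = rsd,
    converged = TRUE,
    no_binding = no_binding,
    n = length(conc)
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$no_binding) {
    cat(sprintf("Hill fit: no binding (amplitude %.3g < 3 x residual sd %.3g), n = %d\n",
                x$amplitude, x$residual_sd, x$n))
  } else {
    cat("Hill dose-response fit\n")
    cat(sprintf("  EC50 (Kd-equivalent) = %.3g +/- %.2g M\n", x$ec50, x$se["ec50"]))
    cat(sprintf("  Hill n = %.3g +/- %.2g\n", x$hill_n, x$se["hill_n"]))
    cat(sprintf("  amplitude = %.3g, baseline = %.3g, residual sd = %.3g, n = %d\n",
                x$amplitude, x$baseline, x$residual_sd, x$n))
  }
  invisible(x)
}

#' Fold change in binding affinity
#'
#' Ratio of two dissociation constants, `kd_wildtype / kd_mutant`, rounded to
#' one decimal — the conventional "fold of affinity change" comparing a
#' mutant ligand with the wild type (values above 1 mean the mutant binds
#' more tightly).
#'
#' @param kd_wildtype,kd_mutant Dissociation constants (molar), both > 0.
#'
#' @return Fold change, rounded to 1 decimal.
#' @examples
#' fold_affinity_change(6.1e-9, 2.3e-9) # 2.7
#' @export
fold_affinity_change <- function(kd_wildtype, kd_mutant) {
  if (!is.numeric(kd_wildtype) || !is.numeric(kd_mutant) ||
      any(!is.finite(kd_wildtype)) || any(!is.finite(kd_mutant)) ||
      any(kd_wildtype <= 0) || any(kd_mutant <= 0))
    stop("both dissociation constants must be finite and > 0")
  round(kd_wildtype / kd_mutant, 1)
}
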