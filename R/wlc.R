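#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation formula for the entropic force of a worm-like
#' chain stretched to end-to-end extension `x`:
#' `F = (kBT / Lp) * (1/4 * (1 - x/Lc)^-2 - 1/4 + x/Lc)`.
#' The force is zero at zero extension, strictly increasing, and diverges as
#' the extension approaches the contour length.
#'
#' @param extension Extension in nm; vectorised. Must satisfy
#'   `0 <= extension < Lc`.
#' @param params A [wlc_params()] object.
#'
#' @return Force in pN, same length as `extension`.
#' @examples
#' p <- wlc_params(Lc = 40, Lp = 0.38)
#' wlc_force(20, p) # 13.53 pN
#' @export
wlc_force <- function(extension, params) {
  params <- as_wlc_params(params)
  if (!is.numeric(extension) || length(extension) == 0L)
    stop("`extension` must be a non-empty numeric vector")
  if (any(!is.finite(extension))) stop("`extension` must be finite")
  if (any(extension < 0)) stop("extension must be >= 0")
  if (any(extension >= params$Lc))
    stop(sprintf("extension must be below the contour length (Lc = %g nm)", params$Lc))
  phi <- extension / params$Lc
  (params$kBT / params$Lp) * (0.25 * (1 - phi)^-2 - 0.25 + phi)
}

#' Worm-like chain extension at a given force
#'
#' Numerical inverse of [wlc_force()], computed by bracketed bisection on
#' `[0, Lc * (1 - 1e-6)]`. The Marko-Siggia force is strictly monotone in
#' extension, so the bisection always converges; iteration stops when the
#' force residual is below `1e-12` relative.
#'
#' @param force Force in pN; vectorised. Must be >= 0.
#' @param params A [wlc_params()] object.
#'
#' @return Extension in nm, in `[0, Lc)`, same length as `force`.
#' @examples
#' p <- wlc_params(Lc = 40, Lp = 0.38)
#' wlc_extension(13.53, p) # ~20 nm
#' @export
wlc_extension <- function(force, params) {
  params <- as_wlc_params(params)
  if (!is.numeric(force) || length(force) == 0L)
    stop("`force` must be a non-empty numeric vector")
  if (any(!is.finite(force))) stop("`force` must be finite")
  if (any(force < 0)) stop("force must be >= 0")
  Lc <- params$Lc
  lo <- rep(0, length(force))
  hi <- rep(Lc * (1 - 1e-6), length(force))
  # force at the upper bracket is ~kBT/(4 Lp 1e-12): astronomically larger
  # than any physical pulling force, so the root is always bracketed
  tol <- 1e-12 * pmax(force, 1)
  for (i in seq_len(200L)) {
    mid <- 0.5 * (lo + hi)
    fm <- wlc_force(mid, params)
    too_low <- fm < force
    lo[too_low] <- mid[too_low]
    hi[!too_low] <- mid[!too_low]
    if (all(abs(fm - force) <= tol)) break
  }
  out <- 0.5 * (lo + hi)
  out[force == 0] <- 0
  out
}

#' Fit the worm-like chain model to force-extension data
#'
#' Nonlinear least squares of the Marko-Siggia worm-like chain, with the
#' thermal energy held fixed. The model is fitted as extension on force
#' (`x = Lc * phi(F; Lp)`, where `phi` is the fractional extension solving
#' the Marko-Siggia relation): measurement noise in pulling data lives
#' predominantly in the extension channel, and this orientation keeps the
#' estimates free of errors-in-variables bias. Contour length and
#' persistence length are estimated jointly unless `Lp` is supplied, in
#' which case only the contour length is free (useful when the persistence
#' length is already known from a reference condition).
#'
#' @param points A data frame with numeric columns `extension` (nm) and
#'   `force` (pN); at least 4 rows.
#' @param kBT Thermal energy in pN nm, held fixed during the fit.
#' @param initial_guess Optional named list or vector with elements `Lc`
#'   and/or `Lp`. Defaults: `Lc = 1.05 * max(extension)`, `Lp = 0.4` nm.
#' @param Lp Optional fixed persistence length in nm. When given, `Lp` is not
#'   estimated.
#'
#' @return An object of class `"wlc_fit"`: a list with `params` (a
#'   [wlc_params()] object holding the estimates), `se` (asymptotic standard
#'   errors from the Jacobian), `residual_sd` (nm), `n`, and the underlying
#'   `nls`-type fit in `fit`.
#' @examples
#' p <- wlc_params(Lc = 55.3, Lp = 0.28)
#' f <- seq(2, 20, length.out = 30)
#' pts <- data.frame(extension = wlc_extension(f, p), force = f)
#' fit_wlc(pts)
#' @export
fit_wlc <- function(points, kBT = kBT_25C, initial_guess = NULL, Lp = NULL) {
  points <- validate_force_extension(points)
  n_par <- if (is.null(Lp)) 2L else 1L
  if (nrow(points) < 4L)
    stop(sprintf("WLC fitting needs at least 4 points (%d supplied, %d parameters)",
                 nrow(points), n_par))
  x <- points$extension
  f <- points$force
  if (any(f <= 0))
    stop("WLC fitting needs strictly positive forces")
  start_Lc <- 1.05 * max(x)
  start_Lp <- 0.4
  if (!is.null(initial_guess)) {
    ig <- as.list(initial_guess)
    if (!is.null(ig$Lc)) start_Lc <- ig$Lc
    if (!is.null(ig$Lp)) start_Lp <- ig$Lp
  }
  # fractional extension at force f: inverse Marko-Siggia with unit Lc
  phi <- function(f, Lp) wlc_extension(f, wlc_params(1, Lp, kBT))
  fit <- tryCatch(
    if (is.null(Lp)) {
      minpack.lm::nlsLM(
        x ~ Lc * phi(f, Lp),
        start = list(Lc = start_Lc, Lp = start_Lp),
        lower = c(Lc = 1e-6, Lp = 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    } else {
      Lp_fixed <- Lp
      minpack.lm::nlsLM(
        x ~ Lc * phi(f, Lp_fixed),
        start = list(Lc = start_Lc),
        lower = c(Lc = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    },
    error = function(e) stop("WLC fit did not converge: ", conditionMessage(e))
  )
  est <- stats::coef(fit)
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  Lp_hat <- if (is.null(Lp)) unname(est["Lp"]) else Lp
  se_out <- c(Lc = unname(se["Lc"]),
              Lp = if (is.null(Lp)) unname(se["Lp"]) else NA_real_)
  structure(list(
    params = wlc_params(Lc = unname(est["Lc"]), Lp = Lp_hat, kBT = kBT),
    se = se_out,
    residual_sd = stats::sigma(fit),
    n = nrow(points),
    Lp_fixed = !is.null(Lp),
    fit = fit
  ), class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat("Worm-like chain fit (Marko-Siggia)\n")
  cat(sprintf("  Lc = %.4g +/- %.3g nm\n", x$params$Lc, x$se["Lc"]))
  if (x$Lp_fixed) {
    cat(sprintf("  Lp = %.4g nm (fixed)\n", x$params$Lp))
  } else {
    cat(sprintf("  Lp = %.4g +/- %.3g nm\n", x$params$Lp, x$se["Lp"]))
  }
  cat(sprintf("  kBT = %g pN nm (fixed), n = %d, residual sd = %.3g nm\n",
              x$params$kBT, x$n, x$residual_sd))
  invisible(x)
}

#' @export
coef.wlc_fit <- function(object, ...) {
  c(Lc = object$params$Lc, Lp = object$params$Lp)
}

validate_force_extension <- function(points) {
  if (!is.data.frame(points))
    stop("`points` must be a data frame with columns `extension` and `force`")
  # accept the on-disk column names as a convenience
  names(points)[names(points) == "extension_nm"] <- "extension"
  names(points)[names(points) == "force_pN"] <- "force"
  if (!all(c("extension", "force") %in% names(points)))
    stop("`points` must have columns `extension` and `force`")
  if (any(!is.finite(points$extension)) || any(!is.finite(points$force)))
    stop("force-extension points must be finite")
  if (any(points$extension < 0) || any(points$force < 0))
    stop("force and extension must be >= 0")
  points
}
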