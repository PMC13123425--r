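#' Thermal energy at 25 degrees Celsius
#'
#' kB * T at 25 C in piconewton-nanometres. All assays in the package's
#' intended use case (optical-tweezer pulling, MST titration, FRETS kinetics)
#' are run at 25 C, so this is the default thermal energy throughout.
#'
#' @format A length-one numeric, 4.114 pN nm.
#' @export
kBT_25C <- 4.114

#' Worm-like chain parameters
#'
#' Container for the two elastic parameters of the worm-like chain (WLC)
#' polymer model plus the thermal energy at which they apply.
#'
#' @param Lc Contour length in nm (maximum end-to-end extension). Must be > 0.
#' @param Lp Persistence length in nm (bending stiffness length scale).
#'   Must be > 0.
#' @param kBT Thermal energy in pN nm. Defaults to [kBT_25C].
#'
#' @return An object of class `"wlc_params"`: a list with elements `Lc`,
#'   `Lp`, `kBT`.
#' @seealso [wlc_force()], [wlc_extension()], [fit_wlc()]
#' @examples
#' wlc_params(Lc = 55.3, Lp = 0.28)
#' @export
wlc_params <- function(Lc, Lp, kBT = kBT_25C) {
  stopifnot(is.numeric(Lc), length(Lc) == 1L,
            is.numeric(Lp), length(Lp) == 1L,
            is.numeric(kBT), length(kBT) == 1L)
  if (!is.finite(Lc) || Lc <= 0) stop("contour length `Lc` must be finite and > 0")
  if (!is.finite(Lp) || Lp <= 0) stop("persistence length `Lp` must be finite and > 0")
  if (!is.finite(kBT) || kBT <= 0) stop("thermal energy `kBT` must be finite and > 0")
  structure(list(Lc = Lc, Lp = Lp, kBT = kBT), class = "wlc_params")
}

#' @export
print.wlc_params <- function(x, ...) {
  cat(sprintf("Worm-like chain: Lc = %g nm, Lp = %g nm (kBT = %g pN nm)\n",
              x$Lc, x$Lp, x$kBT))
  invisible(x)
}

#' Bell-Evans unfolding-kinetics parameters
#'
#' Container for the Bell-Evans model of force-accelerated unfolding,
#' `k(F) = k0 * exp(gamma * F / kBT)`.
#'
#' @param k0 Unstressed (zero-force) unfolding rate in 1/s. Must be >= 0.
#' @param gamma Energy-barrier position (distance to the transition state)
#'   in nm. Must be >= 0. It sets how steeply the unfolding rate grows with
#'   force.
#' @param kBT Thermal energy in pN nm. Defaults to [kBT_25C].
#'
#' @return An object of class `"bell_evans_params"`: a list with elements
#'   `k0`, `gamma`, `kBT`.
#' @seealso [bell_rate()], [evans_ritchie_force()], [fit_bell_evans()],
#'   [crossover_force()]
#' @examples
#' bell_evans_params(k0 = 0.15, gamma = 0.71)
#' @export
bell_evans_params <- function(k0, gamma, kBT = kBT_25C) {
  stopifnot(is.numeric(k0), length(k0) == 1L,
            is.numeric(gamma), length(gamma) == 1L,
            is.numeric(kBT), length(kBT) == 1L)
  if (!is.finite(k0) || k0 < 0) stop("unstressed rate `k0` must be finite and >= 0")
  if (!is.finite(gamma) || gamma < 0) stop("barrier position `gamma` must be finite and >= 0")
  if (!is.finite(kBT) || kBT <= 0) stop("thermal energy `kBT` must be finite and > 0")
  structure(list(k0 = k0, gamma = gamma, kBT = kBT), class = "bell_evans_params")
}

#' @export
print.bell_evans_params <- function(x, ...) {
  cat(sprintf("Bell-Evans kinetics: k0 = %g 1/s, gamma = %g nm (kBT = %g pN nm)\n",
              x$k0, x$gamma, x$kBT))
  invisible(x)
}

as_wlc_params <- function(x) {
  if (inherits(x, "wlc_params")) return(x)
  stop("expected a `wlc_params` object; see `wlc_params()`")
}

as_bell_evans_params <- function(x) {
  if (inherits(x, "bell_evans_params")) return(x)
  stop("expected a `bell_evans_params` object; see `bell_evans_params()`")
}
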