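#' Define a sequential unfolding pathway
#'
#' Describes a protein that unfolds through one or more sequential
#' transitions under force. Each transition releases a contour-length
#' increment (the unfolded polypeptide added to the tether) and is governed
#' by its own Bell-Evans kinetics. A single-increment pathway is the
#' classical two-state unfolder; two increments give a three-state,
#' two-step pathway of the kind seen when a bound ligand splits one long
#' unfolding event into two shorter ones.
#'
#' @param increments Numeric vector of contour-length increments in nm, all
#'   > 0, one per transition, in unfolding order. Their sum is the
#'   fully-unfolded contour-length gain.
#' @param kinetics A single [bell_evans_params()] object (recycled) or a list
#'   of one per transition.
#' @param Lp Persistence length in nm of the unfolded polypeptide chain.
#'   Default 0.28 nm.
#' @param kBT Thermal energy in pN nm.
#' @param folded_Lc Contour length in nm of the tether (DNA handle plus
#'   folded protein) before any unfolding. Default 800 nm, a typical
#'   kilobase-scale DNA handle construct.
#' @param Lp_handle Persistence length of the tether in nm. Default 45 nm
#'   (double-stranded DNA), which makes the handle nearly inextensible over
#'   the 8-20 pN rupture band.
#'
#' @details The molecular extension is modelled as the sum of two worm-like
#' chains in series at common force: the fixed-`Lc` handle and the unfolded
#' polypeptide, whose contour length grows by one increment per rupture. The
#' bead-handle geometry is not mechanically resolved because only rupture
#' forces and extension jumps feed the downstream fits.
#'
#' @return An object of class `"unfolding_pathway"`.
#' @examples
#' # one-step unfolder with the kinetics and length of an A2-like domain
#' unfolding_pathway(55.3, bell_evans_params(0.15, 0.71))
#' @export
unfolding_pathway <- function(increments, kinetics, Lp = 0.28, kBT = kBT_25C,
                              folded_Lc = 800, Lp_handle = 45) {
  if (!is.numeric(increments) || length(increments) < 1L)
    stop("a pathway needs at least one contour-length increment")
  if (any(!is.finite(increments)) || any(increments <= 0))
    stop("all contour-length increments must be finite and > 0")
  if (inherits(kinetics, "bell_evans_params")) {
    kinetics <- rep(list(kinetics), length(increments))
  }
  if (!is.list(kinetics) || length(kinetics) != length(increments))
    stop("`kinetics` must be one bell_evans_params object or a list of one per increment")
  kinetics <- lapply(kinetics, as_bell_evans_params)
  if (any(vapply(kinetics, function(k) k$kBT, numeric(1)) != kBT))
    stop("all kinetics must share the pathway's kBT")
  if (!is.finite(folded_Lc) || folded_Lc <= 0) stop("`folded_Lc` must be > 0")
  if (!is.finite(Lp) || Lp <= 0) stop("`Lp` must be > 0")
  if (!is.finite(Lp_handle) || Lp_handle <= 0) stop("`Lp_handle` must be > 0")
  structure(list(increments = increments, kinetics = kinetics,
                 Lp = Lp, kBT = kBT, folded_Lc = folded_Lc,
                 Lp_handle = Lp_handle),
            class = "unfolding_pathway")
}

# molecular extension at force F with `Lc_unf` nm of unfolded chain released:
# handle WLC plus unfolded-polypeptide WLC in series at common force
pathway_extension <- function(force, Lc_unf, pathway) {
  out <- wlc_extension(force, wlc_params(pathway$folded_Lc, pathway$Lp_handle,
                                         pathway$kBT))
  if (Lc_unf > 0)
    out <- out + wlc_extension(force, wlc_params(Lc_unf, pathway$Lp, pathway$kBT))
  out
}

#' @export
print.unfolding_pathway <- function(x, ...) {
  cat(sprintf("Unfolding pathway: %d transition(s), total gain %.1f nm (Lp = %g nm, baseline Lc = %g nm)\n",
              length(x$increments), sum(x$increments), x$Lp, x$folded_Lc))
  for (i in seq_along(x$increments)) {
    cat(sprintf("  step %d: dLc = %.1f nm, k0 = %g 1/s, gamma = %g nm\n",
                i, x$increments[i], x$kinetics[[i]]$k0, x$kinetics[[i]]$gamma))
  }
  invisible(x)
}

#' Define a constant-loading-rate pulling protocol
#'
#' @param loading_rate Nominal loading rate in pN/s, > 0. Alternatively give
#'   `pulling_speed` (nm/s) together with `effective_stiffness`, in which
#'   case `loading_rate = pulling_speed * effective_stiffness`.
#' @param sampling_interval Sampling interval in s. Default `NULL` chooses
#'   `0.1 / loading_rate`, i.e. one sample per 0.1 pN of ramp.
#' @param max_force Force in pN at which the pull stops. Must exceed the
#'   largest expected rupture force. Default 30 pN.
#' @param noise_sd_force,noise_sd_extension Gaussian measurement noise SDs
#'   added to the force (pN) and extension (nm) channels. Defaults 0.3 pN and
#'   2 nm, a typical optical-trap noise floor.
#' @param effective_stiffness Series stiffness of trap plus tether in pN/nm,
#'   used to convert the extension jump at a rupture into the observed force
#'   drop. Default 0.3 pN/nm.
#' @param pulling_speed Optional pulling speed in nm/s (used only with
#'   `effective_stiffness` when `loading_rate` is missing).
#' @param seed Optional integer seed.
#'
#' @return An object of class `"pulling_protocol"`.
#' @examples
#' pulling_protocol(loading_rate = 10, seed = 1)
#' pulling_protocol(pulling_speed = 100, effective_stiffness = 0.3)
#' @export
pulling_protocol <- function(loading_rate = NULL, sampling_interval = NULL,
                             max_force = 30, noise_sd_force = 0.3,
                             noise_sd_extension = 2, effective_stiffness = 0.3,
                             pulling_speed = NULL, seed = NULL) {
  if (is.null(loading_rate)) {
    if (is.null(pulling_speed))
      stop("give either `loading_rate` or `pulling_speed` with `effective_stiffness`")
    loading_rate <- pulling_speed * effective_stiffness
  }
  if (!is.finite(loading_rate) || loading_rate <= 0) stop("loading rate must be > 0")
  if (is.null(sampling_interval)) sampling_interval <- 0.1 / loading_rate
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    stop("sampling interval must be > 0")
  if (!is.finite(max_force) || max_force <= 0) stop("`max_force` must be > 0")
  if (noise_sd_force < 0 || noise_sd_extension < 0) stop("noise SDs must be >= 0")
  if (effective_stiffness <= 0) stop("`effective_stiffness` must be > 0")
  structure(list(loading_rate = loading_rate,
                 sampling_interval = sampling_interval,
                 max_force = max_force,
                 noise_sd_force = noise_sd_force,
                 noise_sd_extension = noise_sd_extension,
                 effective_stiffness = effective_stiffness,
                 seed = seed),
            class = "pulling_protocol")
}

# conditional rupture force: bond loaded from force f0 at rate r, exact
# inverse of the integrated Bell-Evans hazard mapped through Exp(1)
draw_rupture_from <- function(f0, kin, r) {
  e <- stats::rexp(1)
  g <- kin$gamma
  if (kin$k0 <= 0) return(Inf)
  if (g == 0) return(f0 + r * e / kin$k0)
  (kin$kBT / g) * log(exp(g * f0 / kin$kBT) + g * r * e / (kin$k0 * kin$kBT))
}

#' Simulate one constant-loading-rate pulling trace
#'
#' Kinetic Monte-Carlo simulation of a single pull. The force ramps at the
#' nominal loading rate; each pending transition ruptures at a force drawn
#' exactly from the closed-form Bell-Evans first-rupture distribution
#' (conditional on the current force, so sequential steps are handled
#' without discretization bias). At a rupture the contour length grows by
#' the step's increment and the trap relaxes along the series spring of
#' stiffness `effective_stiffness`: the post-rupture force `F'` solves
#' `x(F', Lc + dLc) + F'/k = x(F, Lc) + F/k` (the trap-to-bead distance is
#' continuous across the rupture), so the recorded force drops suddenly
#' while the recorded extension gains `(F - F')/k`. The ramp then resumes at
#' the nominal rate; once the force re-crosses the rupture force the
#' extension exceeds its pre-rupture value by exactly the worm-like-chain
#' jump at that force. Gaussian noise is added to both recorded channels.
#'
#' @param pathway An [unfolding_pathway()] object.
#' @param protocol A [pulling_protocol()] object.
#' @param trace_id Identifier stored in the trace (default `"trace_1"`).
#'
#' @return An object of class `"pulling_trace"`: a list with `trace_id`,
#'   numeric vectors `time` (s), `force` (pN), `extension` (nm), the
#'   `protocol`, a `ground_truth` data frame (`time`, `force`, `dLc` of each
#'   triggered transition), and a logical `truncated` flag set when the pull
#'   reached `max_force` with transitions still folded.
#' @examples
#' pw <- unfolding_pathway(55.3, bell_evans_params(0.15, 0.71))
#' tr <- simulate_trace(pw, pulling_protocol(loading_rate = 10, seed = 1))
#' @export
simulate_trace <- function(pathway, protocol, trace_id = "trace_1") {
  if (!inherits(pathway, "unfolding_pathway")) stop("`pathway` must be an unfolding_pathway")
  if (!inherits(protocol, "pulling_protocol")) stop("`protocol` must be a pulling_protocol")
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  r <- protocol$loading_rate
  dt <- protocol$sampling_interval
  k_eff <- protocol$effective_stiffness
  n_steps <- length(pathway$increments)

  # draw the rupture forces sequentially, tracking the post-drop force
  ev_force <- ev_time <- ev_drop <- numeric(0)
  ev_step <- integer(0)
  f_resume <- 0   # force at which the current ramp segment starts
  t_resume <- 0   # time at which it starts
  Lc_unf <- 0     # unfolded contour length released so far
  truncated <- FALSE
  for (i in seq_len(n_steps)) {
    f_rupt <- draw_rupture_from(f_resume, pathway$kinetics[[i]], r)
    if (!is.finite(f_rupt) || f_rupt >= protocol$max_force) {
      truncated <- TRUE
      break
    }
    t_rupt <- t_resume + (f_rupt - f_resume) / r
    dLc <- pathway$increments[i]
    # trap-bead distance is continuous across the rupture: solve for the
    # relaxed force F' on the lengthened tether
    d_before <- pathway_extension(f_rupt, Lc_unf, pathway) + f_rupt / k_eff
    f_relax <- stats::uniroot(
      function(fp) pathway_extension(fp, Lc_unf + dLc, pathway) + fp / k_eff - d_before,
      lower = 0, upper = f_rupt, tol = 1e-10
    )$root
    ev_force <- c(ev_force, f_rupt)
    ev_time <- c(ev_time, t_rupt)
    ev_drop <- c(ev_drop, f_rupt - f_relax)
    ev_step <- c(ev_step, i)
    f_resume <- f_relax
    t_resume <- t_rupt
    Lc_unf <- Lc_unf + dLc
  }

  t_end <- t_resume + (protocol$max_force - f_resume) / r
  time <- seq(0, t_end, by = dt)
  seg <- findInterval(time, ev_time) + 1L  # ramp segment index per sample
  seg_f0 <- c(0, ev_force - ev_drop)
  seg_t0 <- c(0, ev_time)
  seg_Lc <- c(0, cumsum(pathway$increments))[seq_len(length(ev_time) + 1L)]
  force <- seg_f0[seg] + r * (time - seg_t0[seg])
  extension <- numeric(length(time))
  for (s in unique(seg)) {
    idx <- seg == s
    extension[idx] <- pathway_extension(force[idx], seg_Lc[s], pathway)
  }
  if (protocol$noise_sd_force > 0)
    force <- force + stats::rnorm(length(force), 0, protocol$noise_sd_force)
  if (protocol$noise_sd_extension > 0)
    extension <- extension + stats::rnorm(length(extension), 0, protocol$noise_sd_extension)

  structure(list(
    trace_id = trace_id,
    time = time,
    force = force,
    extension = extension,
    protocol = protocol,
    ground_truth = data.frame(time = ev_time, force = ev_force,
                              dLc = pathway$increments[ev_step]),
    truncated = truncated
  ), class = "pulling_trace")
}

#' @export
print.pulling_trace <- function(x, ...) {
  cat(sprintf("Pulling trace '%s': %d samples at %g pN/s, %d ground-truth event(s)%s\n",
              x$trace_id, length(x$time), x$protocol$loading_rate,
              nrow(x$ground_truth), if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Simulate a multi-rate pulling experiment
#'
#' Generates `n_traces_per_rate` pulls at each loading rate with independent
#' per-trace sub-seeds derived from `seed`, mirroring the scale of a real
#' dynamic-force-spectroscopy campaign (several hundred traces per
#' condition across five speeds).
#'
#' @param pathway An [unfolding_pathway()] object.
#' @param loading_rates Numeric vector of loading rates in pN/s (default
#'   `c(1, 3, 10, 30, 100)`).
#' @param n_traces_per_rate Integer count per rate (recycled; 0 allowed).
#' @param seed Integer master seed (required, for reproducibility).
#' @param protocol_args Named list of overrides passed to
#'   [pulling_protocol()] (e.g. `noise_sd_force`).
#'
#' @return An object of class `"trace_set"`: a list with `traces` (list of
#'   [simulate_trace()] outputs), `loading_rate` (one per trace), and
#'   `ground_truth` (data frame with `trace_id`, `loading_rate`, `time`,
#'   `force`, `dLc`).
#' @examples
#' pw <- unfolding_pathway(55.3, bell_evans_params(0.15, 0.71))
#' xs <- simulate_experiment(pw, loading_rates = c(5, 50),
#'                           n_traces_per_rate = 3, seed = 1)
#' @export
simulate_experiment <- function(pathway, loading_rates = c(1, 3, 10, 30, 100),
                                n_traces_per_rate = 300, seed,
                                protocol_args = list()) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (length(loading_rates) < 1L || any(loading_rates <= 0))
    stop("at least one positive loading rate is required")
  n_per <- rep_len(as.integer(n_traces_per_rate), length(loading_rates))
  if (any(n_per < 0)) stop("trace counts must be >= 0")
  set.seed(seed)
  total <- sum(n_per)
  sub_seeds <- if (total > 0) sample.int(.Machine$integer.max, total) else integer(0)

  traces <- vector("list", total)
  rate_of <- numeric(total)
  gt_list <- vector("list", total)
  k <- 0L
  for (j in seq_along(loading_rates)) {
    for (i in seq_len(n_per[j])) {
      k <- k + 1L
      args <- c(list(loading_rate = loading_rates[j], seed = sub_seeds[k]),
                protocol_args)
      proto <- do.call(pulling_protocol, args)
      id <- sprintf("r%g_t%03d", loading_rates[j], i)
      tr <- simulate_trace(pathway, proto, trace_id = id)
      traces[[k]] <- tr
      rate_of[k] <- loading_rates[j]
      if (nrow(tr$ground_truth) > 0) {
        gt_list[[k]] <- cbind(trace_id = id, loading_rate = loading_rates[j],
                              tr$ground_truth)
      }
    }
  }
  gt <- do.call(rbind, gt_list[!vapply(gt_list, is.null, logical(1))])
  if (is.null(gt)) gt <- data.frame(trace_id = character(0), loading_rate = numeric(0),
                                    time = numeric(0), force = numeric(0), dLc = numeric(0))
  structure(list(traces = traces, loading_rate = rate_of, ground_truth = gt),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Trace set: %d traces at %d loading rate(s), %d ground-truth events\n",
              length(x$traces), length(unique(x$loading_rate)), nrow(x$ground_truth)))
  invisible(x)
}
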