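#' Detect unfolding events in a pulling trace
#'
#' Scans a force-extension trace for the signature of an unfolding
#' transition: a sudden force drop co-occurring with an extension gain.
#' Candidate positions compare 3-sample running medians before and after
#' each possible rupture (robust to single-sample noise spikes); candidates
#' closer than `merge_within` samples are merged, keeping the largest drop.
#' The rupture force is the pre-drop local maximum of the raw force channel.
#'
#' The reported `extension_gain` is the unfolding extension at the rupture
#' force: after the rupture the ramp recovers, and once the force re-crosses
#' its pre-rupture value the extension exceeds the pre-rupture extension by
#' exactly the worm-like-chain jump of the released chain at that force. The
#' detector therefore interpolates the post-rupture extension back to the
#' pre-rupture force. When the ramp does not recover before the next event
#' the gain cannot be referenced to a matched force and is reported as `NA`
#' (the immediate jump across the drop is still used for thresholding).
#'
#' @param trace A [simulate_trace()] output or any `"pulling_trace"` object
#'   with >= 10 samples.
#' @param min_force_drop Minimum force drop in pN (> 0). Default 1 pN.
#' @param min_extension_gain Minimum extension gain in nm (> 0). Default 5 nm.
#' @param window Maximum number of samples over which the drop may be spread.
#'   Default 5.
#' @param merge_within Candidates within this many samples are treated as one
#'   rupture. Default 2.
#'
#' @return A data frame of class `"unfolding_events"`, one row per event in
#'   time order: `trace_id`, `time` (s), `rupture_force` (pN), `force_drop`
#'   (pN), `extension_gain` (nm), `loading_rate` (pN/s, estimated by
#'   [estimate_loading_rate()]).
#' @examples
#' pw <- unfolding_pathway(55.3, bell_evans_params(0.15, 0.71))
#' tr <- simulate_trace(pw, pulling_protocol(loading_rate = 10, seed = 2))
#' detect_unfolding_events(tr)
#' @export
detect_unfolding_events <- function(trace, min_force_drop = 1,
                                    min_extension_gain = 5,
                                    window = 5L, merge_within = 2L) {
  if (!inherits(trace, "pulling_trace")) stop("`trace` must be a pulling_trace")
  if (min_force_drop <= 0 || min_extension_gain <= 0)
    stop("detection thresholds must be > 0")
  n <- length(trace$force)
  if (n < 10L) stop("trace must have at least 10 samples")
  f <- trace$force
  x <- trace$extension
  medf <- stats::runmed(f, 3)
  medx <- stats::runmed(x, 3)

  # pre statistic at i: median of f[i-2..i]; post at i+w: median of f[i+w..i+w+2]
  window <- as.integer(window)
  i_max <- n - window - 2L
  if (i_max < 3L) stop("trace too short for the detection window")
  idx <- 3:i_max
  best_drop <- rep(-Inf, length(idx))
  best_w <- rep(NA_integer_, length(idx))
  pre_f <- medf[idx - 1L]
  for (w in seq_len(window)) {
    drop_w <- pre_f - medf[idx + w + 1L]
    ok <- drop_w >= min_force_drop
    better <- ok & drop_w > best_drop
    best_drop[better] <- drop_w[better]
    best_w[better] <- w
  }
  cand <- which(!is.na(best_w))
  picks <- integer(0)
  if (length(cand) > 0) {
    # merge candidate runs closer than merge_within samples; keep largest drop
    grp <- cumsum(c(1L, diff(cand) > merge_within))
    picks <- vapply(split(cand, grp), function(members) {
      members[which.max(best_drop[members])]
    }, integer(1))
    picks <- sort(picks)
  }

  events <- list()
  event_idx <- idx[picks]
  for (k in seq_along(picks)) {
    pick <- picks[k]
    ii <- idx[pick]          # sample index of the last pre-rupture point
    w <- best_w[pick]
    anchor_f <- medf[ii - 1L]
    anchor_x <- medx[ii - 1L]
    immediate_gain <- medx[ii + w + 1L] - medx[ii - 1L]
    # interpolate the recovered branch back to the pre-rupture force
    j_stop <- if (k < length(picks)) event_idx[k + 1L] else n
    j_from <- ii + w + 1L
    gain <- NA_real_
    if (j_from < j_stop) {
      rec <- j_from:j_stop
      hit <- rec[medf[rec] >= anchor_f]
      if (length(hit) > 0) {
        j <- hit[1L]
        if (j > j_from && medf[j] > medf[j - 1L]) {
          frac <- (anchor_f - medf[j - 1L]) / (medf[j] - medf[j - 1L])
          gain <- medx[j - 1L] + frac * (medx[j] - medx[j - 1L]) - anchor_x
        } else {
          gain <- medx[j] - anchor_x
        }
      }
    }
    screen_gain <- if (is.na(gain)) immediate_gain else gain
    if (screen_gain < min_extension_gain) next
    events[[length(events) + 1L]] <- data.frame(
      trace_id = trace$trace_id,
      time = trace$time[ii],
      rupture_force = max(f[max(1L, ii - 2L):ii]),
      force_drop = best_drop[pick],
      extension_gain = gain,
      index = ii
    )
  }
  if (length(events) == 0L) {
    out <- data.frame(trace_id = character(0), time = numeric(0),
                      rupture_force = numeric(0), force_drop = numeric(0),
                      extension_gain = numeric(0), loading_rate = numeric(0))
    class(out) <- c("unfolding_events", class(out))
    return(out)
  }
  out <- do.call(rbind, events)
  out <- out[order(out$time), , drop = FALSE]
  out$loading_rate <- vapply(seq_len(nrow(out)), function(k) {
    start_idx <- if (k == 1L) 1L else out$index[k - 1L] + 1L
    estimate_loading_rate(trace, out$index[k], segment_start = start_idx)
  }, numeric(1))
  out$index <- NULL
  rownames(out) <- NULL
  class(out) <- c("unfolding_events", class(out))
  out
}

#' Estimate the loading rate preceding an unfolding event
#'
#' Least-squares slope of force against time over the final fraction of the
#' ramp segment that precedes the event. Falls back to the protocol's nominal
#' loading rate (with a warning) when fewer than 5 samples are available.
#'
#' @param trace A `"pulling_trace"` object.
#' @param event_index Sample index of the last pre-rupture point.
#' @param window_fraction Fraction of the pre-rupture segment used. Default
#'   0.2 (the final 20 percent).
#' @param segment_start First sample index of the ramp segment (1 for the
#'   first event; the sample after the previous rupture otherwise).
#'
#' @return Estimated loading rate in pN/s.
#' @export
estimate_loading_rate <- function(trace, event_index, window_fraction = 0.2,
                                  segment_start = 1L) {
  if (!inherits(trace, "pulling_trace")) stop("`trace` must be a pulling_trace")
  seg_len <- event_index - segment_start + 1L
  first <- event_index - max(ceiling(window_fraction * seg_len), 1L) + 1L
  first <- max(first, segment_start)
  idx <- first:event_index
  if (length(idx) < 5L) {
    warning("fewer than 5 pre-rupture samples: falling back to the nominal loading rate")
    return(trace$protocol$loading_rate)
  }
  unname(stats::coef(stats::lm(trace$force[idx] ~ trace$time[idx]))[2])
}

#' Most probable force from a rupture-force histogram
#'
#' Bins rupture forces into a uniform histogram and returns the centre of the
#' tallest bin, with half the bin width as its uncertainty — the convention
#' used for dynamic-force-spectroscopy plots of unfolding force versus
#' loading rate. Ties between equally tall bins are broken toward the
#' lower-force bin.
#'
#' @param events An `"unfolding_events"` data frame (column `rupture_force`)
#'   or a numeric vector of rupture forces; at least 1 value.
#' @param bin_width Histogram bin width in pN, > 0. Default 1 pN.
#' @param origin Force at which bin edges are anchored. Default 0.
#'
#' @return A list with `force` (centre of the tallest bin, pN), `half_bin`
#'   (pN), and `n` (number of events).
#' @examples
#' f <- simulate_rupture_forces(bell_evans_params(0.15, 0.71), 10, 2000, seed = 1)
#' most_probable_force(f)
#' @export
most_probable_force <- function(events, bin_width = 1, origin = 0) {
  forces <- if (is.data.frame(events)) events$rupture_force else events
  if (is.null(forces) || length(forces) < 1L)
    stop("at least one rupture force is required")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("`bin_width` must be > 0")
  lo <- origin + bin_width * floor((min(forces) - origin) / bin_width)
  hi <- origin + bin_width * ceiling((max(forces) - origin) / bin_width)
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- tabulate(findInterval(forces, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  tallest <- which.max(counts)  # which.max takes the first (lowest-force) tie
  list(force = edges[tallest] + bin_width / 2, half_bin = bin_width / 2,
       n = length(forces))
}

#' Gaussian summary of unfolding extension gains
#'
#' Summarises the extension-gain distribution by a Gaussian fit, reported as
#' the mean plus the half width at half maximum (`HWHM = sd * sqrt(2 log 2)`),
#' the convention used for force-extension profiles of unfolding events.
#'
#' @param events An `"unfolding_events"` data frame (column `extension_gain`)
#'   or a numeric vector of extension gains; at least 3 values.
#'
#' @return A list of class `"extension_summary"` with `gaussian_mean` (nm),
#'   `hwhm` (nm), and `n_events`.
#' @examples
#' summarize_extensions(rnorm(500, 40, 4))
#' @export
summarize_extensions <- function(events) {
  gains <- if (is.data.frame(events)) events$extension_gain else events
  gains <- gains[!is.na(gains)]
  if (is.null(gains) || length(gains) < 3L)
    stop("at least 3 extension gains are required")
  s <- stats::sd(gains)
  if (!is.finite(s) || s == 0)
    stop("degenerate extension distribution: all gains identical")
  structure(list(gaussian_mean = mean(gains),
                 hwhm = s * sqrt(2 * log(2)),
                 n_events = length(gains)),
            class = "extension_summary")
}

#' @export
print.extension_summary <- function(x, ...) {
  cat(sprintf("Extension gains: %.2f nm (Gaussian mean) +/- %.2f nm (HWHM), n = %d\n",
              x$gaussian_mean, x$hwhm, x$n_events))
  invisible(x)
}

#' Detect events across a whole trace set
#'
#' Convenience wrapper running [detect_unfolding_events()] over every trace
#' of a [simulate_experiment()] output (or a list of traces) and binding the
#' results with the nominal loading rate of each trace attached.
#'
#' @param traces A `"trace_set"` or a list of `"pulling_trace"` objects.
#' @param ... Passed to [detect_unfolding_events()].
#'
#' @return An `"unfolding_events"` data frame with an extra column
#'   `nominal_rate` when available.
#' @export
detect_all_events <- function(traces, ...) {
  if (inherits(traces, "trace_set")) {
    lst <- traces$traces
    rates <- traces$loading_rate
  } else {
    lst <- traces
    rates <- rep(NA_real_, length(lst))
  }
  out <- vector("list", length(lst))
  for (i in seq_along(lst)) {
    ev <- detect_unfolding_events(lst[[i]], ...)
    if (nrow(ev) > 0) ev$nominal_rate <- rates[i]
    out[[i]] <- ev
  }
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0L) {
    res <- data.frame(trace_id = character(0), time = numeric(0),
                      rupture_force = numeric(0), force_drop = numeric(0),
                      extension_gain = numeric(0), loading_rate = numeric(0),
                      nominal_rate = numeric(0))
  } else {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
  }
  class(res) <- c("unfolding_events", "data.frame")
  res
}
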