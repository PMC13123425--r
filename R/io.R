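#' Write pulling traces to a tab-separated table
#'
#' One row per sample with columns `trace_id`, `time_s`, `extension_nm`,
#' `force_pN`; all traces concatenated.
#'
#' @param traces A `"trace_set"`, a list of `"pulling_trace"` objects, or a
#'   single trace.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  if (inherits(traces, "pulling_trace")) traces <- list(traces)
  if (inherits(traces, "trace_set")) traces <- traces$traces
  rows <- lapply(traces, function(tr) {
    data.frame(trace_id = tr$trace_id, time_s = tr$time,
               extension_nm = tr$extension, force_pN = tr$force)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pulling traces from a tab-separated table
#'
#' Reads the format written by [write_trace_table()]: header line plus
#' columns `trace_id`, `time_s`, `extension_nm`, `force_pN`. Malformed
#' numeric cells are reported with their line numbers; a trace whose time
#' column is not strictly increasing raises a validation error naming the
#' trace.
#'
#' @param path Input file path.
#' @param nominal_rates Optional named numeric vector mapping trace id to its
#'   nominal loading rate (stored in each trace's protocol; otherwise the
#'   rate is estimated from the ramp).
#'
#' @return A list of `"pulling_trace"` objects.
#' @export
read_trace_table <- function(path, nominal_rates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "character", "character"))
  required <- c("trace_id", "time_s", "extension_nm", "force_pN")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  num <- function(col) suppressWarnings(as.numeric(tab[[col]]))
  t_s <- num("time_s"); x_nm <- num("extension_nm"); f_pN <- num("force_pN")
  bad <- which(is.na(t_s) | is.na(x_nm) | is.na(f_pN))
  if (length(bad) > 0)
    stop("malformed numeric value(s) at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " of ", path)  # +1 for the header line
  ids <- tab$trace_id
  out <- lapply(unique(ids), function(id) {
    sel <- ids == id
    tt <- t_s[sel]
    if (is.unsorted(tt, strictly = TRUE))
      stop(sprintf("validation error: time is not strictly increasing in trace '%s'", id))
    rate <- if (!is.null(nominal_rates) && id %in% names(nominal_rates)) {
      nominal_rates[[id]]
    } else {
      # fall back to the overall ramp slope
      unname(stats::coef(stats::lm(f_pN[sel] ~ tt))[2])
    }
    proto <- pulling_protocol(loading_rate = max(rate, .Machine$double.eps),
                              sampling_interval = stats::median(diff(tt)))
    structure(list(trace_id = id, time = tt, force = f_pN[sel],
                   extension = x_nm[sel], protocol = proto,
                   ground_truth = data.frame(time = numeric(0), force = numeric(0),
                                             dLc = numeric(0)),
                   truncated = FALSE),
              class = "pulling_trace")
  })
  out
}

#' Write detected unfolding events to a tab-separated table
#'
#' @param events An `"unfolding_events"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_table <- function(events, path) {
  out <- data.frame(trace_id = events$trace_id, time_s = events$time,
                    rupture_force_pN = events$rupture_force,
                    force_drop_pN = events$force_drop,
                    extension_gain_nm = events$extension_gain,
                    loading_rate_pNs = events$loading_rate)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a fitted model as a flat JSON document
#'
#' Serialises a `"wlc_fit"`, `"bell_evans_fit"` or `"hill_fit"` object to a
#' flat JSON file holding parameter names, estimates, standard errors, the
#' fixed thermal energy where applicable, and fit diagnostics.
#'
#' @param fit A fit object from [fit_wlc()], [fit_bell_evans()] or
#'   [fit_hill()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  doc <- if (inherits(fit, "wlc_fit")) {
    list(model = "worm_like_chain",
         Lc_nm = fit$params$Lc, Lp_nm = fit$params$Lp,
         Lc_se = unname(fit$se["Lc"]), Lp_se = unname(fit$se["Lp"]),
         kBT_pNnm = fit$params$kBT, residual_sd_pN = fit$residual_sd,
         n_points = fit$n)
  } else if (inherits(fit, "bell_evans_fit")) {
    list(model = "bell_evans",
         k0_per_s = fit$params$k0, gamma_nm = fit$params$gamma,
         k0_se = unname(fit$se["k0"]), gamma_se = unname(fit$se["gamma"]),
         kBT_pNnm = fit$params$kBT, residual_sd_pN = fit$residual_sd,
         n_points = fit$n, method = fit$method)
  } else if (inherits(fit, "hill_fit")) {
    list(model = "hill",
         ec50_M = fit$ec50, hill_n = fit$hill_n,
         amplitude = fit$amplitude, baseline = fit$baseline,
         ec50_se = unname(fit$se["ec50"]), hill_n_se = unname(fit$se["hill_n"]),
         residual_sd = fit$residual_sd, converged = fit$converged,
         no_binding = fit$no_binding, n_points = fit$n)
  } else {
    stop("unsupported fit object of class ", paste(class(fit), collapse = "/"))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
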