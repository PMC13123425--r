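#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the simulate-detect-fit pipeline in one place
#' and validates each field against its module's preconditions before any
#' computation starts. The seed is mandatory so that every run is exactly
#' reproducible.
#'
#' @param conditions Named list, one entry per experimental condition, each a
#'   list with `increments` (nm, one per unfolding step), `k0` (1/s) and
#'   `gamma` (nm) — either scalars (recycled over steps) or one per step —
#'   and optionally `Lp` (nm, default 0.28) and `folded_Lc` (nm, default
#'   800). The first condition is the reference for crossover predictions.
#' @param seed Integer master seed (mandatory).
#' @param kBT Thermal energy in pN nm.
#' @param loading_rates Loading rates in pN/s.
#' @param n_traces Traces per loading rate per condition.
#' @param bin_width Rupture-force histogram bin width in pN.
#' @param min_force_drop,min_extension_gain Detection thresholds, see
#'   [detect_unfolding_events()].
#' @param protocol_args Named list of extra [pulling_protocol()] overrides.
#'
#' @return A validated list of class `"run_config"`.
#' @examples
#' run_config(
#'   conditions = list(
#'     no_ligand = list(increments = 55.3, k0 = 0.15, gamma = 0.71, Lp = 0.28),
#'     bound = list(increments = 40.0, k0 = 0.017, gamma = 1.88, Lp = 0.38)),
#'   seed = 7, n_traces = 20)
#' @export
run_config <- function(conditions, seed, kBT = kBT_25C,
                       loading_rates = c(1, 3, 10, 30, 100),
                       n_traces = 100, bin_width = 1,
                       min_force_drop = 1, min_extension_gain = 5,
                       protocol_args = list()) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("`seed` is mandatory in a run configuration")
  if (!is.list(conditions) || length(conditions) < 1L ||
      is.null(names(conditions)) || any(names(conditions) == ""))
    stop("`conditions` must be a non-empty named list")
  if (any(loading_rates <= 0)) stop("loading rates must be > 0")
  if (n_traces < 1) stop("`n_traces` must be >= 1")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  if (min_force_drop <= 0 || min_extension_gain <= 0)
    stop("detection thresholds must be > 0")
  # build each pathway now so that invalid parameters fail before any work
  pathways <- lapply(names(conditions), function(nm) {
    cond <- conditions[[nm]]
    for (fld in c("increments", "k0", "gamma"))
      if (is.null(cond[[fld]]))
        stop(sprintf("condition '%s' is missing field `%s`", nm, fld))
    n_steps <- length(cond$increments)
    k0 <- rep_len(cond$k0, n_steps)
    gamma <- rep_len(cond$gamma, n_steps)
    kin <- lapply(seq_len(n_steps),
                  function(i) bell_evans_params(k0[i], gamma[i], kBT))
    unfolding_pathway(cond$increments, kin,
                      Lp = if (is.null(cond$Lp)) 0.28 else cond$Lp,
                      kBT = kBT,
                      folded_Lc = if (is.null(cond$folded_Lc)) 800 else cond$folded_Lc)
  })
  names(pathways) <- names(conditions)
  structure(list(conditions = conditions, pathways = pathways, seed = as.integer(seed),
                 kBT = kBT, loading_rates = loading_rates, n_traces = n_traces,
                 bin_width = bin_width, min_force_drop = min_force_drop,
                 min_extension_gain = min_extension_gain,
                 protocol_args = protocol_args),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Parses a JSON document whose fields mirror the arguments of
#' [run_config()] and returns the validated configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$conditions)) stop("config must define `conditions`")
  if (is.null(doc$seed)) stop("config must define `seed` (no silent default)")
  args <- list(conditions = lapply(doc$conditions, as.list), seed = doc$seed)
  for (fld in c("kBT", "loading_rates", "n_traces", "bin_width",
                "min_force_drop", "min_extension_gain"))
    if (!is.null(doc[[fld]])) args[[fld]] <- doc[[fld]]
  do.call(run_config, args)
}

#' Run the full simulate-detect-fit pipeline
#'
#' For each condition: simulates a multi-rate pulling experiment, detects
#' unfolding events, builds per-rate rupture-force histograms, fits the
#' Bell-Evans model to the most probable forces, and fits the worm-like
#' chain to the (rupture force, extension gain) pairs. With two or more
#' conditions it also reports the crossover force of every non-reference
#' condition against the first (reference) condition. Deterministic given
#' the config seed.
#'
#' @param config A [run_config()] object.
#'
#' @return An object of class `"analysis_report"`: a list with
#'   `parameter_table` (one row per condition: fitted `Lc`, `Lp`, `k0`,
#'   `gamma` and standard errors), `crossover` (data frame of crossover
#'   forces vs the reference), `rate_points` (per condition and rate: most
#'   probable force, half-bin, mean estimated loading rate, event count),
#'   `extension_summaries`, and `provenance` (seed, package version, config
#'   hash).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  set.seed(config$seed)
  cond_seeds <- sample.int(.Machine$integer.max, length(config$pathways))

  fits <- list()
  rate_points <- list()
  ext_summaries <- list()
  for (ci in seq_along(config$pathways)) {
    nm <- names(config$pathways)[ci]
    xs <- simulate_experiment(config$pathways[[nm]],
                              loading_rates = config$loading_rates,
                              n_traces_per_rate = config$n_traces,
                              seed = cond_seeds[ci],
                              protocol_args = config$protocol_args)
    ev <- detect_all_events(xs,
                            min_force_drop = config$min_force_drop,
                            min_extension_gain = config$min_extension_gain)
    if (nrow(ev) == 0L) stop("no unfolding events detected for condition ", nm)
    per_rate <- lapply(split(ev, ev$nominal_rate), function(d) {
      mp <- most_probable_force(d, bin_width = config$bin_width)
      data.frame(condition = nm, nominal_rate = d$nominal_rate[1],
                 loading_rate = mean(d$loading_rate),
                 most_probable_force = mp$force, half_bin = mp$half_bin,
                 n_events = nrow(d))
    })
    per_rate <- do.call(rbind, per_rate)
    be <- fit_bell_evans(data.frame(loading_rate = per_rate$loading_rate,
                                    force = per_rate$most_probable_force),
                         kBT = config$kBT)
    evc <- ev[!is.na(ev$extension_gain), , drop = FALSE]
    wlc <- fit_wlc(data.frame(extension = evc$extension_gain,
                              force = evc$rupture_force),
                   kBT = config$kBT)
    fits[[nm]] <- list(bell_evans = be, wlc = wlc)
    rate_points[[nm]] <- per_rate
    ext_summaries[[nm]] <- summarize_extensions(ev)
  }

  parameter_table <- do.call(rbind, lapply(names(fits), function(nm) {
    be <- fits[[nm]]$bell_evans; wl <- fits[[nm]]$wlc
    data.frame(condition = nm,
               Lc = wl$params$Lc, Lc_se = unname(wl$se["Lc"]),
               Lp = wl$params$Lp, Lp_se = unname(wl$se["Lp"]),
               k0 = be$params$k0, k0_se = unname(be$se["k0"]),
               gamma = be$params$gamma, gamma_se = unname(be$se["gamma"]))
  }))

  crossover <- NULL
  if (length(fits) >= 2L) {
    ref <- fits[[1L]]$bell_evans$params
    crossover <- do.call(rbind, lapply(names(fits)[-1L], function(nm) {
      data.frame(reference = names(fits)[1L], condition = nm,
                 crossover_force = crossover_force(ref, fits[[nm]]$bell_evans$params))
    }))
  }

  cfg_json <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_json), add = TRUE)
  jsonlite::write_json(config$conditions, cfg_json, auto_unbox = TRUE, digits = NA)
  provenance <- list(seed = config$seed,
                     package_version = as.character(utils::packageVersion("forcespec")),
                     config_hash = unname(tools::md5sum(cfg_json)))

  structure(list(parameter_table = parameter_table,
                 crossover = crossover,
                 rate_points = do.call(rbind, rate_points),
                 extension_summaries = ext_summaries,
                 fits = fits,
                 provenance = provenance),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Pipeline analysis report\n\nFitted parameters per condition:\n")
  print(x$parameter_table, row.names = FALSE, digits = 4)
  if (!is.null(x$crossover)) {
    cat("\nStability crossover vs reference:\n")
    print(x$crossover, row.names = FALSE, digits = 3)
  }
  cat(sprintf("\nSeed %d, forcespec %s\n", x$provenance$seed,
              x$provenance$package_version))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report An `"analysis_report"` from [run_pipeline()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  doc <- list(parameter_table = report$parameter_table,
              crossover = report$crossover,
              rate_points = report$rate_points,
              extension_summaries = lapply(report$extension_summaries, unclass),
              provenance = report$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
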