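# End-to-end pipeline driver: simulate (optional) -> amplitude histogram ->
# mixture fit -> idealize -> open-probability statistics -> I-V and
# conductance, or the whole-cell branch (maximum currents, density,
# activation tau, ramp reversal). Deterministic given a seed; every run
# writes a machine-readable manifest.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Read a pipeline configuration file
#'
#' Configurations are YAML with keys mirroring [run_pipeline()]'s
#' structure (`mode`, `seed`, `out_dir`, `simulate`, `acquisition`,
#' `analysis`, `whole_cell`).
#'
#' @param path YAML file path.
#' @return A config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

default_config <- function() {
  list(
    mode = "single_channel",
    seed = 1L,
    out_dir = "patchquant-out",
    write_traces = FALSE,
    simulate = list(conductance_pS = 96.5, reversal_mV = 0, n_channels = 1L,
                    opening_rate = 50, closing_rate = 50,
                    opening_v_slope = 100, duration_s = 10,
                    voltages = seq(-100, 100, by = 20)),
    acquisition = list(sampling_rate = 10000, filter_cutoff = 5000,
                       noise_sd = 0.3),
    analysis = list(bin_width = NULL, n_components = 2L, dead_time = NULL,
                    window_s = 10, start_s = 0, N = NULL,
                    fit_range = c(-100, 100)),
    whole_cell = list(max_density_pA_pF = 139.9, capacitance_pF = 20,
                      tau_ms = 10, v_ref = 180, v_rev = 0,
                      v_half = 60, slope_mV = 30, tau_window = NULL)
  )
}

merge_config <- function(config) {
  def <- default_config()
  if (is.null(config)) return(def)
  for (k in names(config)) {
    if (is.list(config[[k]]) && is.list(def[[k]]))
      def[[k]] <- utils::modifyList(def[[k]], config[[k]])
    else def[[k]] <- config[[k]]
  }
  def
}

write_table <- function(d, out_dir, name) {
  p <- file.path(out_dir, name)
  utils::write.csv(format(d, digits = 10, trim = TRUE, scientific = FALSE),
                   p, row.names = FALSE, quote = FALSE)
  p
}

#' Run the full quantification pipeline
#'
#' Executes the configured branch end-to-end and writes tidy CSV result
#' tables plus a JSON manifest (parameters, seed, config hash, package
#' version, output files) into `out_dir`. With the same configuration and
#' seed, outputs are reproduced byte for byte.
#'
#' Single-channel branch: for each command voltage, simulate a patch
#' (unless input trace files are listed under `inputs`), build the
#' all-points amplitude histogram, fit the Gaussian mixture, take the
#' unitary amplitude mu2 - mu1, idealize by half-amplitude threshold, and
#' accumulate Popen/NPo and the I-V relation; finish with the slope
#' conductance. Voltages where no opening is detected, where the fit does
#' not converge, or where open and closed levels overlap are excluded
#' from the conductance fit (and flagged in `amplitudes.csv`).
#'
#' Whole-cell branch: simulate (or read) a step family, report maximum
#' current and current density per step, fit the activation time constant
#' at the most depolarized step, and, when a ramp is configured, the
#' ramp reversal potential.
#'
#' @param config a config list or the path to a YAML file; missing entries
#'   take the package defaults (a two-state single-channel simulation at
#'   the standard step voltages).
#' @param seed optional override of `config$seed`.
#' @param out_dir optional override of `config$out_dir`.
#' @return Invisibly, a list with the computed results and output paths.
#' @export
run_pipeline <- function(config = NULL, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!cfg$mode %in% c("single_channel", "whole_cell"))
    stop("unknown mode '", cfg$mode, "'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(cfg$out_dir, "config.json")
  cfg_written <- cfg
  cfg_written$out_dir <- NULL    # where results land is not a parameter
  jsonlite::write_json(cfg_written, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  cfg_hash <- unname(tools::md5sum(cfg_path))
  outputs <- "config.json"
  res <- list(config = cfg, config_hash = cfg_hash)

  acq <- run_stage("acquisition", do.call(acquisition_spec, cfg$acquisition))

  if (cfg$mode == "single_channel") {
    sim <- cfg$simulate
    model <- run_stage("model", two_state_model(
      opening_rate = sim$opening_rate, closing_rate = sim$closing_rate,
      conductance_pS = sim$conductance_pS, reversal_mV = sim$reversal_mV,
      n_channels = sim$n_channels, opening_v_slope = sim$opening_v_slope))
    volts <- sim$voltages
    seeds <- expand_seed(cfg$seed, length(volts))
    an <- cfg$analysis

    amp_rows <- list(); po_rows <- list(); po_results <- list()
    for (k in seq_along(volts)) {
      v <- volts[k]
      tr <- run_stage("simulate", simulate_patch(
        model, v, sim$duration_s, seed = seeds[k], acq = acq))
      if (isTRUE(cfg$write_traces))
        outputs <- c(outputs, basename(run_stage("write", write_trace(
          tr, file.path(cfg$out_dir, sprintf("trace_%+04d_mV.atf", v))))))
      hist <- run_stage("histogram",
                        amplitude_histogram(tr, bin_width = an$bin_width))
      fit <- run_stage("mixture_fit",
                       fit_gaussian_mixture(hist, an$n_components))
      amp <- run_stage("unitary_amplitude", unitary_amplitude(fit))
      ideal <- run_stage("idealize",
                         idealize_trace(tr, fit, dead_time = an$dead_time))
      n_ch <- if (is.null(an$N)) max(max(ideal$level), 1L) else an$N
      po <- run_stage("popen", popen_multi(ideal, N = n_ch,
                                           window_s = an$window_s,
                                           start_s = an$start_s))
      ok <- fit$converged && !is.na(amp) &&
        !isTRUE(attr(ideal, "overlap_warning"))
      amp_rows[[k]] <- data.frame(
        voltage = v, unitary_pA = as.numeric(amp),
        mu1 = fit$components$mu[1],
        mu2 = if (fit$n >= 2) fit$components$mu[2] else NA_real_,
        converged = fit$converged,
        overlap = isTRUE(attr(ideal, "overlap_warning")),
        used_in_fit = ok)
      po_rows[[k]] <- data.frame(voltage = v, Popen = po$Popen,
                                 NPo = po$NPo, To = po$To, Tc = po$Tc,
                                 T = po$T, N = po$N)
      po_results[[k]] <- po
    }
    amp_tab <- do.call(rbind, amp_rows)
    po_tab <- do.call(rbind, po_rows)
    po_tab <- run_stage("normalize_popen", {
      norm <- normalize_popen(po_results)
      po_tab$Popen_norm <- norm$Popen_norm
      po_tab
    })
    iv <- run_stage("iv_curve", {
      ok <- amp_tab$used_in_fit
      iv_curve(amp_tab$voltage[ok], amp_tab$unitary_pA[ok])
    })
    g <- run_stage("conductance", conductance(iv, range = an$fit_range))
    outputs <- c(outputs,
                 basename(write_table(amp_tab, cfg$out_dir, "amplitudes.csv")),
                 basename(write_table(po_tab, cfg$out_dir, "popen.csv")),
                 basename(write_table(as.data.frame(iv), cfg$out_dir,
                                      "iv.csv")),
                 basename(write_table(data.frame(
                   conductance_pS = g$conductance_pS,
                   intercept_pA = g$intercept_pA,
                   r_squared = g$r_squared,
                   n_points = g$n_points), cfg$out_dir, "conductance.csv")))
    res <- c(res, list(amplitudes = amp_tab, popen = po_tab, iv = iv,
                       conductance = g))
  } else {
    wc <- cfg$whole_cell
    proto <- run_stage("protocol", voltage_protocol("step"))
    fam <- run_stage("simulate_whole_cell", simulate_whole_cell(
      proto, density_params = list(
        max_density_pA_pF = wc$max_density_pA_pF, v_ref = wc$v_ref,
        v_rev = wc$v_rev, v_half = wc$v_half, slope_mV = wc$slope_mV,
        tau_ms = wc$tau_ms),
      capacitance = wc$capacitance_pF, acq = acq, seed = cfg$seed))
    iv <- run_stage("max_current", max_current_per_step(fam))
    iv$density_pA_pF <- run_stage("current_density",
                                  current_density(iv$i_max, fam$capacitance))
    top <- fam$traces[[which.max(fam$voltages)]]
    tau <- run_stage("fit_activation_tau",
                     if (is.null(wc$tau_window)) fit_activation_tau(top)
                     else fit_activation_tau(top, window = wc$tau_window))
    outputs <- c(outputs,
                 basename(write_table(iv, cfg$out_dir, "iv_density.csv")),
                 basename(write_table(data.frame(
                   voltage = max(fam$voltages), tau_ms = tau$tau_ms,
                   Y0 = tau$Y0, A = tau$A, converged = tau$converged),
                   cfg$out_dir, "tau.csv")))
    res <- c(res, list(iv = iv, tau = tau, family = fam))
  }

  manifest <- list(package = "patchquant",
                   version = as.character(utils::packageVersion("patchquant")),
                   mode = cfg$mode, seed = cfg$seed,
                   config_md5 = cfg_hash, outputs = sort(unique(outputs)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
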