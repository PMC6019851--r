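# Study orchestration: simulate -> split -> reconstruct/fit -> sweep ->
# tabulate, with a manifest sufficient to reproduce every run. The
# canonical outputs are CSV tables; figures are left to the user.

#' Configuration for the simulation sweep study
#'
#' @param task_durations activation durations in seconds.
#' @param patterns stimulus pattern labels (see [stimulus_patterns()]).
#' @param cases sign-constraint case labels.
#' @param dpf_values DPF values to sweep.
#' @param vary which DPFs to vary (`"l1"`, `"l2"` or both).
#' @param hrf an [hrf_params].
#' @param nuisance a [nuisance_params]; the default is HRF-plus-baseline
#'   only (sinusoid amplitudes and noise zero), matching clean simulated
#'   response curves; pass nonzero amplitudes to add physiological
#'   interference, noting that the cardiac frequency then requires
#'   `fs > 2 * fc`.
#' @param fs instrument sampling rate in Hz.
#' @param resample_fs analysis rate in Hz (signals are generated at `fs`
#'   and linearly resampled; `NULL` to skip).
#' @param seed integer seed.
#' @return a list of class `"simulation_config"`.
#' @export
simulation_config <- function(task_durations = c(10, 20, 30),
                              patterns = names(stimulus_patterns()),
                              cases = paste0("case", 1:4),
                              dpf_values = 3:8,
                              vary = c("l1", "l2"),
                              hrf = hrf_params(),
                              nuisance = nuisance_params(ac = 0, ar = 0,
                                                         am = 0,
                                                         noise_sd = 0),
                              fs = 1.81, resample_fs = 100,
                              seed = 1) {
  vary <- match.arg(vary, several.ok = TRUE)
  if (any(dpf_values <= 0)) stop("'dpf_values' must be positive")
  stopifnot(all(cases %in% paste0("case", 1:4)),
            all(patterns %in% names(stimulus_patterns())))
  structure(list(task_durations = task_durations, patterns = patterns,
                 cases = cases, dpf_values = dpf_values, vary = vary,
                 hrf = hrf, nuisance = nuisance, fs = fs,
                 resample_fs = resample_fs, seed = seed),
            class = "simulation_config")
}

write_manifest <- function(out_dir, config, extra = list()) {
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- c(list(
    config_file = "config.json",
    config_md5 = unname(tools::md5sum(cfg_path)),
    package = "fnirsdpf",
    package_version = as.character(utils::packageVersion("fnirsdpf")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    created = "run"   # no timestamp: manifests of identical runs are identical
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the simulation sweep study
#'
#' For every combination of task duration and stimulus pattern,
#' generates the synthetic HbO signal, resamples it to the analysis
#' rate, splits it under each configured sign case, reconstructs the
#' series under every swept DPF value (per varied wavelength, the other
#' held at its implied true value), extracts HRF attributes, and
#' returns the combined sweep table. When `out_dir` is given the table,
#' per-curve CSVs and a reproduction manifest (config + its md5 +
#' package version + seed) are written there; a stage failure is logged
#' and the remaining combinations still run.
#'
#' @param config a [simulation_config].
#' @param out_dir optional output directory (created if missing).
#' @param write_curves write one CSV per reconstructed curve (default
#'   `FALSE`; the sweep table is always the canonical output).
#' @return the sweep table (data frame; one row per task duration x
#'   pattern x case x varied wavelength x DPF value), invisibly carrying
#'   attribute `"failures"` with any logged stage errors.
#' @examples
#' \donttest{
#' cfg <- simulation_config(task_durations = 20, patterns = "St1",
#'                          cases = "case1")
#' tab <- run_simulation_study(cfg)
#' }
#' @export
run_simulation_study <- function(config, out_dir = NULL,
                                 write_curves = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tabs <- list()
  failures <- character(0)
  for (task_s in config$task_durations) {
    for (pat in config$patterns) {
      paradigm <- simulated_paradigm(task_s, pat)
      y <- generate_signal(config$hrf, config$nuisance, paradigm,
                           fs = config$fs, seed = config$seed)
      if (!is.null(config$resample_fs))
        y <- resample_to(y, config$resample_fs)
      for (cs in config$cases) {
        sp <- tryCatch(split_signal(y, cs), error = function(e) e)
        if (inherits(sp, "error")) {
          failures <- c(failures, sprintf(
            "split stage (task %g s, %s, %s): %s", task_s, pat, cs,
            conditionMessage(sp)))
          next
        }
        for (vw in config$vary) {
          tab <- tryCatch(
            sweep_reconstruct(sp, paradigm, config$dpf_values, vary = vw),
            error = function(e) e)
          if (inherits(tab, "error")) {
            failures <- c(failures, sprintf(
              "sweep stage (task %g s, %s, %s, vary %s): %s", task_s, pat,
              cs, vw, conditionMessage(tab)))
            next
          }
          tab <- cbind(data.frame(task_s = task_s, varied = vw), tab)
          tabs[[length(tabs) + 1L]] <- tab
          if (!is.null(out_dir) && write_curves) {
            for (d in config$dpf_values) {
              d1 <- if (vw == "l1") d else implied_true_dpf()[["dpf_l1"]]
              d2 <- if (vw == "l2") d else implied_true_dpf()[["dpf_l2"]]
              rec <- reconstruct_under_dpf(sp, d1, d2)
              write_signal_csv(rec, file.path(out_dir, sprintf(
                "curve_task%g_%s_%s_%s%g.csv", task_s, pat, cs, vw, d)))
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "sweep_table.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, config,
                   extra = list(rows = nrow(out),
                                failures = as.list(failures)))
  }
  out
}

#' Configuration for the multi-subject fit study
#'
#' Defines a cohort of synthetic "subjects", each with its own seeded
#' parameter draw inside the fitting box, emulating the design of a
#' small real-subject study.
#'
#' @param n_subjects number of synthetic subjects (default 6).
#' @param task_s,pattern paradigm of each subject's run.
#' @param dpf_values DPF values swept per subject.
#' @param vary which DPFs to vary (`"l1"`, `"l2"` or both).
#' @param fs analysis sampling rate in Hz for generation and fitting.
#' @param noise_sd measurement noise of the synthetic subjects.
#' @param n_restarts,max_iter fit settings (see [fit_hrf()]).
#' @param seed integer seed governing subject draws and fits.
#' @return a list of class `"fit_study_config"`.
#' @export
fit_study_config <- function(n_subjects = 6, task_s = 20, pattern = "St1",
                             dpf_values = 3:8, vary = c("l1", "l2"),
                             fs = 10, noise_sd = 0.1,
                             n_restarts = 12, max_iter = 4000,
                             seed = 1) {
  vary <- match.arg(vary, several.ok = TRUE)
  structure(list(n_subjects = n_subjects, task_s = task_s,
                 pattern = pattern, dpf_values = dpf_values, vary = vary,
                 fs = fs, noise_sd = noise_sd, n_restarts = n_restarts,
                 max_iter = max_iter, seed = seed),
            class = "fit_study_config")
}

# seeded per-subject parameter draw, comfortably inside the fitting box
draw_subject_params <- function(seed) {
  set.seed(seed)
  list(
    hrf = hrf_params(alpha1 = stats::runif(1, 4, 8),
                     alpha2 = stats::runif(1, 10, 18),
                     beta1 = stats::runif(1, 0.8, 1.5),
                     beta2 = stats::runif(1, 0.5, 1.2)),
    nuisance = nuisance_params(a0 = stats::runif(1, 2, 10),
                               a1 = stats::runif(1, 2, 10),
                               ac = stats::runif(1, 0.3, 1.5),
                               ar = stats::runif(1, 0.3, 1.5),
                               am = stats::runif(1, 0.3, 1.5),
                               fc = stats::runif(1, 0.7, 1.3),
                               fr = stats::runif(1, 0.21, 0.29),
                               fm = stats::runif(1, 0.091, 0.099),
                               noise_sd = 0)
  )
}

#' Run the multi-subject fit study
#'
#' For each synthetic subject: draw subject-specific HRF and nuisance
#' parameters, generate the HbO signal, split it under case 1 at the
#' implied true DPFs to obtain the subject's optical-density pair, then
#' run [sweep_fit()] per varied wavelength across the configured DPF
#' values. The result is the peak-versus-DPF summary table of the
#' cohort.
#'
#' @param config a [fit_study_config].
#' @param out_dir optional output directory for the table + manifest.
#' @return data frame with one row per subject x varied wavelength x
#'   DPF value (`subject`, `varied`, sweep columns).
#' @export
run_fit_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "fit_study_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paradigm <- simulated_paradigm(config$task_s, config$pattern)
  tabs <- list()
  for (s in seq_len(config$n_subjects)) {
    sub_seed <- config$seed * 1000L + s
    pars <- draw_subject_params(sub_seed)
    pars$nuisance$noise_sd <- config$noise_sd
    y <- generate_signal(pars$hrf, pars$nuisance, paradigm,
                         fs = config$fs, seed = sub_seed + 1L)
    pair <- split_signal(y, "case1")$pair
    for (vw in config$vary) {
      tab <- sweep_fit(pair, paradigm, config$dpf_values, vary = vw,
                       n_restarts = config$n_restarts,
                       max_iter = config$max_iter, seed = sub_seed + 2L)
      tabs[[length(tabs) + 1L]] <-
        cbind(data.frame(subject = s, varied = vw), tab)
    }
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "fit_study_table.csv"),
                     row.names = FALSE)
    write_manifest(out_dir, config, extra = list(rows = nrow(out)))
  }
  out
}
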