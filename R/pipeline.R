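pipeline_known_keys <- c("seed", "out_dir", "stages", "train_sim",
                         "mini_sim", "image_sim", "detector", "fit_window",
                         "alpha")

#' Build and validate a pipeline configuration
#'
#' A configuration is a named list with a mandatory `seed`, a vector of
#' `stages` to run (any of `"simulate_train"`, `"simulate_minis"`,
#' `"simulate_images"`, `"detect"`, `"intervals"`, `"train_analysis"`,
#' `"coloc"`), and per-stage parameter blocks. Unknown top-level keys are
#' rejected so that typos never pass silently. The configuration round-trips
#' losslessly through JSON.
#'
#' @param ... Named configuration entries, or a single list.
#' @return Validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && is.list(args[[1]])) {
    args <- args[[1]]
  }
  unknown <- setdiff(names(args), pipeline_known_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(list(
    seed = NULL,
    out_dir = tempfile("synquant_run_"),
    stages = c("simulate_train", "train_analysis"),
    train_sim = list(N0_nA = 16.3, p = 0.44, r_pA_per_ms = 62.2,
                     q_pA = 50, q_cv = 0.3, n_stim = 30, ipi_ms = 10,
                     mode = "deterministic"),
    mini_sim = list(w_fast = 0.64, tau_fast_ms = 170, tau_slow_ms = 740,
                    amp_mean_pA = 37, amp_sd_pA = 8, duration_ms = 30000,
                    noise_sd_pA = 2),
    image_sim = list(shape = c(256, 256), r_target = 0.78,
                     signal_mean = 100, signal_sd = 30, bg_level = 16),
    detector = list(),
    fit_window = c(20, 30),
    alpha = 0.01
  ), args)
  if (is.null(cfg$seed)) stop("config must include a seed", call. = FALSE)
  stop_if_not_scalar_number(cfg$seed, "seed")
  ts <- cfg$train_sim
  if (!is.null(ts$ipi_ms) && ts$ipi_ms <= 0) {
    stop("config field train_sim$ipi_ms must be > 0", call. = FALSE)
  }
  if (!is.null(ts$n_stim) && ts$n_stim < 1) {
    stop("config field train_sim$n_stim must be >= 1", call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(cfg), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the synthetic/analysis pipeline
#'
#' Executes the requested stages in order
#' simulate -> detect -> intervals -> train analysis -> colocalization and
#' writes each stage's outputs (CSV/TIFF/JSON) under `config$out_dir`. Each
#' output file is tagged with the hash of the generating configuration, and
#' the returned report echoes the config, seed, package version and per-stage
#' results. Identical config + seed reproduces identical outputs. A stage
#' failure aborts with the stage name and cause; outputs of completed stages
#' are preserved.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: list with `config`, `config_hash`, `seed`,
#'   `version`, `stages` (named per-stage result list), `files`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  report <- list(config = unclass(config), config_hash = hash, seed = seed,
                 version = as.character(packageVersion("synquant")),
                 stages = list(), files = character(0))
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- res$summary
    report$files <<- c(report$files, res$files)
    invisible(NULL)
  }
  train <- NULL; recording <- NULL; images <- NULL; events <- NULL

  if ("simulate_train" %in% config$stages) run_stage("simulate_train", function() {
    ts <- config$train_sim
    pool <- release_pool_params(N0_nA = ts$N0_nA, p = ts$p,
                                r_pA_per_ms = ts$r_pA_per_ms,
                                q_pA = ts$q_pA %||% 50, q_cv = ts$q_cv %||% 0)
    proto <- stim_protocol(ts$n_stim, ts$ipi_ms)
    train <<- if (identical(ts$mode, "stochastic")) {
      simulate_train_stochastic(pool, proto, seed = seed)
    } else {
      simulate_train_deterministic(pool, proto)
    }
    f <- file.path(config$out_dir, "train.csv")
    write_train_csv(train, f, hash)
    list(summary = list(n_stim = proto$n_stim, ipi_ms = proto$ipi_ms,
                        mode = ts$mode %||% "deterministic",
                        p1_nA = train$amplitudes_nA[1]),
         files = f)
  })

  if ("simulate_minis" %in% config$stages) run_stage("simulate_minis", function() {
    ms <- config$mini_sim
    mp <- mini_interval_params(w_fast = ms$w_fast, tau_fast_ms = ms$tau_fast_ms,
                               tau_slow_ms = ms$tau_slow_ms,
                               amp_mean_pA = ms$amp_mean_pA,
                               amp_sd_pA = ms$amp_sd_pA)
    recording <<- simulate_mini_recording(mp, ms$duration_ms, seed = seed + 1L,
                                          noise_sd_pA = ms$noise_sd_pA %||% 2)
    f <- file.path(config$out_dir, "trace.csv")
    write_trace_csv(recording$trace, f, hash)
    list(summary = list(n_events_true = length(recording$times_ms),
                        duration_ms = ms$duration_ms),
         files = f)
  })

  if ("simulate_images" %in% config$stages) run_stage("simulate_images", function() {
    is_ <- config$image_sim
    ip <- image_sim_params(shape = is_$shape, r_target = is_$r_target,
                           signal_mean = is_$signal_mean,
                           signal_sd = is_$signal_sd, bg_level = is_$bg_level)
    images <<- simulate_image_pair(ip, seed = seed + 2L)
    fa <- file.path(config$out_dir, "channel_a.tif")
    fb <- file.path(config$out_dir, "channel_b.tif")
    write_channel_tiff(images$chA, fa)
    write_channel_tiff(images$chB, fb)
    list(summary = list(r_target = is_$r_target, shape = ip$shape),
         files = c(fa, fb))
  })

  if ("detect" %in% config$stages) run_stage("detect", function() {
    if (is.null(recording)) stop("no trace available; run simulate_minis first")
    dp <- do.call(detection_params, config$detector)
    events <<- detect_minis(recording$trace, dp)
    f <- file.path(config$out_dir, "events.csv")
    write_events_csv(events, f, hash)
    summ <- event_summary(events, config$mini_sim$duration_ms)
    fj <- file.path(config$out_dir, "event_summary.json")
    jsonlite::write_json(summ, fj, auto_unbox = TRUE, digits = NA)
    list(summary = list(n_events = nrow(events),
                        frequency_hz = summ$frequency_hz),
         files = c(f, fj))
  })

  if ("intervals" %in% config$stages) run_stage("intervals", function() {
    if (is.null(events)) stop("no events available; run detect first")
    iv <- diff(events$peak_time_ms)
    fit <- fit_hyperexponential(iv)
    fj <- file.path(config$out_dir, "hyperexp_fit.json")
    jsonlite::write_json(list(w_fast = fit$w_fast,
                              tau_fast_ms = fit$tau_fast_ms,
                              tau_slow_ms = fit$tau_slow_ms,
                              percent_fast = fit$percent_fast,
                              rss = fit$rss, n = fit$n,
                              config = hash),
                         fj, auto_unbox = TRUE, digits = NA)
    list(summary = list(w_fast = fit$w_fast, tau_fast_ms = fit$tau_fast_ms,
                        tau_slow_ms = fit$tau_slow_ms),
         files = fj)
  })

  if ("train_analysis" %in% config$stages) run_stage("train_analysis", function() {
    if (is.null(train)) stop("no train available; run simulate_train first")
    est <- estimate_quantal_train(train, window = config$fit_window)
    expfit <- tryCatch(estimate_pr_exponential(train), error = function(e) NULL)
    res <- list(rrp_nA = est$rrp_nA, pr1 = est$pr1,
                slope_pA_per_ms = est$slope_pA_per_ms,
                ppr = paired_pulse_ratio(train),
                tau_stim = expfit$tau_stim %||% NA,
                pr_exp = expfit$pr %||% NA, fc = expfit$fc %||% NA,
                config = hash)
    fj <- file.path(config$out_dir, "train_estimates.json")
    jsonlite::write_json(res, fj, auto_unbox = TRUE, digits = NA)
    list(summary = res[names(res) != "config"], files = fj)
  })

  if ("coloc" %in% config$stages) run_stage("coloc", function() {
    if (is.null(images)) stop("no images available; run simulate_images first")
    bg <- config$image_sim$bg_level %||% 16
    pr_raw <- pearson_coloc(images$chA, images$chB)
    pr_bg <- pearson_coloc(images$chA, images$chB, background = bg)
    res <- list(r_raw = pr_raw$r, r_background_subtracted = pr_bg$r,
                n_pixels = pr_raw$n_pixels, background = bg, config = hash)
    fj <- file.path(config$out_dir, "coloc.json")
    jsonlite::write_json(res, fj, auto_unbox = TRUE, digits = NA)
    list(summary = res[names(res) != "config"], files = fj)
  })

  fj <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, fj, auto_unbox = TRUE, digits = NA, force = TRUE)
  report$files <- c(report$files, fj)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("synquant run %s (seed %d): %d stage(s)\n",
              substr(x$config_hash, 1, 8), x$seed, length(x$stages)))
  for (nm in names(x$stages)) cat("  -", nm, "\n")
  invisible(x)
}
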